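#' @import methods
NULL

#' FrameSequence: a raw ICG-A recording
#'
#' Ordered stack of two-dimensional near-infrared fluorescence frames with
#' acquisition timestamps. Frames are stored as an \code{H x W x T} array
#' (rows x columns x time); intensities are arbitrary nonnegative units
#' (gray-level counts of the NIR camera).
#'
#' @slot frames numeric array, \code{H x W x T}, all values >= 0.
#' @slot times numeric vector of length \code{T}, strictly increasing
#'   acquisition times in seconds since ICG injection.
#' @slot metadata named list of free-form acquisition metadata
#'   (ICG dose, device tag, ...).
#'
#' @seealso [FrameSequence()] for the constructor, [meanRoiCurve()],
#'   [extractPerfusionMap()]
#' @export
setClass("FrameSequence",
  representation(frames = "array", times = "numeric", metadata = "list"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L)
      return("frames must be a 3-dimensional H x W x T array")
    if (d[3] != length(object@times))
      return(sprintf("number of frames (%d) != number of timestamps (%d)",
                     d[3], length(object@times)))
    if (d[3] < 1L) return("at least one frame is required")
    if (anyNA(object@frames) || any(object@frames < 0))
      return("frame intensities must be nonnegative and non-missing")
    if (anyNA(object@times) || any(diff(object@times) <= 0))
      return("times must be strictly increasing")
    TRUE
  })

#' PhaseSegmentation: bolus-phase boundaries on a time-intensity curve
#'
#' Frame-index boundaries separating the arterial inflow, plateau, and
#' venous washout phases of the ICG bolus. The plateau window is the
#' closed index range \code{arterialEnd:venousStart}; it is nonempty by
#' construction (the curve maximum satisfies both boundary rules).
#'
#' @slot arterialEnd integer, first frame index of the plateau
#'   (end of arterial inflow).
#' @slot venousStart integer, last frame index of the plateau
#'   (start of venous washout).
#' @slot riseFraction,fallFraction the curve-maximum fractions used to
#'   locate the boundaries.
#'
#' @seealso [detectPhases()], [plateauIndices()]
#' @export
setClass("PhaseSegmentation",
  representation(arterialEnd = "integer", venousStart = "integer",
                 riseFraction = "numeric", fallFraction = "numeric"),
  validity = function(object) {
    if (object@arterialEnd < 1L) return("arterialEnd must be >= 1")
    if (object@venousStart < object@arterialEnd)
      return("venousStart must be >= arterialEnd (plateau must be nonempty)")
    TRUE
  })

#' PerfusionMap: plateau-phase absolute perfusion image
#'
#' A single per-pixel perfusion image aggregated over the plateau window
#' of the recording. Values are raw intensity units (the absolute
#' perfusion scale of the device, e.g. 0-255 gray shading); see
#' [computeRPU()] for conversion to relative perfusion units.
#'
#' @slot values numeric matrix \code{H x W}, all values >= 0.
#' @slot sourceIndices integer vector of the frame indices aggregated.
#' @slot aggregator character, \code{"median"}, \code{"mean"} or
#'   \code{"frame"} (single operator-chosen frame).
#'
#' @seealso [extractPerfusionMap()], [computeRPU()]
#' @export
setClass("PerfusionMap",
  representation(values = "matrix", sourceIndices = "integer",
                 aggregator = "character"),
  validity = function(object) {
    if (anyNA(object@values) || any(object@values < 0))
      return("perfusion values must be nonnegative and non-missing")
    if (length(object@sourceIndices) < 1L)
      return("sourceIndices must be nonempty")
    TRUE
  })

#' RPUMap: relative perfusion units over the breast ROI
#'
#' Per-pixel relative perfusion on a 0-100 scale inside the breast region
#' of interest: the normalizer intensity (by default the brightest in-ROI
#' point) is mapped to 100 and intensities are expressed as percentages,
#' clipped to [0, 100]. Pixels outside the ROI are 0 and carry no meaning.
#'
#' @slot values numeric matrix \code{H x W}, in [0, 100] inside the ROI.
#' @slot breastMask logical matrix, the breast ROI.
#' @slot normalizer numeric, the raw intensity mapped to RPU 100.
#' @slot percentile numeric, the in-ROI intensity percentile used as
#'   normalizer (100 = maximum).
#'
#' @seealso [computeRPU()], [segmentHypoperfused()], [assessFlap()]
#' @export
setClass("RPUMap",
  representation(values = "matrix", breastMask = "matrix",
                 normalizer = "numeric", percentile = "numeric"),
  validity = function(object) {
    if (!is.logical(object@breastMask))
      return("breastMask must be a logical matrix")
    if (!identical(dim(object@values), dim(object@breastMask)))
      return("values and breastMask dimensions differ")
    v <- object@values[object@breastMask]
    if (anyNA(v) || any(v < 0) || any(v > 100))
      return("in-ROI RPU values must lie in [0, 100]")
    if (object@percentile == 100 && length(v) && max(v) < 100 - 1e-9)
      return("with percentile 100 at least one in-ROI pixel must equal 100")
    if (object@normalizer <= 0) return("normalizer must be positive")
    TRUE
  })

#' FlapAssessment: hypoperfusion flags for one breast
#'
#' Bundles the hypoperfused-region segmentation with the three clinical
#' flags derived from it: whether the flap is hypoperfused at all
#' (any sub-cutoff region outside the nipple), whether the
#' hypoperfused-area percent ratio exceeds the reconstruction-decision
#' threshold (default 15\%), and whether it exceeds the study-eligibility
#' limit (default one-third of the breast area).
#'
#' @slot hypoMask logical matrix, the segmented hypoperfused region
#'   (never intersects the nipple).
#' @slot areaPercentRatio numeric, 100 * |hypoMask| / |breast ROI|.
#' @slot isHypoperfusedFlap logical, TRUE iff hypoMask is nonempty after
#'   small-component cleanup.
#' @slot decisionFlag character, \code{"proceed"} or
#'   \code{"change_strategy_or_close_followup"}.
#' @slot eligibilityExcluded logical, TRUE iff the ratio exceeds the
#'   eligibility threshold.
#' @slot cutoff,decisionThreshold,eligibilityThreshold,minComponentPx the
#'   parameters used, echoed for the report.
#'
#' @seealso [assessFlap()], [areaRatio()], [hypoMask()]
#' @export
setClass("FlapAssessment",
  representation(hypoMask = "matrix", areaPercentRatio = "numeric",
                 isHypoperfusedFlap = "logical", decisionFlag = "character",
                 eligibilityExcluded = "logical", cutoff = "numeric",
                 decisionThreshold = "numeric",
                 eligibilityThreshold = "numeric",
                 minComponentPx = "numeric"),
  validity = function(object) {
    if (!is.logical(object@hypoMask)) return("hypoMask must be logical")
    if (object@areaPercentRatio < 0 || object@areaPercentRatio > 100)
      return("areaPercentRatio must lie in [0, 100]")
    if (!object@decisionFlag %in%
          c("proceed", "change_strategy_or_close_followup"))
      return("invalid decisionFlag")
    if (object@isHypoperfusedFlap != any(object@hypoMask))
      return("isHypoperfusedFlap inconsistent with hypoMask")
    TRUE
  })

#' ConfusionTable: 2x2 predictor-by-outcome counts
#'
#' Cross-tabulation of a binary predictor (e.g. hypoperfused flap) against
#' a binary outcome (e.g. skin-flap necrosis).
#'
#' @slot tp,fp,fn,tn nonnegative integer counts (true positive, false
#'   positive, false negative, true negative); total >= 1.
#'
#' @seealso [ConfusionTable()], [buildConfusion()], [diagnosticMetrics()],
#'   [fisherExactTwoSided()]
#' @export
setClass("ConfusionTable",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer"),
  validity = function(object) {
    cnt <- c(object@tp, object@fp, object@fn, object@tn)
    if (anyNA(cnt) || any(cnt < 0)) return("counts must be nonnegative")
    if (sum(cnt) < 1L) return("table total must be >= 1")
    TRUE
  })

#' DiagnosticSummary: accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value with
#' exact (Clopper-Pearson) binomial confidence intervals. A metric with a
#' zero denominator is reported as \code{NA}, never as 0.
#'
#' @slot metrics data.frame with columns \code{metric}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{x}, \code{n} (successes and
#'   denominator of each proportion).
#' @slot prevalence numeric, outcome prevalence (tp+fn)/total.
#' @slot level numeric, the confidence level.
#' @slot table the source [ConfusionTable-class].
#'
#' @seealso [diagnosticMetrics()], [clopperPearsonCI()]
#' @export
setClass("DiagnosticSummary",
  representation(metrics = "data.frame", prevalence = "numeric",
                 level = "numeric", table = "ConfusionTable"),
  validity = function(object) {
    need <- c("metric", "estimate", "lower", "upper", "x", "n")
    if (!all(need %in% names(object@metrics)))
      return("metrics must have columns metric/estimate/lower/upper/x/n")
    ok <- stats::complete.cases(object@metrics[, c("estimate", "lower", "upper")])
    m <- object@metrics[ok, ]
    if (any(m$estimate < m$lower - 1e-12 | m$estimate > m$upper + 1e-12))
      return("each point estimate must lie inside its interval")
    TRUE
  })

#' KineticProfile: per-pixel ICG bolus kinetics
#'
#' Piecewise fluorescence time course of a fully perfused pixel: linear
#' arterial rise from 0 to \code{plateauLevel} at \code{timeToPeak},
#' constant plateau until \code{washoutStart}, then exponential venous
#' washout at rate \code{washoutRate}. This is the minimal functional form
#' exhibiting the three phases of the ICG bolus (arterial, plateau,
#' venous).
#'
#' @slot timeToPeak numeric, seconds > 0.
#' @slot plateauLevel numeric, plateau intensity in arbitrary units >= 0.
#' @slot washoutStart numeric, seconds >= timeToPeak.
#' @slot washoutRate numeric, washout decay rate in 1/seconds >= 0.
#'
#' @seealso [KineticProfile()], [kineticCurve()], [simulateRecording()]
#' @export
setClass("KineticProfile",
  representation(timeToPeak = "numeric", plateauLevel = "numeric",
                 washoutStart = "numeric", washoutRate = "numeric"),
  validity = function(object) {
    if (object@timeToPeak <= 0) return("timeToPeak must be > 0")
    if (object@plateauLevel < 0) return("plateauLevel must be >= 0")
    if (object@washoutStart < object@timeToPeak)
      return("washoutStart must be >= timeToPeak")
    if (object@washoutRate < 0) return("washoutRate must be >= 0")
    TRUE
  })

#' TerritoryModel: perforator-territory partition of the breast ROI
#'
#' Nearest-seed (Voronoi) partition of the breast pixels into perfusion
#' territories, a subset of which may be "dropped out" (their plateau
#' intensity multiplied by \code{dropoutFactor}) to emulate perforator
#' damage.
#'
#' @slot labels integer matrix; territory id 1..n inside the breast ROI,
#'   0 outside. Every breast pixel carries exactly one label.
#' @slot seedPoints integer matrix \code{n x 2} of (row, col) seed pixels.
#' @slot dropoutIds integer vector, subset of 1..n.
#' @slot dropoutFactor numeric in [0, 1]; plateau multiplier in dropout
#'   territories.
#'
#' @seealso [makeTerritories()], [simulateRecording()]
#' @export
setClass("TerritoryModel",
  representation(labels = "matrix", seedPoints = "matrix",
                 dropoutIds = "integer", dropoutFactor = "numeric"),
  validity = function(object) {
    n <- nrow(object@seedPoints)
    lab <- object@labels[object@labels > 0L]
    if (length(lab) && (min(lab) < 1L || max(lab) > n))
      return("territory labels must lie in 1..n_territories")
    if (length(object@dropoutIds) &&
        !all(object@dropoutIds %in% seq_len(n)))
      return("dropoutIds must be a subset of 1..n_territories")
    if (object@dropoutFactor < 0 || object@dropoutFactor > 1)
      return("dropoutFactor must lie in [0, 1]")
    TRUE
  })

#' SyntheticCase: a simulated ICG-A recording with ground truth
#'
#' One synthetic breast: the simulated frame stack, the breast and nipple
#' ROI masks, and the ground-truth hypoperfusion geometry against which
#' the analysis pipeline can be validated.
#'
#' @slot frames a [FrameSequence-class].
#' @slot breastMask,nippleMask logical matrices.
#' @slot truthHypoMask logical matrix, union of dropout territories
#'   (nipple excluded); always a subset of the breast ROI.
#' @slot truthAreaFraction numeric percent,
#'   100 * |truthHypoMask| / |breastMask| (same denominator convention as
#'   [areaPercentRatio()]).
#' @slot territories the [TerritoryModel-class] used.
#' @slot seed integer RNG seed of the case.
#'
#' @seealso [simulateRecording()], [assessRecording()]
#' @export
setClass("SyntheticCase",
  representation(frames = "FrameSequence", breastMask = "matrix",
                 nippleMask = "matrix", truthHypoMask = "matrix",
                 truthAreaFraction = "numeric", territories = "TerritoryModel",
                 seed = "integer"),
  validity = function(object) {
    if (any(object@truthHypoMask & !object@breastMask))
      return("truthHypoMask must be a subset of breastMask")
    if (any(object@nippleMask & !object@breastMask))
      return("nippleMask must be a subset of breastMask")
    expect <- 100 * sum(object@truthHypoMask) / sum(object@breastMask)
    if (abs(expect - object@truthAreaFraction) > 1e-9)
      return("truthAreaFraction inconsistent with truthHypoMask")
    TRUE
  })

#' RunConfig: resolved analysis parameters
#'
#' All tunable thresholds of the assessment pipeline in one validated,
#' serializable object. Configurations round-trip exactly through
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @slot cutoff RPU hypoperfusion cutoff in percent (default 30).
#' @slot decisionThreshold area-ratio percent above which a change of
#'   reconstruction strategy or close follow-up is advised (default 15).
#' @slot eligibilityThreshold area-ratio percent above which the flap is
#'   outside the intended use of the criterion (default 100/3).
#' @slot percentile normalizer percentile for RPU (default 100).
#' @slot minComponentPx smallest hypoperfused component kept, pixels.
#' @slot riseFraction,fallFraction plateau boundary fractions.
#' @slot aggregator plateau aggregator, \code{"median"} or \code{"mean"}.
#' @slot seed integer RNG seed for stochastic stages.
#' @slot version package version string.
#'
#' @seealso [runConfig()], [readRunConfig()], [writeRunConfig()]
#' @export
setClass("RunConfig",
  representation(cutoff = "numeric", decisionThreshold = "numeric",
                 eligibilityThreshold = "numeric", percentile = "numeric",
                 minComponentPx = "numeric", riseFraction = "numeric",
                 fallFraction = "numeric", aggregator = "character",
                 seed = "integer", version = "character"),
  validity = function(object) {
    chk <- function(x, lo, hi, what)
      if (length(x) != 1L || is.na(x) || x < lo || x > hi)
        sprintf("%s must be a single value in [%g, %g]", what, lo, hi) else NULL
    msg <- c(chk(object@cutoff, 1e-12, 100, "cutoff"),
             chk(object@decisionThreshold, 0, 100, "decisionThreshold"),
             chk(object@eligibilityThreshold, 0, 100, "eligibilityThreshold"),
             chk(object@percentile, 1e-12, 100, "percentile"),
             chk(object@minComponentPx, 1, Inf, "minComponentPx"),
             chk(object@riseFraction, 0, 1, "riseFraction"),
             chk(object@fallFraction, 0, 1, "fallFraction"))
    if (length(msg)) return(msg[1])
    if (!object@aggregator %in% c("median", "mean"))
      return("aggregator must be 'median' or 'mean'")
    TRUE
  })
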