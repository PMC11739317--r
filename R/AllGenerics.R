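#' Accessors for the core classes
#'
#' Small accessor generics so user code never reaches into slots:
#' \describe{
#'   \item{`frames(x)`}{the H x W x T intensity array of a
#'     [FrameSequence-class] (or of a [SyntheticCase-class]'s recording).}
#'   \item{`frameTimes(x)`}{acquisition times in seconds.}
#'   \item{`nFrames(x)`}{number of frames.}
#'   \item{`plateauIndices(x)`}{the contiguous plateau frame-index range of
#'     a [PhaseSegmentation-class].}
#'   \item{`mapValues(x)`}{the numeric matrix of a [PerfusionMap-class] or
#'     [RPUMap-class].}
#'   \item{`breastMask(x)`, `nippleMask(x)`}{ROI masks.}
#'   \item{`hypoMask(x)`}{segmented hypoperfused region of a
#'     [FlapAssessment-class].}
#'   \item{`areaRatio(x)`}{hypoperfused-area percent ratio.}
#'   \item{`isHypoperfused(x)`}{the hypoperfused-flap flag.}
#'   \item{`decisionFlag(x)`}{`"proceed"` or
#'     `"change_strategy_or_close_followup"`.}
#'   \item{`eligibilityExcluded(x)`}{the one-third eligibility screen flag.}
#'   \item{`territoryLabels(x)`}{integer label matrix of a
#'     [TerritoryModel-class].}
#'   \item{`truthHypoMask(x)`, `truthAreaFraction(x)`}{simulation ground
#'     truth of a [SyntheticCase-class].}
#'   \item{`counts(x)`}{named tp/fp/fn/tn vector of a
#'     [ConfusionTable-class].}
#'   \item{`metrics(x)`}{the estimate/CI data.frame of a
#'     [DiagnosticSummary-class].}
#' }
#'
#' @param x an object of the matching class.
#' @return See the list above.
#' @name accessors
#' @aliases frames frameTimes nFrames plateauIndices mapValues breastMask
#'   nippleMask hypoMask areaRatio isHypoperfused decisionFlag
#'   eligibilityExcluded territoryLabels truthHypoMask truthAreaFraction
#'   counts metrics
#' @examples
#' dom <- makeBreastDomain(60, 60)
#' terr <- makeTerritories(dom$breastMask, 4, seed = 1, dropoutIds = 1L,
#'                         dropoutFactor = 0.1)
#' case <- simulateRecording(dom, terr, KineticProfile())
#' nFrames(frames(case))
#' truthAreaFraction(case)
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("plateauIndices", function(x) standardGeneric("plateauIndices"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("breastMask", function(x) standardGeneric("breastMask"))
#' @rdname accessors
#' @export
setGeneric("nippleMask", function(x) standardGeneric("nippleMask"))
#' @rdname accessors
#' @export
setGeneric("hypoMask", function(x) standardGeneric("hypoMask"))
#' @rdname accessors
#' @export
setGeneric("areaRatio", function(x) standardGeneric("areaRatio"))
#' @rdname accessors
#' @export
setGeneric("isHypoperfused", function(x) standardGeneric("isHypoperfused"))
#' @rdname accessors
#' @export
setGeneric("decisionFlag", function(x) standardGeneric("decisionFlag"))
#' @rdname accessors
#' @export
setGeneric("eligibilityExcluded",
           function(x) standardGeneric("eligibilityExcluded"))
#' @rdname accessors
#' @export
setGeneric("territoryLabels", function(x) standardGeneric("territoryLabels"))
#' @rdname accessors
#' @export
setGeneric("truthHypoMask", function(x) standardGeneric("truthHypoMask"))
#' @rdname accessors
#' @export
setGeneric("truthAreaFraction",
           function(x) standardGeneric("truthAreaFraction"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))

#' @rdname accessors
setMethod("frames", "FrameSequence", function(x) x@frames)
#' @rdname accessors
setMethod("frames", "SyntheticCase", function(x) x@frames@frames)
#' @rdname accessors
setMethod("frameTimes", "FrameSequence", function(x) x@times)
#' @rdname accessors
setMethod("frameTimes", "SyntheticCase", function(x) x@frames@times)
#' @rdname accessors
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3])
#' @rdname accessors
setMethod("plateauIndices", "PhaseSegmentation",
          function(x) x@arterialEnd:x@venousStart)
#' @rdname accessors
setMethod("mapValues", "PerfusionMap", function(x) x@values)
#' @rdname accessors
setMethod("mapValues", "RPUMap", function(x) x@values)
#' @rdname accessors
setMethod("breastMask", "RPUMap", function(x) x@breastMask)
#' @rdname accessors
setMethod("breastMask", "SyntheticCase", function(x) x@breastMask)
#' @rdname accessors
setMethod("nippleMask", "SyntheticCase", function(x) x@nippleMask)
#' @rdname accessors
setMethod("hypoMask", "FlapAssessment", function(x) x@hypoMask)
#' @rdname accessors
setMethod("areaRatio", "FlapAssessment", function(x) x@areaPercentRatio)
#' @rdname accessors
setMethod("isHypoperfused", "FlapAssessment",
          function(x) x@isHypoperfusedFlap)
#' @rdname accessors
setMethod("decisionFlag", "FlapAssessment", function(x) x@decisionFlag)
#' @rdname accessors
setMethod("eligibilityExcluded", "FlapAssessment",
          function(x) x@eligibilityExcluded)
#' @rdname accessors
setMethod("territoryLabels", "TerritoryModel", function(x) x@labels)
#' @rdname accessors
setMethod("truthHypoMask", "SyntheticCase", function(x) x@truthHypoMask)
#' @rdname accessors
setMethod("truthAreaFraction", "SyntheticCase",
          function(x) x@truthAreaFraction)
#' @rdname accessors
setMethod("counts", "ConfusionTable",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))
#' @rdname accessors
setMethod("metrics", "DiagnosticSummary", function(x) x@metrics)

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameSequence: %d frames of %d x %d px, t = %.1f..%.1f s\n",
              d[3], d[1], d[2], object@times[1], object@times[d[3]]))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "PhaseSegmentation", function(object) {
  cat(sprintf(
    "PhaseSegmentation: plateau frames %d..%d (rise %.2f, fall %.2f)\n",
    object@arterialEnd, object@venousStart,
    object@riseFraction, object@fallFraction))
})

setMethod("show", "PerfusionMap", function(object) {
  cat(sprintf("PerfusionMap: %d x %d px, %s over %d plateau frame(s)\n",
              nrow(object@values), ncol(object@values), object@aggregator,
              length(object@sourceIndices)))
})

setMethod("show", "RPUMap", function(object) {
  v <- object@values[object@breastMask]
  cat(sprintf(
    "RPUMap: %d ROI px, normalizer %.3g (percentile %g), RPU range %.1f..%.1f\n",
    sum(object@breastMask), object@normalizer, object@percentile,
    min(v), max(v)))
})

setMethod("show", "FlapAssessment", function(object) {
  cat(sprintf("FlapAssessment:\n  hypoperfused flap: %s (%d px < %g RPU)\n",
              if (object@isHypoperfusedFlap) "YES" else "no",
              sum(object@hypoMask), object@cutoff))
  cat(sprintf("  area percent ratio: %.2f%% (decision threshold %g%%)\n",
              object@areaPercentRatio, object@decisionThreshold))
  cat(sprintf("  decision: %s\n", object@decisionFlag))
  cat(sprintf("  eligibility excluded (> %.1f%%): %s\n",
              object@eligibilityThreshold,
              if (object@eligibilityExcluded) "YES" else "no"))
})

setMethod("show", "ConfusionTable", function(object) {
  m <- matrix(c(object@tp, object@fp, object@fn, object@tn), 2, 2,
              byrow = TRUE,
              dimnames = list(c("predictor (+)", "predictor (-)"),
                              c("outcome (+)", "outcome (-)")))
  cat("ConfusionTable (n =", sum(m), ")\n")
  print(m)
})

setMethod("show", "DiagnosticSummary", function(object) {
  cat(sprintf("DiagnosticSummary (%.0f%% Clopper-Pearson CIs)\n",
              100 * object@level))
  m <- object@metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s  NA (zero denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %6.1f%%  [%.1f, %.1f]  (%d/%d)\n", m$metric[i],
                  100 * m$estimate[i], 100 * m$lower[i], 100 * m$upper[i],
                  m$x[i], m$n[i]))
    }
  }
  cat(sprintf("  prevalence   %6.1f%%\n", 100 * object@prevalence))
})

setMethod("show", "TerritoryModel", function(object) {
  cat(sprintf(
    "TerritoryModel: %d territories over %d px; dropout %s (factor %.2f)\n",
    nrow(object@seedPoints), sum(object@labels > 0L),
    if (length(object@dropoutIds))
      paste(object@dropoutIds, collapse = ",") else "none",
    object@dropoutFactor))
})

setMethod("show", "SyntheticCase", function(object) {
  cat("SyntheticCase (seed", object@seed, ")\n  ")
  show(object@frames)
  cat(sprintf("  breast %d px, nipple %d px, truth hypo %d px (%.2f%%)\n",
              sum(object@breastMask), sum(object@nippleMask),
              sum(object@truthHypoMask), object@truthAreaFraction))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  for (f in c("cutoff", "decisionThreshold", "eligibilityThreshold",
              "percentile", "minComponentPx", "riseFraction",
              "fallFraction", "aggregator", "seed", "version"))
    cat(sprintf("  %-20s %s\n", f, format(slot(object, f))))
})
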