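#' Normalize a perfusion map to relative perfusion units
#'
#' RPU expresses each pixel's plateau intensity as a percentage of the
#' most perfused point in the target area: the chosen percentile of the
#' in-ROI intensities (default 100, i.e. the maximum) is mapped to 100
#' and values are clipped to [0, 100]. With a percentile below 100 the
#' normalizer is robust to isolated hot pixels; its use is flagged via
#' a message.
#'
#' @param map a [PerfusionMap-class].
#' @param breastMask logical matrix, the breast ROI (nonempty).
#' @param percentile in-ROI intensity percentile mapped to 100.
#' @return an [RPUMap-class]. RPU is invariant to rescaling all
#'   intensities by any k > 0.
#' @examples
#' pm <- new("PerfusionMap", values = matrix(c(10, 50, 200, 0), 2, 2),
#'           sourceIndices = 1L, aggregator = "frame")
#' roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
#' mapValues(computeRPU(pm, roi))[roi]  # 5 25 100
#' @export
computeRPU <- function(map, breastMask, percentile = 100) {
  stopifnot(is(map, "PerfusionMap"), is.logical(breastMask))
  if (!identical(dim(map@values), dim(breastMask)))
    stop("perfusion map and breast mask dimensions differ")
  if (!any(breastMask)) stop("breast mask is empty")
  stopifnot(percentile > 0, percentile <= 100)
  intens <- map@values[breastMask]
  if (max(intens) <= 0) stop("no perfusion signal in breast ROI")
  normalizer <- if (percentile == 100) max(intens) else
    as.numeric(stats::quantile(intens, percentile / 100, names = FALSE))
  if (normalizer <= 0) stop("normalizer percentile of ROI intensities is 0")
  if (percentile != 100)
    message(sprintf("RPU normalizer: percentile %g (intensity %.4g)",
                    percentile, normalizer))
  values <- matrix(0, nrow(breastMask), ncol(breastMask))
  values[breastMask] <- 100 * pmin(pmax(intens / normalizer, 0), 1)
  new("RPUMap", values = values, breastMask = breastMask,
      normalizer = normalizer, percentile = percentile)
}

# 8-connected component labelling (union of row/col/diagonal neighbours).
# Iterative flood fill; masks are small (hundreds x hundreds of px).
labelComponents <- function(mask) {
  stopifnot(is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    stack <- p
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((q - 1L) %% h) + 1L
      cc <- ((q - 1L) %/% h) + 1L
      rr <- r + dr; ccc <- cc + dc
      ok <- rr >= 1L & rr <= h & ccc >= 1L & ccc <= w
      nb <- (ccc[ok] - 1L) * h + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Segment the hypoperfused region
#'
#' The hypoperfused region is the set of breast pixels outside the nipple
#' whose RPU is strictly below the cutoff ("below 30\%": RPU exactly at
#' the cutoff is not hypoperfused). Connected components (8-connectivity)
#' smaller than \code{minComponentPx} are then removed as speckle;
#' \code{minComponentPx = 1} reproduces the raw per-pixel thresholding.
#' The nipple is never counted hypoperfused regardless of its RPU - after
#' nipple-sparing mastectomy the nipple-areolar complex routinely reads
#' below the cutoff without going on to necrosis.
#'
#' @param rpu an [RPUMap-class].
#' @param nippleMask logical matrix, same size; subset of the breast ROI.
#' @param cutoff RPU cutoff in percent, 0 < cutoff <= 100 (default 30).
#' @param minComponentPx smallest connected component kept (default 25).
#' @return logical matrix: the hypoperfused mask.
#' @export
segmentHypoperfused <- function(rpu, nippleMask, cutoff = 30,
                                minComponentPx = 25) {
  stopifnot(is(rpu, "RPUMap"), is.logical(nippleMask))
  if (!identical(dim(nippleMask), dim(rpu@values)))
    stop("nipple mask and RPU map dimensions differ")
  stopifnot(cutoff > 0, cutoff <= 100, minComponentPx >= 1)
  raw <- rpu@breastMask & !nippleMask & (rpu@values < cutoff)
  if (minComponentPx > 1 && any(raw)) {
    lab <- labelComponents(raw)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minComponentPx)
    raw <- matrix(lab %in% keep, nrow(raw), ncol(raw)) & raw
  }
  raw
}

#' Hypoperfused-area percent ratio
#'
#' 100 times the hypoperfused area divided by the ipsilateral breast
#' area. The denominator is the full breast ROI including the nipple;
#' the numerator never contains nipple pixels (they are excluded at
#' segmentation).
#'
#' @param hypoMask logical matrix, subset of \code{breastMask}.
#' @param breastMask logical matrix, nonempty.
#' @return percent in [0, 100].
#' @examples
#' b <- matrix(TRUE, 100, 100)          # 10,000 px breast
#' h <- matrix(FALSE, 100, 100); h[seq_len(655)] <- TRUE
#' areaPercentRatio(h, b)               # 6.55
#' @export
areaPercentRatio <- function(hypoMask, breastMask) {
  stopifnot(is.logical(hypoMask), is.logical(breastMask))
  if (!any(breastMask)) stop("breast mask is empty")
  if (any(hypoMask & !breastMask))
    stop("hypoMask must be a subset of breastMask")
  100 * sum(hypoMask) / sum(breastMask)
}

#' Assess a flap from its RPU map
#'
#' Bundles segmentation and the three clinical flags:
#' \itemize{
#'   \item \emph{hypoperfused flap} - any region outside the nipple with
#'     RPU below \code{cutoff} (after small-component cleanup);
#'   \item \emph{decision rule} - if the hypoperfused-area percent ratio
#'     exceeds \code{decisionThreshold} (default 15\%), a change of
#'     reconstruction strategy (delayed reconstruction) or close
#'     follow-up wound monitoring is advised;
#'   \item \emph{eligibility screen} - a ratio above
#'     \code{eligibilityThreshold} (default one-third) marks a flap whose
#'     necrosis risk is so high it falls outside the criterion's intended
#'     use.
#' }
#'
#' @inheritParams segmentHypoperfused
#' @param decisionThreshold percent ratio above which the decision flag
#'   switches (default 15).
#' @param eligibilityThreshold percent ratio above which the case is
#'   screened out (default 100/3).
#' @return a [FlapAssessment-class].
#' @export
assessFlap <- function(rpu, nippleMask, cutoff = 30, decisionThreshold = 15,
                       eligibilityThreshold = 100 / 3, minComponentPx = 25) {
  hypo <- segmentHypoperfused(rpu, nippleMask, cutoff = cutoff,
                              minComponentPx = minComponentPx)
  ratio <- areaPercentRatio(hypo, rpu@breastMask)
  new("FlapAssessment", hypoMask = hypo, areaPercentRatio = ratio,
      isHypoperfusedFlap = any(hypo),
      decisionFlag = if (ratio > decisionThreshold)
        "change_strategy_or_close_followup" else "proceed",
      eligibilityExcluded = ratio > eligibilityThreshold,
      cutoff = cutoff, decisionThreshold = decisionThreshold,
      eligibilityThreshold = eligibilityThreshold,
      minComponentPx = minComponentPx)
}

#' Run the full assessment pipeline on a recording
#'
#' Convenience wrapper chaining the stages: ROI bolus curve ->
#' phase detection -> plateau perfusion map -> RPU normalization ->
#' hypoperfusion segmentation and flags.
#'
#' @param seq a [FrameSequence-class] or [SyntheticCase-class] (masks are
#'   then taken from the case unless given).
#' @param breastMask,nippleMask logical ROI masks.
#' @param config a [RunConfig-class] with all thresholds; default
#'   [runConfig()].
#' @return list with components \code{curve}, \code{phases}, \code{map},
#'   \code{rpu} and \code{assessment} (a [FlapAssessment-class]).
#' @examples
#' dom <- makeBreastDomain(80, 80)
#' terr <- makeTerritories(dom$breastMask, 5, seed = 3,
#'                         dropoutIds = 1L, dropoutFactor = 0.1)
#' case <- simulateRecording(dom, terr, KineticProfile())
#' res <- assessRecording(case)
#' areaRatio(res$assessment)      # equals truthAreaFraction(case)
#' @export
assessRecording <- function(seq, breastMask = NULL, nippleMask = NULL,
                            config = runConfig()) {
  if (is(seq, "SyntheticCase")) {
    if (is.null(breastMask)) breastMask <- seq@breastMask
    if (is.null(nippleMask)) nippleMask <- seq@nippleMask
    seq <- seq@frames
  }
  stopifnot(is(seq, "FrameSequence"),
            !is.null(breastMask), !is.null(nippleMask))
  curve <- meanRoiCurve(seq, breastMask)
  phases <- detectPhases(curve, riseFraction = config@riseFraction,
                         fallFraction = config@fallFraction)
  map <- extractPerfusionMap(seq, phases, aggregator = config@aggregator)
  rpu <- computeRPU(map, breastMask, percentile = config@percentile)
  assessment <- assessFlap(rpu, nippleMask, cutoff = config@cutoff,
                           decisionThreshold = config@decisionThreshold,
                           eligibilityThreshold = config@eligibilityThreshold,
                           minComponentPx = config@minComponentPx)
  list(curve = curve, phases = phases, map = map, rpu = rpu,
       assessment = assessment)
}
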