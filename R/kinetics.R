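#' Mean ROI time-intensity curve
#'
#' Mean intensity over the ROI pixels of each frame: the bolus curve used
#' to locate the arterial, plateau and venous phases.
#'
#' @param seq a [FrameSequence-class].
#' @param roi logical matrix, same H x W as the frames, nonempty.
#' @return numeric vector, one value per frame.
#' @export
meanRoiCurve <- function(seq, roi) {
  stopifnot(is(seq, "FrameSequence"))
  if (!is.logical(roi)) stop("roi must be a logical mask")
  d <- dim(seq@frames)
  if (!identical(dim(roi), d[1:2]))
    stop(sprintf("roi is %d x %d but frames are %d x %d",
                 nrow(roi), ncol(roi), d[1], d[2]))
  if (!any(roi)) stop("roi is empty")
  idx <- which(roi)
  flat <- matrix(seq@frames, d[1] * d[2], d[3])
  colMeans(flat[idx, , drop = FALSE])
}

#' Detect the arterial / plateau / venous phases of the bolus curve
#'
#' Threshold rule on the ROI curve: the plateau starts at the first frame
#' reaching \code{riseFraction} of the curve maximum (end of arterial
#' inflow) and ends at the last frame still at \code{fallFraction} of the
#' maximum (start of venous washout). The maximum frame satisfies both,
#' so the plateau window is never empty and always contains the argmax.
#'
#' @param curve numeric time-intensity curve, length >= 3.
#' @param riseFraction fraction of the maximum ending the arterial phase
#'   (default 0.95).
#' @param fallFraction fraction of the maximum starting the venous phase
#'   (default 0.90).
#' @return a [PhaseSegmentation-class].
#' @examples
#' curve <- kineticCurve(KineticProfile(), seq(0, 180, 2))
#' detectPhases(curve)
#' @export
detectPhases <- function(curve, riseFraction = 0.95, fallFraction = 0.90) {
  if (length(curve) < 3L) stop("curve must have at least 3 samples")
  stopifnot(riseFraction > 0, riseFraction <= 1,
            fallFraction > 0, fallFraction <= 1)
  m <- max(curve)
  if (!is.finite(m) || m <= 0) stop("no perfusion signal in ROI curve")
  arterialEnd <- which(curve >= riseFraction * m)[1]
  venousStart <- max(which(curve >= fallFraction * m))
  new("PhaseSegmentation", arterialEnd = as.integer(arterialEnd),
      venousStart = as.integer(venousStart),
      riseFraction = riseFraction, fallFraction = fallFraction)
}

#' Extract the plateau-phase perfusion map
#'
#' Per-pixel aggregate of the plateau frames - the "frozen" perfusion
#' image read off the device screen during the plateau phase. The default
#' median over the plateau window is robust to frame flicker; a single
#' operator-chosen frame (\code{frameIndex}) mirrors the one-screen
#' clinical workflow.
#'
#' @param seq a [FrameSequence-class].
#' @param seg a [PhaseSegmentation-class] valid for \code{seq}.
#' @param aggregator \code{"median"} (default) or \code{"mean"}.
#' @param frameIndex optional single frame index; overrides the
#'   aggregator.
#' @return a [PerfusionMap-class].
#' @export
extractPerfusionMap <- function(seq, seg, aggregator = c("median", "mean"),
                                frameIndex = NULL) {
  stopifnot(is(seq, "FrameSequence"), is(seg, "PhaseSegmentation"))
  d <- dim(seq@frames)
  if (!is.null(frameIndex)) {
    if (length(frameIndex) != 1L || frameIndex < 1 || frameIndex > d[3])
      stop("frameIndex out of range")
    return(new("PerfusionMap", values = seq@frames[, , frameIndex],
               sourceIndices = as.integer(frameIndex),
               aggregator = "frame"))
  }
  aggregator <- match.arg(aggregator)
  idx <- plateauIndices(seg)
  if (idx[length(idx)] > d[3]) stop("plateau indices out of range for seq")
  sub <- seq@frames[, , idx, drop = FALSE]
  values <- if (length(idx) == 1L) {
    sub[, , 1]
  } else if (aggregator == "mean") {
    rowMeans(sub, dims = 2)
  } else {
    matrix(apply(matrix(sub, d[1] * d[2], length(idx)), 1,
                 stats::median), d[1], d[2])
  }
  new("PerfusionMap", values = values, sourceIndices = as.integer(idx),
      aggregator = aggregator)
}
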