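#' Construct a FrameSequence
#'
#' @param frames numeric H x W x T array of nonnegative intensities, or a
#'   single H x W matrix (one frame).
#' @param times numeric vector of strictly increasing frame times,
#'   seconds.
#' @param metadata optional named list of acquisition metadata.
#' @return a [FrameSequence-class].
#' @examples
#' fs <- FrameSequence(array(1, c(4, 4, 3)), times = c(0, 2, 4))
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, times, metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("FrameSequence", frames = frames, times = as.numeric(times),
      metadata = metadata)
}

#' Construct a kinetic profile of the ICG bolus
#'
#' Defaults describe a typical 3-minute post-injection recording: arterial
#' rise over the first 30 s, stable plateau until 120 s, then venous
#' washout with rate 0.02/s.
#'
#' @param timeToPeak seconds to reach the plateau, > 0.
#' @param plateauLevel plateau intensity, arbitrary units >= 0.
#' @param washoutStart seconds at which venous washout begins,
#'   >= timeToPeak.
#' @param washoutRate exponential washout rate, 1/s >= 0.
#' @return a [KineticProfile-class].
#' @examples
#' kineticCurve(KineticProfile(), c(0, 15, 30, 100, 120, 170))
#' @export
KineticProfile <- function(timeToPeak = 30, plateauLevel = 100,
                           washoutStart = 120, washoutRate = 0.02) {
  new("KineticProfile", timeToPeak = timeToPeak, plateauLevel = plateauLevel,
      washoutStart = washoutStart, washoutRate = washoutRate)
}

#' Evaluate a kinetic profile
#'
#' Piecewise bolus curve: linear rise to \code{plateauLevel} at
#' \code{timeToPeak}, constant until \code{washoutStart}, exponential
#' decay afterwards. Nonnegative for all t; 0 before injection (t < 0).
#'
#' @param profile a [KineticProfile-class].
#' @param times numeric vector of times in seconds.
#' @return numeric vector of intensities, same length as \code{times}.
#' @export
kineticCurve <- function(profile, times) {
  t <- as.numeric(times)
  p <- profile
  y <- ifelse(t < 0, 0,
       ifelse(t < p@timeToPeak, p@plateauLevel * t / p@timeToPeak,
       ifelse(t < p@washoutStart, p@plateauLevel,
              p@plateauLevel * exp(-p@washoutRate * (t - p@washoutStart)))))
  y
}

#' Build a breast-shaped analysis domain
#'
#' An elliptical breast ROI inscribed in the image (with a small margin)
#' and a circular nipple ROI. These stand in for the operator-drawn ROIs
#' of the clinical workflow.
#'
#' @param height,width image size in pixels.
#' @param nippleCenter integer (row, col) of the nipple centre; default
#'   the breast centroid.
#' @param nippleRadius nipple disc radius in pixels (0 gives an empty
#'   nipple mask, e.g. after skin-sparing mastectomy).
#' @return list with logical matrices \code{breastMask} and
#'   \code{nippleMask}; the nipple is always inside the breast.
#' @examples
#' dom <- makeBreastDomain(100, 100, nippleRadius = 6)
#' sum(dom$nippleMask)  # ~ pi * 6^2
#' @export
makeBreastDomain <- function(height, width,
                             nippleCenter = NULL, nippleRadius = 8) {
  stopifnot(height >= 4, width >= 4, nippleRadius >= 0)
  cr <- (height + 1) / 2; cc <- (width + 1) / 2
  a <- height / 2 - 1; b <- width / 2 - 1
  r <- matrix(seq_len(height), height, width)
  c0 <- matrix(seq_len(width), height, width, byrow = TRUE)
  breast <- ((r - cr) / a)^2 + ((c0 - cc) / b)^2 <= 1
  if (is.null(nippleCenter)) {
    nippleCenter <- c(round(mean(r[breast])), round(mean(c0[breast])))
  }
  nr <- nippleCenter[1]; nc <- nippleCenter[2]
  if (nr < 1 || nr > height || nc < 1 || nc > width || !breast[nr, nc])
    stop("nippleCenter must lie inside the breast mask")
  nipple <- if (nippleRadius == 0) matrix(FALSE, height, width) else
    ((r - nr)^2 + (c0 - nc)^2 <= nippleRadius^2) & breast
  if (nippleRadius > 0 && any(nipple & !breast))
    stop("nipple disc must fit inside the breast mask")
  list(breastMask = breast, nippleMask = nipple)
}

#' Partition the breast ROI into perfusion territories
#'
#' Draws \code{n} seed pixels uniformly from the breast ROI and labels
#' every breast pixel with its nearest seed (Euclidean, ties broken by
#' lowest territory id) - a Voronoi partition emulating perforator
#' territories. Deterministic given \code{seed}.
#'
#' @param breastMask logical matrix, the breast ROI.
#' @param n number of territories, >= 1 and <= number of breast pixels.
#' @param seed integer RNG seed.
#' @param dropoutIds integer vector of territories whose perfusion is
#'   suppressed (subset of 1..n).
#' @param dropoutFactor plateau multiplier in dropout territories, in
#'   [0, 1].
#' @return a [TerritoryModel-class].
#' @export
makeTerritories <- function(breastMask, n, seed = 1L,
                            dropoutIds = integer(0), dropoutFactor = 0) {
  stopifnot(is.logical(breastMask), n >= 1)
  npx <- sum(breastMask)
  if (n > npx) stop("more territories requested than breast pixels")
  idx <- which(breastMask)
  set.seed(as.integer(seed))
  seedIdx <- sort(sample(idx, n))
  h <- nrow(breastMask)
  sr <- ((seedIdx - 1L) %% h) + 1L
  sc <- ((seedIdx - 1L) %/% h) + 1L
  pr <- ((idx - 1L) %% h) + 1L
  pc <- ((idx - 1L) %/% h) + 1L
  # n x npx squared distances; nearest seed wins, ties -> lowest id
  d2 <- outer(sr, pr, function(a, b) (a - b)^2) +
        outer(sc, pc, function(a, b) (a - b)^2)
  lab <- apply(d2, 2, which.min)
  labels <- matrix(0L, nrow(breastMask), ncol(breastMask))
  labels[idx] <- as.integer(lab)
  new("TerritoryModel", labels = labels,
      seedPoints = cbind(row = sr, col = sc),
      dropoutIds = as.integer(dropoutIds), dropoutFactor = dropoutFactor)
}

#' Choose dropout territories approximating a target area fraction
#'
#' Selects the subset of territories whose total pixel count (nipple
#' pixels not counted) is closest to \code{targetPercent} of the breast
#' ROI, by exact subset-sum dynamic programming over the territory
#' sizes. Useful for constructing cases with a prescribed ground-truth
#' area ratio: the achieved fraction is within one territory-size
#' rounding of the target whenever the sizes permit.
#'
#' @param territories a [TerritoryModel-class].
#' @param targetPercent desired 100 * |dropout minus nipple| / |breast|.
#' @param nippleMask logical matrix (excluded from the numerator), or
#'   NULL.
#' @param minSizePx territories contributing fewer pixels than this are
#'   never selected (default 25, the segmentation speckle floor):
#'   perforator-territory dropout is anatomically sizable, and ground
#'   truth built from such fragments would be indistinguishable from
#'   sensor speckle.
#' @return integer vector of territory ids.
#' @export
chooseDropoutIds <- function(territories, targetPercent,
                             nippleMask = NULL, minSizePx = 25) {
  lab <- territories@labels
  nBreast <- sum(lab > 0L)
  eff <- lab
  if (!is.null(nippleMask)) eff[nippleMask] <- 0L
  sizes <- tabulate(eff[eff > 0L], nbins = nrow(territories@seedPoints))
  cand <- which(sizes >= minSizePx)
  target <- round(targetPercent / 100 * nBreast)
  if (target <= 0 || !length(cand)) return(integer(0))
  total <- sum(sizes[cand])
  # reachable subset sums, one row per candidate, for backtracking
  reach <- matrix(FALSE, length(cand) + 1L, total + 1L)
  reach[1L, 1L] <- TRUE                       # sum 0 at offset 1
  for (i in seq_along(cand)) {
    s <- sizes[cand[i]]
    reach[i + 1L, ] <- reach[i, ]
    reach[i + 1L, (s + 1L):(total + 1L)] <-
      reach[i + 1L, (s + 1L):(total + 1L)] | reach[i, 1L:(total + 1L - s)]
  }
  best <- which(reach[length(cand) + 1L, ]) - 1L
  acc <- best[which.min(abs(best - target))]
  chosen <- integer(0)
  for (i in rev(seq_along(cand))) {          # standard DP backtrack
    if (reach[i, acc + 1L]) next             # achievable without item i
    s <- sizes[cand[i]]
    chosen <- c(chosen, cand[i]); acc <- acc - s
  }
  stopifnot(acc == 0L)
  sort(chosen)
}

#' Simulate an ICG-A recording over a territory model
#'
#' Every pixel follows the kinetic-profile curve scaled by its territory
#' factor (\code{dropoutFactor} in dropout territories, 1 elsewhere);
#' pixels outside the breast ROI sit at a constant background of 1\% of
#' the plateau level. Zero-mean Gaussian sensor noise (SD
#' \code{noiseSd}) is added to every pixel of every frame and the result
#' clamped at 0 (intensities are nonnegative counts). RNG stream: a
#' single \code{set.seed(seed)}, then one \code{rnorm} block per frame in
#' temporal order.
#'
#' @param domain list with \code{breastMask} and \code{nippleMask} (as
#'   from [makeBreastDomain()]).
#' @param territories a [TerritoryModel-class] over the same breast mask.
#' @param profile a [KineticProfile-class].
#' @param frameTimes strictly increasing frame times in seconds; default
#'   one frame every 2 s over 0..180 s (a 3-minute recording).
#' @param noiseSd sensor noise SD in intensity units, >= 0.
#' @param seed integer RNG seed.
#' @return a [SyntheticCase-class]. Ground truth: \code{truthHypoMask} is
#'   the union of dropout territories with nipple pixels removed (the
#'   nipple is never counted hypoperfused downstream), and
#'   \code{truthAreaFraction} uses the full breast ROI as denominator.
#' @examples
#' dom <- makeBreastDomain(80, 80)
#' terr <- makeTerritories(dom$breastMask, 5, seed = 3,
#'                         dropoutIds = c(1L, 4L), dropoutFactor = 0.15)
#' case <- simulateRecording(dom, terr, KineticProfile(), noiseSd = 0)
#' truthAreaFraction(case)
#' @export
simulateRecording <- function(domain, territories, profile,
                              frameTimes = seq(0, 180, by = 2),
                              noiseSd = 0, seed = 1L) {
  breast <- domain$breastMask; nipple <- domain$nippleMask
  stopifnot(is.logical(breast), is.logical(nipple))
  if (length(frameTimes) < 1L) stop("frameTimes must be nonempty")
  if (any(diff(frameTimes) <= 0))
    stop("frameTimes must be strictly increasing")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (!identical(dim(territories@labels), dim(breast)))
    stop("territory labels and breast mask dimensions differ")

  h <- nrow(breast); w <- ncol(breast); nT <- length(frameTimes)
  factor <- matrix(1, h, w)
  drop <- territories@labels > 0L &
          territories@labels %in% territories@dropoutIds
  factor[drop] <- territories@dropoutFactor
  curve <- kineticCurve(profile, frameTimes)
  background <- 0.01 * profile@plateauLevel

  set.seed(as.integer(seed))
  arr <- array(0, c(h, w, nT))
  for (k in seq_len(nT)) {
    frame <- matrix(background, h, w)
    frame[breast] <- curve[k] * factor[breast]
    if (noiseSd > 0)
      frame <- frame + matrix(stats::rnorm(h * w, 0, noiseSd), h, w)
    arr[, , k] <- pmax(frame, 0)
  }

  truth <- drop & !nipple
  new("SyntheticCase",
      frames = FrameSequence(arr, frameTimes,
                             metadata = list(simulated = TRUE,
                                             icg_dose = "4 mL at 2.5 mg/mL",
                                             noise_sd = noiseSd)),
      breastMask = breast, nippleMask = nipple, truthHypoMask = truth,
      truthAreaFraction = 100 * sum(truth) / sum(breast),
      territories = territories, seed = as.integer(seed))
}

#' Simulate a diagnostic cohort with known operating characteristics
#'
#' One row per breast. Necrosis is Bernoulli(\code{prevalence}); the
#' binary predictor (hypoperfused flap) is drawn with
#' P(+ | necrosis) = \code{sens} and P(- | no necrosis) = \code{spec}.
#' Covariates (age, BMI, mastectomy and reconstruction type) are drawn
#' independently of the outcome so that group comparisons are null;
#' predictor-positive rows receive a log-normal hypoperfused-area percent
#' ratio, others 0. RNG stream (single \code{set.seed(seed)}): necrosis
#' uniforms, predictor uniforms, age, BMI, mastectomy type,
#' reconstruction type, area ratios.
#'
#' @param n cohort size, > 0.
#' @param prevalence,sens,spec probabilities in [0, 1].
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{case_id},
#'   \code{predictor_positive}, \code{necrosis}, \code{age}, \code{bmi},
#'   \code{mastectomy_type} (SSM/NSM), \code{reconstruction_type}
#'   (TE/DTI), \code{area_percent_ratio}.
#' @examples
#' coh <- simulateCohort(200, prevalence = 0.15, sens = 1, spec = 0.978,
#'                       seed = 7)
#' buildConfusion(coh)
#' @export
simulateCohort <- function(n, prevalence, sens, spec, seed = 1L) {
  if (n <= 0) stop("cohort size n must be > 0")
  p <- c(prevalence, sens, spec)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("prevalence, sens and spec must lie in [0, 1]")
  set.seed(as.integer(seed))
  necrosis <- stats::runif(n) < prevalence
  u <- stats::runif(n)
  predictor <- ifelse(necrosis, u < sens, u < 1 - spec)
  age <- pmax(19, round(stats::rnorm(n, 46, 8.5)))
  bmi <- round(pmin(45, pmax(16, stats::rnorm(n, 23.2, 3.9))), 2)
  mast <- sample(c("SSM", "NSM"), n, replace = TRUE, prob = c(34, 19))
  recon <- sample(c("TE", "DTI"), n, replace = TRUE, prob = c(23, 30))
  ratio <- numeric(n)
  if (any(predictor))
    ratio[predictor] <- round(pmin(100,
      stats::rlnorm(sum(predictor), meanlog = log(8), sdlog = 0.8)), 2)
  data.frame(case_id = sprintf("case_%04d", seq_len(n)),
             predictor_positive = predictor, necrosis = necrosis,
             age = age, bmi = bmi, mastectomy_type = mast,
             reconstruction_type = recon, area_percent_ratio = ratio,
             stringsAsFactors = FALSE)
}
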