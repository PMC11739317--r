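#' Write / read a frame stack as multi-page grayscale TIFF
#'
#' Frames are stored as a multi-page TIFF (16-bit by default). TIFF
#' samples live in [0, 1], so intensities are divided by the stack
#' maximum before writing; that scale factor is recorded in the
#' timestamp sidecar CSV (header \code{frame_index,time_s,scale}, scale
#' constant across rows) and restored on read. A sidecar without a
#' \code{scale} column is accepted (scale 1).
#'
#' @param seq a [FrameSequence-class].
#' @param path TIFF file path.
#' @param timesPath sidecar CSV path; default \code{<path>} with a
#'   \code{_times.csv} suffix.
#' @param bitsPerSample 16 (default) or 8; 16-bit keeps quantization
#'   error below 1/65535 of the stack maximum.
#' @return \code{writeFrames}: invisibly, the paths written.
#'   \code{readFrames}: a validated [FrameSequence-class].
#' @export
writeFrames <- function(seq, path, timesPath = defaultTimesPath(path),
                        bitsPerSample = 16) {
  stopifnot(is(seq, "FrameSequence"), bitsPerSample %in% c(8, 16))
  scale <- max(seq@frames)
  if (scale <= 0) scale <- 1
  d <- dim(seq@frames)
  pages <- lapply(seq_len(d[3]), function(k) seq@frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample)
  utils::write.csv(data.frame(frame_index = seq_len(d[3]) - 1L,
                              time_s = seq@times, scale = scale),
                   timesPath, row.names = FALSE)
  invisible(c(frames = path, times = timesPath))
}

defaultTimesPath <- function(path) sub("\\.tiff?$", "", path) |>
  paste0("_times.csv")

#' @rdname writeFrames
#' @export
readFrames <- function(path, timesPath = defaultTimesPath(path)) {
  if (!file.exists(path)) stop(sprintf("frame stack not found: %s", path))
  if (!file.exists(timesPath))
    stop(sprintf("timestamp sidecar not found: %s", timesPath))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  tm <- utils::read.csv(timesPath)
  for (f in c("frame_index", "time_s"))
    if (!f %in% names(tm))
      stop(sprintf("timestamp sidecar lacks column '%s'", f))
  if (nrow(tm) != length(pages))
    stop(sprintf("sidecar has %d rows but stack has %d pages",
                 nrow(tm), length(pages)))
  if (any(diff(tm$time_s) <= 0))
    stop("sidecar times are not strictly increasing")
  scale <- if ("scale" %in% names(tm)) tm$scale[1] else 1
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, c(h, w, length(pages)))
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # collapse gray-as-RGB
    arr[, , k] <- pg * scale
  }
  FrameSequence(arr, tm$time_s)
}

#' Write / read a binary mask as 8-bit PNG
#'
#' Masks are written 0/255; on read, any channel value above 0.5 is
#' foreground.
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return \code{readMask}: a logical matrix.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.logical(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask not found: %s", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

cohortSchema <- list(
  case_id = "character", predictor_positive = "boolean",
  necrosis = "boolean", age = "numeric", bmi = "numeric",
  mastectomy_type = c("SSM", "NSM"), reconstruction_type = c("TE", "DTI"),
  area_percent_ratio = "numeric")

#' Write / read a cohort CSV
#'
#' Fixed documented header: \code{case_id, predictor_positive, necrosis,
#' age, bmi, mastectomy_type, reconstruction_type, area_percent_ratio}.
#' \code{readCohort} validates strictly: boolean columns must be
#' TRUE/FALSE-codable, \code{mastectomy_type} must be SSM or NSM,
#' \code{reconstruction_type} TE or DTI; errors name the field and rows.
#' Extra columns are passed through untouched.
#'
#' @param cohort data.frame in the schema above (e.g. from
#'   [simulateCohort()]).
#' @param path CSV file path.
#' @return \code{readCohort}: the validated data.frame with boolean
#'   columns as logical.
#' @export
writeCohort <- function(cohort, path) {
  need <- names(cohortSchema)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop(sprintf("cohort lacks column(s): %s", paste(miss, collapse = ", ")))
  utils::write.csv(cohort[, union(need, names(cohort))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("cohort CSV not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (f in names(cohortSchema)) {
    if (!f %in% names(df))
      stop(sprintf("cohort CSV lacks column '%s'", f))
    kind <- cohortSchema[[f]]
    if (identical(kind, "boolean")) {
      df[[f]] <- codeBoolean(df[[f]], f)
    } else if (identical(kind, "numeric")) {
      if (!is.numeric(df[[f]]))
        stop(sprintf("column '%s' must be numeric", f))
    } else if (length(kind) > 1) {
      bad <- which(!df[[f]] %in% kind)
      if (length(bad))
        stop(sprintf("column '%s' has invalid value(s) in row(s) %s (allowed: %s)",
                     f, paste(utils::head(bad, 10), collapse = ", "),
                     paste(kind, collapse = "/")))
    }
  }
  df
}

#' Write a flap assessment report as JSON
#'
#' Serializes all flags, the area ratio and the parameters used (plus the
#' package version) so that a run can be audited and re-rendered. The
#' report round-trips through [readAssessmentReport()].
#'
#' @param assessment a [FlapAssessment-class].
#' @param path JSON file path.
#' @param extra optional named list merged into the report (e.g. seed,
#'   input paths).
#' @return \code{readAssessmentReport}: the report as a named list.
#' @export
writeAssessmentReport <- function(assessment, path, extra = list()) {
  stopifnot(is(assessment, "FlapAssessment"))
  rep <- c(list(
    is_hypoperfused_flap = assessment@isHypoperfusedFlap,
    area_percent_ratio = assessment@areaPercentRatio,
    decision_flag = assessment@decisionFlag,
    eligibility_excluded = assessment@eligibilityExcluded,
    hypo_pixels = sum(assessment@hypoMask),
    parameters = list(cutoff = assessment@cutoff,
                      decision_threshold = assessment@decisionThreshold,
                      eligibility_threshold = assessment@eligibilityThreshold,
                      min_component_px = assessment@minComponentPx),
    version = as.character(utils::packageVersion("icgaFlap"))),
    extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeAssessmentReport
#' @export
readAssessmentReport <- function(path) {
  if (!file.exists(path)) stop(sprintf("report not found: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a synthetic case to a directory
#'
#' Writes \code{frames.tif} + \code{frames_times.csv}, the breast,
#' nipple and ground-truth masks as PNG, and a \code{truth.json} sidecar
#' with the ground-truth area fraction, seed and dropout parameters.
#'
#' @param case a [SyntheticCase-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCase <- function(case, dir) {
  stopifnot(is(case, "SyntheticCase"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFrames(case@frames, file.path(dir, "frames.tif"))
  writeMask(case@breastMask, file.path(dir, "breast_mask.png"))
  writeMask(case@nippleMask, file.path(dir, "nipple_mask.png"))
  writeMask(case@truthHypoMask, file.path(dir, "truth_hypo_mask.png"))
  jsonlite::write_json(list(
    truth_area_fraction = case@truthAreaFraction,
    rng_seed = case@seed,
    n_territories = nrow(case@territories@seedPoints),
    dropout_ids = case@territories@dropoutIds,
    dropout_factor = case@territories@dropoutFactor),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
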