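#' Construct a run configuration
#'
#' All tunable thresholds of the pipeline with their clinical defaults:
#' RPU hypoperfusion cutoff 30\%, decision threshold 15\%, eligibility
#' limit one-third, normalizer percentile 100 (the brightest in-flap
#' point), speckle floor 25 px, plateau boundary fractions 0.95/0.90,
#' median plateau aggregation.
#'
#' @param cutoff,decisionThreshold,eligibilityThreshold,percentile
#'   percent-scale thresholds; see [RunConfig-class].
#' @param minComponentPx,riseFraction,fallFraction,aggregator,seed see
#'   [RunConfig-class].
#' @return a validated [RunConfig-class].
#' @examples
#' runConfig(percentile = 99)
#' @export
runConfig <- function(cutoff = 30, decisionThreshold = 15,
                      eligibilityThreshold = 100 / 3, percentile = 100,
                      minComponentPx = 25, riseFraction = 0.95,
                      fallFraction = 0.90,
                      aggregator = c("median", "mean"), seed = 1L) {
  new("RunConfig", cutoff = cutoff, decisionThreshold = decisionThreshold,
      eligibilityThreshold = eligibilityThreshold, percentile = percentile,
      minComponentPx = minComponentPx, riseFraction = riseFraction,
      fallFraction = fallFraction, aggregator = match.arg(aggregator),
      seed = as.integer(seed),
      version = as.character(utils::packageVersion("icgaFlap")))
}

configFields <- c("cutoff", "decisionThreshold", "eligibilityThreshold",
                  "percentile", "minComponentPx", "riseFraction",
                  "fallFraction", "aggregator", "seed", "version")

#' Serialize / deserialize a run configuration (YAML)
#'
#' Configurations round-trip exactly: \code{readRunConfig(writeRunConfig(x))}
#' is identical to \code{x}.
#'
#' @param config a [RunConfig-class].
#' @param path YAML file path.
#' @param overrides named list applied on top of the file's values
#'   (command-line precedence: overrides > file > defaults).
#' @return \code{readRunConfig}: a validated [RunConfig-class].
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  vals <- lapply(configFields, function(f) slot(config, f))
  names(vals) <- configFields
  yaml::write_yaml(vals, path, precision = 17)  # exact double round-trip
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(overrides), configFields)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")))
  vals[names(overrides)] <- overrides
  cfg <- runConfig()
  for (f in setdiff(configFields, "version"))
    if (!is.null(vals[[f]]))
      slot(cfg, f) <- if (f == "seed") as.integer(vals[[f]]) else vals[[f]]
  validObject(cfg)
  cfg
}
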