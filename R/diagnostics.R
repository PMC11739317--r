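#' Construct a ConfusionTable from counts
#'
#' @param tp,fp,fn,tn nonnegative integer counts; total >= 1.
#' @return a [ConfusionTable-class].
#' @examples
#' ConfusionTable(tp = 8, fp = 1, fn = 0, tn = 44)
#' @export
ConfusionTable <- function(tp, fp, fn, tn) {
  new("ConfusionTable", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

# coerce a cohort column to logical; error names the offending rows
codeBoolean <- function(x, field) {
  out <- if (is.logical(x)) x
    else if (is.numeric(x) && all(x %in% c(0, 1, NA))) x == 1
    else if (is.character(x)) {
      lo <- tolower(trimws(x))
      ifelse(lo %in% c("true", "t", "yes", "1", "+"), TRUE,
             ifelse(lo %in% c("false", "f", "no", "0", "-"), FALSE, NA))
    } else rep(NA, length(x))
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("field '%s' has missing/uncodable values in row(s) %s",
                 field, paste(utils::head(bad, 10), collapse = ", ")))
  out
}

#' Cross-tabulate a binary predictor against a binary outcome
#'
#' @param cohort data.frame, one row per breast (e.g. from
#'   [simulateCohort()] or [readCohort()]).
#' @param predictorField,outcomeField names of boolean-coded columns
#'   (logical, 0/1, or TRUE/FALSE-like strings).
#' @return a [ConfusionTable-class]; counts sum to \code{nrow(cohort)}.
#' @export
buildConfusion <- function(cohort, predictorField = "predictor_positive",
                           outcomeField = "necrosis") {
  for (f in c(predictorField, outcomeField))
    if (!f %in% names(cohort)) stop(sprintf("no column '%s' in cohort", f))
  pred <- codeBoolean(cohort[[predictorField]], predictorField)
  out <- codeBoolean(cohort[[outcomeField]], outcomeField)
  ConfusionTable(tp = sum(pred & out), fp = sum(pred & !out),
                 fn = sum(!pred & out), tn = sum(!pred & !out))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Closed-form beta-quantile interval: lower = qbeta(alpha/2; x, n-x+1)
#' (0 when x = 0), upper = qbeta(1-alpha/2; x+1, n-x) (1 when x = n).
#' Vectorized over \code{x} and \code{n}. Agrees with
#' \code{binom.test()$conf.int}.
#'
#' @param x number of successes.
#' @param n number of trials, >= x.
#' @param level confidence level (default 0.95).
#' @return matrix with columns \code{lower}, \code{upper}.
#' @export
clopperPearsonCI <- function(x, n, level = 0.95) {
  stopifnot(all(x >= 0), all(n >= x), level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  upper <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lower = lower, upper = upper)
}

#' Diagnostic accuracy metrics with exact confidence intervals
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and
#' NPV tn/(tn+fn), each with an exact Clopper-Pearson interval. A metric
#' with a zero denominator is reported as \code{NA} with a warning.
#'
#' @param table a [ConfusionTable-class].
#' @param level confidence level (default 0.95).
#' @return a [DiagnosticSummary-class].
#' @examples
#' diagnosticMetrics(ConfusionTable(8, 1, 0, 44))
#' @export
diagnosticMetrics <- function(table, level = 0.95) {
  stopifnot(is(table, "ConfusionTable"))
  k <- counts(table)
  x <- c(sensitivity = k[["tp"]], specificity = k[["tn"]],
         ppv = k[["tp"]], npv = k[["tn"]])
  n <- c(sensitivity = k[["tp"]] + k[["fn"]],
         specificity = k[["tn"]] + k[["fp"]],
         ppv = k[["tp"]] + k[["fp"]],
         npv = k[["tn"]] + k[["fn"]])
  est <- ifelse(n > 0, x / n, NA_real_)
  if (any(n == 0))
    warning(sprintf("zero denominator, metric(s) undefined: %s",
                    paste(names(n)[n == 0], collapse = ", ")))
  ci <- matrix(NA_real_, 4, 2, dimnames = list(NULL, c("lower", "upper")))
  ok <- n > 0
  if (any(ok)) ci[ok, ] <- clopperPearsonCI(x[ok], n[ok], level)
  new("DiagnosticSummary",
      metrics = data.frame(metric = names(n), estimate = unname(est),
                           lower = ci[, "lower"], upper = ci[, "upper"],
                           x = unname(x), n = unname(n),
                           stringsAsFactors = FALSE),
      prevalence = (k[["tp"]] + k[["fn"]]) / sum(k),
      level = level, table = table)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass two-sided convention: with margins fixed, the p-value
#' sums the hypergeometric probabilities of every table whose probability
#' does not exceed the observed table's (up to a 1e-7 relative tolerance
#' for floating-point ties), clipped to [0, 1].
#'
#' @param table a [ConfusionTable-class] or a 2x2 numeric matrix.
#' @return the two-sided p-value.
#' @examples
#' fisherExactTwoSided(ConfusionTable(8, 1, 0, 44))   # < 0.001
#' @export
fisherExactTwoSided <- function(table) {
  m <- if (is(table, "ConfusionTable")) {
    k <- counts(table)
    matrix(k[c("tp", "fn", "fp", "tn")], 2, 2)
  } else {
    stopifnot(is.matrix(table), all(dim(table) == 2))
    table
  }
  if (sum(m) < 1) stop("table total must be >= 1")
  min(1, stats::fisher.test(m, alternative = "two.sided")$p.value)
}

#' Two-sample t test from summary statistics
#'
#' Two-sided t test computed from group means, SDs and sizes (as printed
#' in a demographics table), without raw data. The pooled variant is the
#' classical Student's t; Welch uses the Satterthwaite approximation.
#'
#' @param mean1,sd1,n1 summary statistics of group 1 (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{variant}. Degenerate input (both SDs zero): p = 1 if the means
#'   are equal, else p = 0 with a warning.
#' @examples
#' summaryTTest(45.2, 8.4, 45, 50.4, 7.3, 8)$p.value   # ~ 0.107
#' @export
summaryTTest <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2)
      return(list(statistic = 0, df = n1 + n2 - 2, p.value = 1,
                  variant = variant))
    warning("both SDs are zero with unequal means; p = 0")
    return(list(statistic = Inf, df = n1 + n2 - 2, p.value = 0,
                variant = variant))
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
       variant = variant)
}

#' Format a p-value in report style
#'
#' Three decimals, with values below 0.001 rendered as \code{"<0.001"}.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
formatPValue <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Group-comparison report for a cohort
#'
#' Demographics-table style report: for each continuous variable, group
#' means/SDs and a Student's t test (from the computed summaries); for
#' each categorical variable, per-group counts and a Fisher exact test.
#' With a single group (or \code{group = NULL}) only descriptive rows are
#' produced. Row order follows the order of \code{continuous} then
#' \code{categorical}.
#'
#' @param cohort data.frame, one row per case.
#' @param group name of the boolean-coded grouping column (default
#'   \code{"necrosis"}), or NULL for a descriptive-only report.
#' @param continuous,categorical character vectors of column names.
#' @return data.frame with columns \code{variable}, \code{type},
#'   \code{test}, \code{group1}, \code{group2}, \code{p_value},
#'   \code{p_formatted}.
#' @export
cohortReport <- function(cohort, group = "necrosis",
                         continuous = c("age", "bmi"),
                         categorical = c("mastectomy_type",
                                         "reconstruction_type")) {
  for (f in c(group, continuous, categorical))
    if (!f %in% names(cohort)) stop(sprintf("unknown variable '%s'", f))
  g <- if (is.null(group)) rep(FALSE, nrow(cohort))
       else codeBoolean(cohort[[group]], group)
  twoGroups <- length(unique(g)) == 2L
  rows <- list()
  descCont <- function(x)
    sprintf("%.1f +/- %.1f (n=%d)", mean(x), stats::sd(x), length(x))
  descCat <- function(x) {
    tb <- table(x)
    paste(sprintf("%s:%d", names(tb), tb), collapse = " ")
  }
  for (v in continuous) {
    x0 <- cohort[[v]][!g]; x1 <- cohort[[v]][g]
    p <- NA_real_
    if (twoGroups && length(x0) >= 2 && length(x1) >= 2)
      p <- summaryTTest(mean(x0), stats::sd(x0), length(x0),
                        mean(x1), stats::sd(x1), length(x1))$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous", test = "student_t",
      group1 = descCont(x0),
      group2 = if (twoGroups) descCont(x1) else NA_character_,
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    x <- as.factor(cohort[[v]])
    p <- NA_real_
    if (twoGroups && nlevels(x) >= 2) {
      tb <- table(x, g)
      p <- stats::fisher.test(tb)$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical", test = "fisher_exact",
      group1 = descCat(cohort[[v]][!g]),
      group2 = if (twoGroups) descCat(cohort[[v]][g]) else NA_character_,
      p_value = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_formatted <- ifelse(is.na(out$p_value), NA_character_,
                            formatPValue(out$p_value))
  out
}
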