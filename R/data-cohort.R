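#' Bundled 53-breast reference cohort
#'
#' A deterministic reference cohort of 53 breasts (one row each) used in
#' examples, the acceptance script and regression tests. Its
#' cross-tabulation of the hypoperfused-flap read against skin-flap
#' necrosis is tp = 8, fp = 1, fn = 0, tn = 44; the nine
#' predictor-positive rows carry the individually recorded
#' hypoperfused-area percent ratios, necrosis depth (full / partial /
#' none) and treatment (debridement and revision in the two
#' full-thickness cases, secondary healing in the six partial-thickness
#' cases, none for the single false positive). Group margins by
#' mastectomy type (SSM/NSM) and reconstruction type (TE/DTI) match the
#' cohort totals 34/19 and 23/30. Ages and BMIs of the
#' predictor-negative rows are deterministic normal quantiles matched to
#' the non-necrosis group summaries (mean age 45.2, SD 8.4; mean BMI
#' 23.2, SD 4.0), so the cohort carries no RNG state.
#'
#' @return data.frame in the [readCohort()] schema plus columns
#'   \code{smoking}, \code{neoadjuvant_ctx}, \code{necrosis_type}
#'   (\code{full}/\code{partial}/\code{none}) and \code{treatment}.
#' @examples
#' coh <- referenceCohort()
#' buildConfusion(coh)
#' @export
referenceCohort <- function() {
  pos <- data.frame(
    age = c(52, 53, 55, 50, 42, 42, 40, 48, 63),
    bmi = c(24.57, 23.79, 24.79, 20.31, 28.48, 19.76, 18.37, 22.28, 20.63),
    smoking = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    neoadjuvant_ctx = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                        FALSE, FALSE),
    mastectomy_type = c("NSM", "NSM", "SSM", "NSM", "SSM", "NSM", "NSM",
                        "NSM", "NSM"),
    reconstruction_type = rep("DTI", 9),
    area_percent_ratio = c(27.71, 16.02, 17.94, 4.82, 1.99, 2.28, 10.16,
                           6.55, 3.94),
    necrosis_type = c("full", "partial", "full", "partial", "partial",
                      "none", "partial", "partial", "partial"),
    treatment = c("debridement_revision", "secondary_healing",
                  "debridement_revision", "secondary_healing",
                  "secondary_healing", "none", "secondary_healing",
                  "secondary_healing", "secondary_healing"),
    stringsAsFactors = FALSE)
  pos <- cbind(predictor_positive = TRUE,
               necrosis = pos$necrosis_type != "none", pos)

  # 44 predictor-negative, necrosis-free rows; margins SSM 32 / NSM 12
  # and TE 23 / DTI 21 complete the cohort totals (34/19, 23/30).
  nNeg <- 44L
  q <- stats::qnorm(stats::ppoints(nNeg))
  neg <- data.frame(
    predictor_positive = FALSE, necrosis = FALSE,
    age = pmin(66, pmax(30, round(45.27 + 8.66 * q))),
    bmi = pmin(36.3, pmax(17.6, round(23.28 + 4.12 * q[order(q %% 1)], 2))),
    smoking = rep(c(TRUE, FALSE), c(3L, nNeg - 3L)),
    neoadjuvant_ctx = rep(c(FALSE, TRUE, FALSE), c(5L, 13L, nNeg - 18L)),
    mastectomy_type = rep(c("SSM", "NSM"), c(32L, 12L)),
    reconstruction_type = rep(c("TE", "DTI", "TE", "DTI"),
                              c(22L, 10L, 1L, 11L)),
    area_percent_ratio = 0,
    necrosis_type = "none", treatment = "none",
    stringsAsFactors = FALSE)

  coh <- rbind(pos, neg)
  cbind(case_id = sprintf("ref_%02d", seq_len(nrow(coh))), coh,
        stringsAsFactors = FALSE)
}
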