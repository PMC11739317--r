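test_that("confusion tables from cohort rows", {
  coh <- referenceCohort()
  ct <- buildConfusion(coh)
  expect_equal(unname(counts(ct)), c(8L, 1L, 0L, 44L))
  expect_equal(sum(counts(ct)), nrow(coh))

  # all-negative predictor
  coh2 <- coh; coh2$predictor_positive <- FALSE
  ct2 <- buildConfusion(coh2)
  expect_equal(unname(counts(ct2)[c("tp", "fp")]), c(0L, 0L))

  # string and 0/1 coding accepted; uncodable values are named
  coh3 <- coh
  coh3$necrosis <- ifelse(coh$necrosis, "yes", "no")
  coh3$predictor_positive <- as.numeric(coh$predictor_positive)
  expect_equal(counts(buildConfusion(coh3)), counts(ct))
  coh3$necrosis[4] <- "maybe"
  expect_error(buildConfusion(coh3), "row\\(s\\) 4")
  expect_error(buildConfusion(coh, predictorField = "nope"), "no column")
})

test_that("diagnostic metrics equal the direct ratio formulas with exact CIs", {
  # random tables vs brute-force formulas
  set.seed(1)
  for (i in 1:25) {
    k <- as.integer(rpois(4, c(8, 3, 2, 30)) + c(1, 0, 0, 1))
    ds <- diagnosticMetrics(ConfusionTable(k[1], k[2], k[3], k[4]))
    m <- metrics(ds)
    expect_equal(m$estimate[m$metric == "sensitivity"], k[1] / (k[1] + k[3]))
    expect_equal(m$estimate[m$metric == "specificity"], k[4] / (k[4] + k[2]))
    expect_equal(m$estimate[m$metric == "ppv"], k[1] / (k[1] + k[2]))
    expect_equal(m$estimate[m$metric == "npv"], k[4] / (k[4] + k[3]))
    # each estimate inside its interval
    expect_true(all(m$estimate >= m$lower & m$estimate <= m$upper))
  }

  # degenerate table: sensitivity and PPV undefined, reported missing
  expect_warning(ds0 <- diagnosticMetrics(ConfusionTable(0, 0, 0, 12)),
                 "sensitivity, ppv")
  m0 <- metrics(ds0)
  expect_true(all(is.na(m0$estimate[m0$metric %in% c("sensitivity", "ppv")])))
  expect_equal(m0$estimate[m0$metric %in% c("specificity", "npv")], c(1, 1))
})

test_that("Clopper-Pearson intervals agree with binom.test", {
  for (xn in list(c(8, 8), c(44, 45), c(8, 9), c(0, 12), c(12, 12),
                  c(3, 10))) {
    ci <- clopperPearsonCI(xn[1], xn[2])
    bt <- stats::binom.test(xn[1], xn[2])$conf.int
    expect_equal(unname(ci[1, ]), as.numeric(bt), tolerance = 1e-10)
  }
})

test_that("two-sided Fisher p equals full margin-fixed enumeration", {
  set.seed(99)
  for (i in 1:60) {
    k <- as.integer(sample(0:12, 4, replace = TRUE))
    if (sum(k) == 0) k[1] <- 1L
    p <- fisherExactTwoSided(ConfusionTable(k[1], k[2], k[3], k[4]))
    expect_equal(p, min(1, fisherEnumOracle(k[1], k[2], k[3], k[4])),
                 tolerance = 1e-10)
  }
  # symmetric table
  expect_equal(fisherExactTwoSided(ConfusionTable(1, 1, 1, 1)), 1)
})

test_that("Fisher p is invariant under transposition and row/column swaps", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(as.integer(sample(0:15, 4, replace = TRUE) + 1), 2, 2)
    p <- fisherExactTwoSided(m)
    expect_equal(fisherExactTwoSided(t(m)), p)
    expect_equal(fisherExactTwoSided(m[2:1, 2:1]), p)
  }
})

test_that("summary t test matches t.test on raw data and handles degenerate SDs", {
  set.seed(12)
  for (i in 1:15) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, .5, 3))
    out <- summaryTTest(mean(x), sd(x), length(x),
                        mean(y), sd(y), length(y))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(out$p.value, ref$p.value, tolerance = 1e-12)
    outW <- summaryTTest(mean(x), sd(x), length(x),
                         mean(y), sd(y), length(y), variant = "welch")
    refW <- stats::t.test(x, y)
    expect_equal(outW$p.value, refW$p.value, tolerance = 1e-12)
  }
  expect_equal(summaryTTest(3, 0, 5, 3, 0, 9)$p.value, 1)
  expect_warning(p0 <- summaryTTest(3, 0, 5, 4, 0, 9)$p.value, "p = 0")
  expect_equal(p0, 0)
  expect_equal(summaryTTest(5, 1, 10, 5, 1, 10)$p.value, 1)
})

test_that("cohort report renders the demographic comparisons deterministically", {
  rep <- cohortReport(referenceCohort(), group = "necrosis",
                      continuous = c("age", "bmi"),
                      categorical = c("smoking", "mastectomy_type",
                                      "reconstruction_type"))
  expect_equal(rep$variable, c("age", "bmi", "smoking", "mastectomy_type",
                               "reconstruction_type"))
  expect_equal(rep$test, c("student_t", "student_t", "fisher_exact",
                           "fisher_exact", "fisher_exact"))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  # categorical comparisons are count-exact, so the printed cohort's
  # Fisher p-values reproduce to 3 decimals
  expect_equal(rep$p_formatted[rep$variable == "mastectomy_type"], "0.019")
  expect_equal(rep$p_formatted[rep$variable == "reconstruction_type"],
               "0.007")
  expect_equal(rep$p_formatted[rep$variable == "smoking"], "0.159")

  # single-group cohort: descriptive only
  one <- cohortReport(referenceCohort(), group = NULL)
  expect_true(all(is.na(one$p_value)))
  expect_error(cohortReport(referenceCohort(), continuous = "height"),
               "unknown variable")
})

test_that("null cohorts give uniform t-test p-values and conservative Fisher", {
  # 400 null replicates: covariates independent of outcome
  set.seed(202)
  pT <- pF <- numeric(400)
  for (i in 1:400) {
    coh <- simulateCohort(60, prevalence = 0.4, sens = 0.5, spec = 0.5,
                          seed = 10000 + i)
    rep <- cohortReport(coh, continuous = "bmi",
                        categorical = "mastectomy_type")
    pT[i] <- rep$p_value[1]
    pF[i] <- rep$p_value[2]
  }
  ks <- stats::ks.test(pT, "punif")
  expect_gt(ks$p.value, 0.01)
  # exact-test p-values are discrete and super-uniform under the null
  expect_lte(mean(pF <= 0.05), 0.07)
})

test_that("p-value formatting follows the report convention", {
  expect_equal(formatPValue(c(0.0004, 0.0011, 0.019, 0.5)),
               c("<0.001", "0.001", "0.019", "0.500"))
})
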