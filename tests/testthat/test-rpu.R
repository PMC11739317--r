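test_that("RPU normalization: arithmetic, identity and errors", {
  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  pm <- new("PerfusionMap", values = matrix(c(10, 50, 200, 7), 2, 2),
            sourceIndices = 1L, aggregator = "frame")
  rpu <- computeRPU(pm, roi)
  expect_equal(mapValues(rpu)[roi], c(5, 25, 100))
  expect_equal(rpu@normalizer, 200)
  expect_equal(mapValues(rpu)[!roi], 0)

  # uniform ROI: RPU 100 everywhere in ROI
  pmU <- new("PerfusionMap", values = matrix(3, 4, 4),
             sourceIndices = 1L, aggregator = "frame")
  expect_true(all(mapValues(computeRPU(pmU, matrix(TRUE, 4, 4))) == 100))

  pm0 <- new("PerfusionMap", values = matrix(0, 2, 2),
             sourceIndices = 1L, aggregator = "frame")
  expect_error(computeRPU(pm0, matrix(TRUE, 2, 2)), "no perfusion signal")
  expect_error(computeRPU(pm, matrix(FALSE, 2, 2)), "empty")
  expect_message(computeRPU(pm, roi, percentile = 99), "percentile 99")
})

test_that("noise-free dropout pixels read exactly 100 * dropoutFactor RPU", {
  case <- smallCase(dropoutFactor = 0.2)
  res <- assessRecording(case)
  rpu <- mapValues(res$rpu)
  expect_true(all(rpu[truthHypoMask(case)] == 20))
  inView <- breastMask(case) & !(territoryLabels(case@territories) %in% 1L)
  expect_true(all(rpu[inView] == 100))
})

test_that("hypoperfusion segmentation matches a per-pixel oracle with strict cutoff", {
  set.seed(42)
  vals <- matrix(runif(32 * 32, 0, 120), 32, 32)
  vals[5, 5] <- 120           # pin the max so clipping is exercised
  vals[7, 9] <- 36            # exactly the cutoff after normalization: 30.0
  breast <- matrix(TRUE, 32, 32)
  nipple <- matrix(FALSE, 32, 32); nipple[15:18, 15:18] <- TRUE
  rpu <- rpuFromMatrix(vals, breast)

  hypo <- segmentHypoperfused(rpu, nipple, cutoff = 30, minComponentPx = 1)
  # brute-force per-pixel scan, no morphology
  oracle <- matrix(FALSE, 32, 32)
  for (r in 1:32) for (cc in 1:32) {
    rpuVal <- 100 * min(vals[r, cc] / 120, 1)
    oracle[r, cc] <- !nipple[r, cc] && rpuVal < 30
  }
  expect_identical(hypo, oracle)
  # RPU exactly 30.0 is NOT hypoperfused (strict inequality)
  expect_equal(mapValues(rpu)[7, 9], 30)
  expect_false(hypo[7, 9])
  expect_false(any(hypo & nipple))
})

test_that("sub-cutoff perfusion confined to the nipple is not a hypoperfused flap", {
  vals <- matrix(100, 20, 20)
  nipple <- matrix(FALSE, 20, 20); nipple[9:12, 9:12] <- TRUE
  vals[nipple] <- 10           # nipple well below cutoff, flap fine
  rpu <- rpuFromMatrix(vals)
  a <- assessFlap(rpu, nipple, minComponentPx = 1)
  expect_false(isHypoperfused(a))
  expect_equal(areaRatio(a), 0)
  expect_equal(decisionFlag(a), "proceed")
  expect_false(eligibilityExcluded(a))
})

test_that("small-component cleanup is 8-connected and reproduces raw thresholding at 1 px", {
  # two diagonally-touching pixels must count as ONE component
  vals <- matrix(100, 12, 12)
  vals[3, 3] <- 5; vals[4, 4] <- 5
  rpu <- rpuFromMatrix(vals)
  nip <- matrix(FALSE, 12, 12)
  expect_equal(sum(segmentHypoperfused(rpu, nip, minComponentPx = 2)), 2)
  expect_equal(sum(segmentHypoperfused(rpu, nip, minComponentPx = 3)), 0)

  # labelComponents agrees with a brute-force 8-neighbour flood fill
  set.seed(7)
  m <- matrix(runif(400) < 0.4, 20, 20)
  lab <- icgaFlap:::labelComponents(m)
  expect_equal(lab > 0L, m)
  # neighbouring foreground pixels (incl. diagonals) share a label
  for (r in 1:19) for (cc in 1:19) {
    if (m[r, cc] && m[r + 1, cc + 1])
      expect_equal(lab[r, cc], lab[r + 1, cc + 1])
    if (m[r + 1, cc] && m[r, cc + 1])
      expect_equal(lab[r + 1, cc], lab[r, cc + 1])
    if (m[r, cc] && m[r, cc + 1]) expect_equal(lab[r, cc], lab[r, cc + 1])
    if (m[r, cc] && m[r + 1, cc]) expect_equal(lab[r, cc], lab[r + 1, cc])
  }
})

test_that("area percent ratio arithmetic and degenerate masks", {
  b <- matrix(TRUE, 100, 100)
  h <- matrix(FALSE, 100, 100); h[seq_len(655)] <- TRUE
  expect_equal(areaPercentRatio(h, b), 6.55)
  expect_equal(areaPercentRatio(matrix(FALSE, 100, 100), b), 0)
  expect_equal(areaPercentRatio(b, b), 100)
  expect_error(areaPercentRatio(h, matrix(FALSE, 100, 100)), "empty")
  expect_error(areaPercentRatio(matrix(TRUE, 2, 2),
                                matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)),
               "subset")
})

test_that("ratio is monotone in cutoff and in the component floor", {
  case <- smallCase(nTerr = 8, dropoutIds = c(2L, 5L), dropoutFactor = 0.25,
                    noiseSd = 3)
  res <- assessRecording(case)
  ratios <- vapply(c(10, 20, 30, 50, 80), function(k)
    areaPercentRatio(segmentHypoperfused(res$rpu, nippleMask(case),
                                         cutoff = k, minComponentPx = 1),
                     breastMask(case)), 0)
  expect_true(all(diff(ratios) >= 0))

  byFloor <- vapply(c(1, 9, 25, 100), function(mc)
    areaPercentRatio(segmentHypoperfused(res$rpu, nippleMask(case),
                                         minComponentPx = mc),
                     breastMask(case)), 0)
  expect_true(all(diff(byFloor) <= 0))
})

test_that("the whole assessment is invariant to intensity rescaling", {
  case <- smallCase(dropoutIds = c(1L, 2L), dropoutFactor = 0.22,
                    noiseSd = 2)
  res <- assessRecording(case)
  for (k in c(0.01, 7, 255)) {
    scaled <- FrameSequence(frames(case) * k, frameTimes(case))
    resK <- assessRecording(scaled, breastMask(case), nippleMask(case))
    expect_equal(mapValues(resK$rpu), mapValues(res$rpu))
    expect_identical(hypoMask(resK$assessment), hypoMask(res$assessment))
    expect_equal(areaRatio(resK$assessment), areaRatio(res$assessment))
  }
})

test_that("recovery: truth reproduced exactly at zero noise, within 1 pp at 5% noise", {
  dom <- makeBreastDomain(120, 120, nippleRadius = 6)
  for (target in c(0, 10, 25, 40)) {
    terr <- makeTerritories(dom$breastMask, 12, seed = 31)
    terr@dropoutIds <- chooseDropoutIds(terr, target, dom$nippleMask)
    terr@dropoutFactor <- 0.15
    case0 <- simulateRecording(dom, terr, KineticProfile(), noiseSd = 0,
                               seed = 7)
    res0 <- assessRecording(case0)
    expect_identical(hypoMask(res0$assessment), truthHypoMask(case0))
    expect_equal(areaRatio(res0$assessment), truthAreaFraction(case0))

    caseN <- simulateRecording(dom, terr, KineticProfile(), noiseSd = 5,
                               seed = 7)
    resN <- assessRecording(caseN)
    expect_lt(abs(areaRatio(resN$assessment) - truthAreaFraction(caseN)), 1)
  }
})

test_that("flap assessment flags fire at the documented thresholds", {
  vals <- matrix(100, 50, 50)
  nip <- matrix(FALSE, 50, 50)
  # 28% of pixels below cutoff -> hypoperfused, change-strategy, eligible
  vals[seq_len(700)] <- 10
  a <- assessFlap(rpuFromMatrix(vals), nip)
  expect_true(isHypoperfused(a))
  expect_equal(areaRatio(a), 28)
  expect_equal(decisionFlag(a), "change_strategy_or_close_followup")
  expect_false(eligibilityExcluded(a))

  # 6.5%: hypoperfused flap but proceed / monitor
  vals2 <- matrix(100, 40, 40); vals2[seq_len(104)] <- 10
  a2 <- assessFlap(rpuFromMatrix(vals2), matrix(FALSE, 40, 40))
  expect_true(isHypoperfused(a2))
  expect_equal(areaRatio(a2), 6.5)
  expect_equal(decisionFlag(a2), "proceed")

  # above one-third: excluded by the eligibility screen
  vals3 <- matrix(100, 40, 40); vals3[seq_len(600)] <- 10
  a3 <- assessFlap(rpuFromMatrix(vals3), matrix(FALSE, 40, 40))
  expect_true(eligibilityExcluded(a3))
})
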