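# Shared fixtures, built in code.

# Small default domain + territory model with a known dropout.
smallCase <- function(height = 80, width = 80, nTerr = 5, seed = 3,
                      dropoutIds = 1L, dropoutFactor = 0.2, noiseSd = 0,
                      nippleRadius = 5, frameTimes = seq(0, 180, by = 2),
                      profile = KineticProfile()) {
  dom <- makeBreastDomain(height, width, nippleRadius = nippleRadius)
  terr <- makeTerritories(dom$breastMask, nTerr, seed = seed,
                          dropoutIds = dropoutIds,
                          dropoutFactor = dropoutFactor)
  simulateRecording(dom, terr, profile, frameTimes = frameTimes,
                    noiseSd = noiseSd, seed = seed)
}

# Independent Fisher oracle: enumerate all 2x2 tables with the observed
# margins; p = sum of hypergeometric probabilities (choose() products)
# not exceeding the observed table's, with 1e-7 relative tie tolerance.
fisherEnumOracle <- function(tp, fp, fn, tn) {
  r1 <- tp + fp; c1 <- tp + fn; n <- tp + fp + fn + tn
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  prob <- function(k) choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  ps <- vapply(ks, prob, 0)
  sum(ps[ps <= prob(tp) * (1 + 1e-7)])
}

# RPU map straight from a matrix, for segmentation unit tests.
rpuFromMatrix <- function(values, breastMask = NULL) {
  if (is.null(breastMask))
    breastMask <- matrix(TRUE, nrow(values), ncol(values))
  pm <- new("PerfusionMap", values = values, sourceIndices = 1L,
            aggregator = "frame")
  computeRPU(pm, breastMask)
}
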