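test_that("zero-class fraction handles clamping and bad pairs", {
  expect_equal(as.numeric(zeroClassFraction(50, 50)), 1)
  p0 <- zeroClassFraction(36.79, 100)
  expect_equal(as.numeric(p0), 0.3679)
  expect_equal(zeroClassMu(as.numeric(p0)), 1, tolerance = 1e-3)
  # small over-unity ratios clamp to 1 with a QC flag
  cl <- zeroClassFraction(103, 100)
  expect_equal(as.numeric(cl), 1)
  expect_true(attr(cl, "qcClamped"))
  expect_false(attr(zeroClassFraction(90, 100), "qcClamped"))
  expect_error(zeroClassFraction(106, 100), "pairing")
  expect_error(zeroClassFraction(50, 0), "positive")
  # invariant to common gain on both bands
  expect_equal(as.numeric(zeroClassFraction(36.79 * 13, 100 * 13)), 0.3679)
})

test_that("fragment time course applies -ln(P0) per point", {
  tt <- c(0, 30, 60, 120)
  rc <- fragmentTimecourse(tt, p0 = c(0.33, 0.55, 0.74, 0.90),
                           fragmentLengthNt = 2200)
  # recomputed independently: 100 * (1 - ln(P0_t)/ln(P0_0))
  expect_equal(repairPercent(rc), c(0, 46.08, 72.84, 90.50),
               tolerance = 1e-4)
  expect_equal(initialPerKb(rc), -log(0.33) * 1000 / 2200,
               tolerance = 1e-9)
  # flat P0 -> flat zero curve
  rcf <- fragmentTimecourse(c(0, 60), p0 = c(0.5, 0.5),
                            fragmentLengthNt = 2200)
  expect_equal(repairPercent(rcf), c(0, 0))
  # undamaged start cannot be normalized
  expect_error(fragmentTimecourse(c(0, 60), p0 = c(1, 0.9),
                                  fragmentLengthNt = 2200), "initial")
  # percent repair invariant to the fragment length, per-kb is not
  rc2 <- fragmentTimecourse(tt, p0 = c(0.33, 0.55, 0.74, 0.90),
                            fragmentLengthNt = 1100)
  expect_equal(repairPercent(rc2), repairPercent(rc))
  expect_equal(initialPerKb(rc2), 2 * initialPerKb(rc))
  # band pairs route equals the p0 route
  rc3 <- fragmentTimecourse(tt, bandPlus = c(33, 55, 74, 90),
                            bandMinus = rep(100, 4),
                            fragmentLengthNt = 2200)
  expect_equal(repairPercent(rc3), repairPercent(rc))
})

test_that("simulated zero-class counting recovers the lesion burden", {
  sim <- simulateRestrictionAssay(1.1, 1e4, seed = 21)
  muHat <- zeroClassMu(sim$intact / sim$total)
  expect_equal(muHat, 1.1, tolerance = 0.05)
  # programmed kinetics recovered through the band-pair interface
  tc <- simulateFragmentTimecourse(1.1, c(1, 0.6, 0.3, 0.15),
                                   c(0, 30, 60, 120), 1e4, seed = 8)
  rc <- fragmentTimecourse(tc$time_min, bandPlus = tc$band_plus,
                           bandMinus = tc$band_minus,
                           fragmentLengthNt = 2200)
  # binomial counting error at n = 1e4 keeps each point within ~5 points
  expect_lt(max(abs(repairPercent(rc) - c(0, 40, 70, 85))), 5)
})

test_that("normalized band ratios reference the control condition", {
  expect_equal(normalizedBandRatio(3, 6, 0.5), 1)
  expect_equal(normalizedBandRatio(6, 6, 0.5), 2)
  expect_equal(normalizedBandRatio(4, 2, 0.5), 4)
  expect_error(normalizedBandRatio(4, 0, 0.5), "loading")
  expect_error(normalizedBandRatio(4, 2, 0), "reference")
})

test_that("replicate summary uses the sample standard deviation", {
  s <- replicateSummary(c(1, 1, 1))
  expect_equal(s$mean, 1)
  expect_equal(s$sd, 0)
  s2 <- replicateSummary(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$sd, sqrt(2))
  expect_error(replicateSummary(5), "2 replicate")
})
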