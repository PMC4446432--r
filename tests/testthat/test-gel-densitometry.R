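test_that("ladder calibration reproduces knots and interpolates log-linearly", {
  mm <- fitLadder(SizeLadder(c(10, 20), c(10000, 1000)))
  expect_equal(as.numeric(migrationToLength(mm, 10)), 10000)
  expect_equal(as.numeric(migrationToLength(mm, 20)), 1000)
  # midpoint is the geometric mean of the knot lengths
  expect_equal(as.numeric(migrationToLength(mm, 15)), 3162.2777,
               tolerance = 1e-6)
  # extrapolation beyond the knots is flagged
  v <- migrationToLength(mm, c(5, 15, 25))
  expect_identical(attr(v, "extrapolated"), c(TRUE, FALSE, TRUE))
  # linear in log10 continues the knot slope: 10^(3 - 0.1*5)
  expect_equal(as.numeric(v[3]), 316.22777, tolerance = 1e-6)
  # non-monotone ladders are rejected naming the offending pairs
  expect_error(SizeLadder(c(10, 20, 30), c(10000, 1000, 2000)),
               "decreasing")
  expect_error(SizeLadder(c(10, 5), c(100, 10)), "increasing")
})

test_that("background subtraction recovers known baselines", {
  m <- seq(1, 40, length.out = 40)
  y <- dnorm(m, 20, 3)
  clean <- LaneProfile(m, y, label = "clean")
  # already at zero baseline: unchanged
  expect_equal(intensity(subtractBackground(clean, "constant")), y)
  # constant offset removed exactly
  shifted <- LaneProfile(m, y + 7, label = "shift")
  expect_equal(intensity(subtractBackground(shifted, "constant")), y)
  # descending ramp removed by the linear mode (line through end segments)
  ramp <- LaneProfile(m, 10 - 0.2 * m, label = "ramp")
  expect_lt(max(abs(intensity(subtractBackground(ramp, "linear")))), 1e-10)
  expect_identical(subtractBackground(clean, "none"), clean)
  expect_error(subtractBackground(clean, "spline"))
})

test_that("ensemble average is the mass-weighted harmonic mean length", {
  # all intensity at one length
  fx <- endpointProfile(3000, 1000, 5, 0)
  expect_equal(ensembleLengthNt(
    ensembleAverageLength(fx$profile, fx$map, c(1, 1e5))), 3000)
  # equal split between 1000 and 2000 nt -> 1333.33
  fx <- endpointProfile(2000, 1000, 1, 1)
  expect_equal(ensembleLengthNt(
    ensembleAverageLength(fx$profile, fx$map, c(1, 1e5))),
    4000 / 3, tolerance = 1e-9)
  # intensities (3, 1) at (3000, 1000) -> 2000
  fx <- endpointProfile(3000, 1000, 3, 1)
  ea <- ensembleAverageLength(fx$profile, fx$map, c(1, 1e5))
  expect_equal(ensembleLengthNt(ea), 2000)
  # invariant under uniform intensity rescaling
  for (cc in c(0.01, 3, 1e4)) {
    fxc <- endpointProfile(3000, 1000, 3 * cc, 1 * cc)
    expect_equal(ensembleLengthNt(
      ensembleAverageLength(fxc$profile, fxc$map, c(1, 1e5))), 2000)
  }
  # Ln lies between the extreme lengths present
  expect_gte(ensembleLengthNt(ea), 1000)
  expect_lte(ensembleLengthNt(ea), 3000)
  # bounds clipping that removes everything is an error
  expect_error(ensembleAverageLength(fx$profile, fx$map, c(1e4, 1e5)),
               "bounds")
})

test_that("ensemble average censors at the bound for noise-only lanes", {
  fx <- endpointProfile(3000, 1000, 3, 1)
  # zero-mean noise with no net count signal: sum(I/L) <= sum(I)/upper
  mig <- seq(10, 20, length.out = 11L)
  noisy <- LaneProfile(mig, c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 0.05),
                       label = "noise")
  ea <- ensembleAverageLength(noisy, fx$map, c(1, 1e5))
  expect_true(ea@censored)
  expect_equal(ensembleLengthNt(ea), 1e5)
})

test_that("lesion frequency subtracts the control in reciprocal space", {
  ln <- function(x, lab = "l") new("EnsembleAverage", lengthNt = x,
                                   label = lab, censored = FALSE)
  expect_equal(as.numeric(lesionFrequency(ln(1500), ln(1500))), 0)
  expect_equal(as.numeric(lesionFrequency(ln(500), ln(2000))), 1.5)
  # intact-control limit: the finite-length term vanishes
  expect_equal(as.numeric(lesionFrequency(ln(1000), ln(1e9))), 1,
               tolerance = 1e-5)
  # antisymmetric under swapping the lanes
  f1 <- lesionFrequency(ln(500), ln(2000))
  f2 <- lesionFrequency(ln(2000), ln(500))
  expect_equal(as.numeric(f1), -as.numeric(f2))
  expect_true(attr(f2, "qcNegative"))
  expect_false(attr(f1, "qcNegative"))
})

test_that("genomic time course recovers programmed repair from ideal lanes", {
  gel <- GelModel(bandSigma = 1, noiseSd = 0, lengthRange = c(1, 2e5),
                  gridStep = 1)
  # constant burden across times -> flat curve near 0% repair
  sim <- simulateGenomicAssay(5e3, 5e4, 1.0, c(0, 0, 0), c(0, 60, 120),
                              gel, seed = 7)
  rc <- genomicTimecourse(sim$lanes, sim$ladder, lengthBounds = c(1, 2e5))
  expect_lt(max(abs(repairPercent(rc))), 2)
  expect_equal(initialPerKb(rc), 1.0, tolerance = 0.05)
  # duplicate of the t = 0 pair passed as a later time -> exactly 0%
  dup <- lapply(sim$lanes[1:2], function(l)
    initialize(l, timeMin = 60))
  rc0 <- genomicTimecourse(c(sim$lanes[1:2], dup), sim$ladder,
                           lengthBounds = c(1, 2e5))
  expect_equal(repairPercent(rc0)[2], 0)
  # a missing/duplicated control lane is an error naming the time
  expect_error(genomicTimecourse(sim$lanes[c(1, 2, 3, 3)], sim$ladder,
                                 lengthBounds = c(1, 2e5)), "60")
})

test_that("Poisson identity: lesion frequency recovers the break rate", {
  # moderate-size version of the ensemble-average oracle; the full-size
  # run lives in the acceptance suite
  gel <- GelModel(bandSigma = 1, noiseSd = 0, lengthRange = c(1, 2e5),
                  gridStep = 1)
  sim <- simulateGenomicAssay(1e4, 5e4, 1.0, c(0, 0.4), c(0, 60), gel,
                              seed = 3)
  rc <- genomicTimecourse(sim$lanes, sim$ladder, lengthBounds = c(1, 2e5))
  expect_equal(initialPerKb(rc), 1.0, tolerance = 0.04)
  expect_equal(repairPercent(rc)[2], 40, tolerance = 0.05 * 40)
})
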