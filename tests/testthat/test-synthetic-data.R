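test_that("lesion fields are Poisson, uniform, sorted and reproducible", {
  f0 <- simulateLesions(5e4, 0, seed = 1)
  expect_length(f0@positions, 0)
  f1 <- simulateLesions(5e4, 1.0, seed = 2)
  f2 <- simulateLesions(5e4, 1.0, seed = 2)
  expect_identical(f1@positions, f2@positions)
  expect_false(is.unsorted(f1@positions))
  expect_false(anyDuplicated(f1@positions) > 0)
  # Poisson moments over many molecules: mean ~ 50, variance ~ mean
  set.seed(3)
  counts <- replicate(2000, length(simulateLesions(5e4, 1.0)@positions))
  expect_equal(mean(counts), 50, tolerance = 0.05)
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.15)
})

test_that("repair removes lesions first-order and nests across times", {
  # half of 1e5 lesions survive one half-life
  f <- new("LesionField", lengthNt = 1e6,
           positions = seq_len(1e5) * 10L - 3L, ratePerKb = 100)
  surv <- applyRepair(f, log(2) / 60, times = c(0, 60), seed = 4)
  expect_identical(surv[[1]], f@positions)
  expect_equal(length(surv[[2]]) / 1e5, 0.5, tolerance = 0.01)
  # nested survivor sets under one random stream
  surv2 <- applyRepair(f, log(2) / 60, times = c(0, 30, 60, 120), seed = 5)
  for (j in 2:4)
    expect_true(all(surv2[[j]] %in% surv2[[j - 1]]))
  # fully occupied sites with alpha = 1 never repair
  model <- RepairModel(f@positions[1:100], kBase = log(2) / 60,
                       occupancy = 1, alpha = 1)
  f100 <- new("LesionField", lengthNt = 1e6,
              positions = f@positions[1:100], ratePerKb = 1)
  surv3 <- applyRepair(f100, model, times = c(0, 1e5), seed = 6)
  expect_identical(surv3[[2]], f100@positions)
  expect_error(applyRepair(f, 0.1, times = -5), "negative")
})

test_that("fragmentation conserves length exactly", {
  expect_identical(fragmentsFromBreaks(100, integer(0)), 100)
  expect_equal(fragmentsFromBreaks(100, 40), c(40, 60))
  expect_equal(fragmentsFromBreaks(100, c(10, 20, 30)), c(10, 10, 10, 70))
  expect_error(fragmentsFromBreaks(100, 101), "outside")
  set.seed(7)
  for (i in 1:25) {
    L <- sample(1000:50000, 1)
    br <- sort(sample.int(L - 1L, sample(0:80, 1)))
    expect_equal(sum(fragmentsFromBreaks(L, br)), L)
  }
})

test_that("rendered lanes put mass-proportional Gaussians at m(L)", {
  gel <- GelModel(bandSigma = 0.5, noiseSd = 0, lengthRange = c(1, 2e5))
  lane <- renderLane(5000, gel, weights = "mass")
  expect_equal(migration(lane)[which.max(intensity(lane))],
               migrationOf(gel, 5000), tolerance = 0.02)
  # total rendered signal proportional to total mass (noise-free)
  lane2 <- renderLane(c(5000, 5000, 10000), gel, weights = "mass")
  expect_equal(sum(intensity(lane2)) / sum(intensity(lane)), 4,
               tolerance = 1e-3)
  # count weighting gives equal areas regardless of length
  laneC <- renderLane(c(100, 10000), gel, weights = "count")
  half <- migrationOf(gel, 1000)
  left <- intensity(laneC)[migration(laneC) < half]   # long fragment
  right <- intensity(laneC)[migration(laneC) >= half] # short fragment
  expect_equal(sum(left), sum(right), tolerance = 1e-3)
})

test_that("zero-class counting follows the Poisson law", {
  sim0 <- simulateRestrictionAssay(0, 100, seed = 1)
  expect_equal(sim0$intact, 100)
  sim <- simulateRestrictionAssay(1, 1e5, seed = 9)
  # binomial test of intact fraction against exp(-1) at alpha = 0.01
  expect_gt(binom.test(sim$intact, sim$total,
                       p = exp(-1))$p.value, 0.01)
  expect_identical(simulateRestrictionAssay(1, 1e4, seed = 11),
                   simulateRestrictionAssay(1, 1e4, seed = 11))
})

test_that("sequencing-gel simulation honors the runoff geometry", {
  gel <- GelModel(bandSigma = 0.06, lengthRange = c(50, 1200))
  rmFast <- RepairModel(c(300L, 700L), rateConstants = c(0, 0))
  # no damage anywhere: only the full-length band
  s0 <- simulateSequencingGel(c(300L, 700L), 0, rmFast, c(0, 30), gel,
                              1000, 1144, seed = 2)
  expect_true(all(bandIntensities(s0$counts) == 0))
  expect_true(all(fullLengthIntensity(s0$counts) == 1000))
  # one certain lesion, no repair: a single damage band, no full length
  s1 <- simulateSequencingGel(300L, 1, RepairModel(300L, rateConstants = 0),
                              c(0, 30), gel, 500, 1144, seed = 3)
  expect_true(all(bandIntensities(s1$counts) == 500))
  expect_true(all(fullLengthIntensity(s1$counts) == 0))
  # the proximal surviving lesion shadows the distal one
  s2 <- simulateSequencingGel(c(300L, 700L), 1, rmFast, c(0), gel,
                              400, 1144, seed = 4)
  expect_equal(unname(bandIntensities(s2$counts)[, 1]), c(400, 0))
})

test_that("plating simulation respects its edge cases", {
  r <- simulatePlating(1e6, 7.2e-6, 1, 1e3, seed = 13)
  expect_equal(r$cells_plated_selective, 1e6)
  # survival 1: titer close to nominal cells / dilution
  expect_equal(r$titer_colonies, 1000, tolerance = 0.15)
  expect_identical(simulatePlating(1e6, 7.2e-6, 0.5, 1e3, seed = 5),
                   simulatePlating(1e6, 7.2e-6, 0.5, 1e3, seed = 5))
})

test_that("the high-resolution study design is internally consistent", {
  d <- hiresStudyDesign(seed = 31)
  expect_length(d$sites, 50)
  expect_true(all(d$sites >= 1 & d$sites <= d$fragmentLengthNt))
  expect_true(all(d$tHalfTrue[d$inCore] >= 120))
  expect_true(all(d$tHalfTrue[!d$inCore] <= 90))
  expect_true(IRanges::isDisjoint(d$coreIntervals))
  # adjacent band centers at least 3 sigma apart for the deconvolution
  centers <- migrationOf(d$gel, c(d$sites, d$fragmentLengthNt))
  expect_gte(min(abs(diff(sort(centers)))), 3 * d$bandSigma)
})
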