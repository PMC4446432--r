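test_that("band deconvolution recovers constructed mixture areas", {
  sig <- 0.4
  # single Gaussian at a listed center: its area, others ~ 0
  lane1 <- gaussianLane(8, 3, sig, 4, 20)
  a1 <- deconvolveLane(lane1, centers = c(8, 12, 16), sigma = sig)
  expect_equal(as.numeric(a1[1]), 3, tolerance = 0.01)
  expect_lt(max(as.numeric(a1[2:3])), 0.03)
  # two Gaussians separated by 4 sigma, amplitudes (2, 1)
  lane2 <- gaussianLane(c(8, 8 + 4 * sig), c(2, 1), sig, 4, 14)
  a2 <- deconvolveLane(lane2, centers = c(8, 8 + 4 * sig), sigma = sig)
  expect_equal(as.numeric(a2), c(2, 1), tolerance = 0.01)
  expect_lt(attr(a2, "residualNorm"), 1e-6)
  # flat zero profile -> all amplitudes zero
  flat <- LaneProfile(seq(4, 14, by = 0.1), rep(0, 101))
  expect_equal(as.numeric(deconvolveLane(flat, c(8, 10), sig)), c(0, 0))
  # guards
  expect_error(deconvolveLane(lane1, numeric(0), sig), "empty")
  expect_error(deconvolveLane(lane1, c(8, 12), -1), "positive")
  expect_error(deconvolveLane(lane1, c(8, 8.01), sig), "ill-conditioned")
})

test_that("deconvolution stays within 5% under 1% additive noise", {
  sig <- 0.4
  set.seed(42)
  centers <- c(6, 8, 10, 12.5)
  areas <- c(2, 1, 0.5, 3)
  lane <- gaussianLane(centers, areas, sig, 3, 16)
  y <- intensity(lane)
  noisy <- LaneProfile(migration(lane),
                       y + rnorm(length(y), 0, 0.01 * max(y)),
                       label = "noisy")
  a <- deconvolveLane(noisy, centers, sig)
  expect_lt(max(abs(as.numeric(a) - areas) / areas), 0.05)
})

test_that("fraction remaining corrects loading and normalizes to t = 0", {
  pos <- c(100L, 300L, 700L)
  tt <- c(0, 60)
  # identical lanes at all times -> all fractions 1
  bkt <- BandKineticsTable(pos, tt, cbind(c(2, 2, 2), c(2, 2, 2)),
                           fullLength = c(4, 4), fragmentLengthNt = 1144)
  expect_true(all(fractionRemaining(bkt) == 1))
  # a uniformly scaled lane (loading loss) is fully corrected
  bkt2 <- BandKineticsTable(pos, tt, cbind(c(2, 2, 2), 0.5 * c(2, 2, 2)),
                            fullLength = c(4, 2), fragmentLengthNt = 1144)
  expect_true(all(abs(fractionRemaining(bkt2) - 1) < 1e-12))
  # one band halved with all else constant: hand-computed 3-band toy
  bkt3 <- BandKineticsTable(pos, tt, cbind(c(2, 2, 2), c(1, 2, 2)),
                            fullLength = c(4, 4), fragmentLengthNt = 1144)
  fr <- fractionRemaining(bkt3)
  # t=1 totals: 9; normalized (1/9, 2/9, 2/9) vs t=0 (0.2, 0.2, 0.2)
  expect_equal(unname(fr[, 2]), c((1/9)/0.2, (2/9)/0.2, (2/9)/0.2))
  expect_equal(unname(fr[, 1]), c(1, 1, 1))
  # zero t=0 band is marked unusable, not an abort
  bkt4 <- BandKineticsTable(pos, tt, cbind(c(0, 2, 2), c(1, 2, 2)),
                            fullLength = c(4, 4), fragmentLengthNt = 1144)
  expect_warning(fr4 <- fractionRemaining(bkt4), "unusable")
  expect_true(all(is.na(fr4[1, ])))
  expect_false(anyNA(fr4[-1, ]))
})

test_that("per-position half-times follow the per-band kinetics", {
  pos <- c(50L, 400L, 900L)
  tt <- c(0, 30, 60, 120, 240)
  # all positions exponential with t1/2 = 60
  fr <- matrix(rep(exp(-log(2) / 60 * tt), each = 3), nrow = 3)
  prof <- tHalfProfile(fr, tt, pos)
  expect_equal(tHalf(prof), rep(60, 3), tolerance = 1e-9)
  # mixed: fast, slow, and censored positions
  fr2 <- rbind(exp(-log(2) / 30 * tt), exp(-log(2) / 240 * tt),
               c(1, 0.95, 0.9, 0.8, 0.55))
  prof2 <- tHalfProfile(fr2, tt, pos)
  expect_equal(tHalf(prof2)[1:2], c(30, 240), tolerance = 1e-9)
  expect_identical(isCensored(prof2), c(FALSE, FALSE, TRUE))
})

test_that("positional smoothing averages non-censored sites within 20 nt", {
  # constant profile smooths to itself
  p <- smoothProfile(THalfProfile(c(10L, 25L, 40L), rep(55, 3),
                                  rep(FALSE, 3)))
  expect_equal(smoothedTHalf(p), rep(55, 3))
  # isolated position keeps its own value
  p2 <- smoothProfile(THalfProfile(c(10L, 200L), c(40, 80),
                                   rep(FALSE, 2)))
  expect_equal(smoothedTHalf(p2), c(40, 80))
  # three sites within one 41-nt window (ends exactly 20 nt from each
  # other): every position averages all three
  p3 <- smoothProfile(THalfProfile(c(10L, 20L, 30L), c(30, 60, 90),
                                   rep(FALSE, 3)))
  expect_equal(smoothedTHalf(p3), c(60, 60, 60))
  # and with sites 25 nt apart the ends see only their nearer neighbor
  p3b <- smoothProfile(THalfProfile(c(10L, 30L, 50L), c(30, 60, 90),
                                    rep(FALSE, 3)))
  expect_equal(smoothedTHalf(p3b), c(45, 60, 75))
  # censored neighbors are excluded, not imputed
  p4 <- smoothProfile(THalfProfile(c(10L, 20L, 30L), c(30, NA, 90),
                                   c(FALSE, TRUE, FALSE)))
  expect_equal(smoothedTHalf(p4), c(60, 60, 60))
  expect_error(smoothProfile(p, window = 40), "odd")
  # interior windowed means equal direct re-averaging (oracle)
  set.seed(5)
  pos <- sort(sample.int(1000, 60))
  th <- runif(60, 20, 300)
  pr <- smoothProfile(THalfProfile(pos, th, rep(FALSE, 60)))
  direct <- vapply(pos, function(x) mean(th[abs(pos - x) <= 20]),
                   numeric(1))
  expect_equal(smoothedTHalf(pr), direct)
})

test_that("nucleosome annotation labels core/linker and summarizes", {
  prof <- THalfProfile(c(10L, 50L, 120L), c(30, 100, 40), rep(FALSE, 3))
  # no intervals: all linker
  a0 <- annotateNucleosomes(prof, matrix(numeric(0), ncol = 2))
  expect_true(all(nucleosomeLabel(a0) == "linker"))
  # containment: (10, 50) with core (40, 147) -> linker, core
  a1 <- annotateNucleosomes(prof, cbind(40, 147))
  expect_identical(nucleosomeLabel(a1), c("linker", "core", "core"))
  smry <- nucleosomeSummary(a1)
  expect_equal(smry$mean_t_half_min[smry$label == "core"], 70)
  expect_equal(smry$mean_t_half_min[smry$label == "linker"], 30)
  # everything inside one interval
  a2 <- annotateNucleosomes(prof, cbind(1, 1144))
  expect_true(all(nucleosomeLabel(a2) == "core"))
  expect_error(annotateNucleosomes(prof, rbind(c(1, 100), c(50, 200))),
               "overlap")
  # BED-like 0-based half-open conversion
  ir <- bedToIntervals(c(0, 147), c(147, 294))
  expect_equal(IRanges::start(ir), c(1, 148))
  expect_equal(IRanges::end(ir), c(147, 294))
})

test_that("lane-set deconvolution assembles a kinetics table", {
  sig <- 0.3
  centers <- c(20, 15, 10)          # two damage bands + full length
  tt <- c(0, 60)
  lanes <- list(
    initialize(gaussianLane(centers, c(4, 2, 10), sig, 8, 22),
               timeMin = 0),
    initialize(gaussianLane(centers, c(2, 2, 12), sig, 8, 22),
               timeMin = 60))
  bkt <- deconvolveKinetics(lanes, centers, sig,
                            positions = c(300L, 600L),
                            fragmentLengthNt = 1144)
  expect_s4_class(bkt, "BandKineticsTable")
  expect_equal(positions(bkt), c(300L, 600L))
  expect_equal(timesMin(bkt), tt)
  expect_equal(unname(bandIntensities(bkt)[, 1]), c(4, 2),
               tolerance = 0.01)
  expect_equal(unname(fullLengthIntensity(bkt)), c(10, 12),
               tolerance = 0.01)
  expect_equal(fragmentLength(bkt), 1144)
})
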