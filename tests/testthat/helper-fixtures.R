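# Shared in-code fixtures for the test suite.

# lane with intensity w1 at a sample mapping exactly to length L1 and w2 at
# a sample mapping exactly to L2 (the ladder knots), zero elsewhere
endpointProfile <- function(L1, L2, w1, w2) {
  ladder <- SizeLadder(migration = c(10, 20), lengthNt = c(L1, L2))
  mig <- seq(10, 20, length.out = 11L)
  intens <- rep(0, 11L)
  intens[1L] <- w1
  intens[11L] <- w2
  list(profile = LaneProfile(mig, intens, label = "fix"),
       ladder = ladder, map = fitLadder(ladder))
}

# analytic Gaussian-mixture lane on a regular migration grid
gaussianLane <- function(centers, areas, sigma, from, to, by = sigma / 5,
                         label = "mix") {
  m <- seq(from, to, by = by)
  y <- rep(0, length(m))
  for (i in seq_along(centers))
    y <- y + areas[i] * dnorm(m, centers[i], sigma)
  LaneProfile(m, y, label = label)
}
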