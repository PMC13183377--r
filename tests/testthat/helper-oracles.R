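# Brute-force Lomb-Scargle oracle: explicit least-squares sinusoid fit via
# the 2x2 normal equations at each frequency, independent of the package's
# tau-rotation implementation.
lsOracle <- function(timesH, values, periodsH) {
  yc <- values - mean(values)
  ss <- sum(yc^2)
  vapply(periodsH, function(P) {
    X <- cbind(cos(2 * pi * timesH / P), sin(2 * pi * timesH / P))
    beta <- solve(crossprod(X), crossprod(X, yc))
    resid <- yc - X %*% beta
    (ss - sum(resid^2)) / (2 * stats::var(values))
  }, numeric(1))
}

# Periodogram object with hand-made power curve (no significance lines
# unless given), for exercising peak and classification rules in isolation.
makePg <- function(periodsH, power, sig = NULL) {
  sl <- if (is.null(sig)) stats::setNames(numeric(0), character(0))
  else stats::setNames(sig, as.character(c(0.05, 0.01))[seq_along(sig)])
  new("Periodogram", periodsH = periodsH, power = power, sigLines = sl,
      nRand = 0L, seed = 0L,
      peaks = ovirhythm:::peakCandidates(periodsH, power))
}

# Smooth power curve with Gaussian bumps at given periods/heights on a grid.
bumpCurve <- function(grid, centers, heights, width = 1.2) {
  rowSums(vapply(seq_along(centers), function(k)
    heights[k] * exp(-(grid - centers[k])^2 / (2 * width^2)),
    numeric(length(grid))))
}

# Count-weighted circular mean of time-of-day, hours in [0, 24).
circMeanPhase <- function(timesH, counts, periodH = 24) {
  th <- 2 * pi * (timesH %% periodH) / periodH
  (atan2(sum(counts * sin(th)), sum(counts * cos(th))) * periodH / (2 * pi)) %%
    periodH
}
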