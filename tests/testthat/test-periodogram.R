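test_that("power equals the brute-force least-squares oracle", {
  set.seed(101)
  worst <- 0
  for (k in 1:30) {
    n <- sample(10:48, 1)
    t <- sort(runif(n, 0, 180))
    y <- rnorm(n)
    grid <- periodGrid(t)
    p <- lombScargle(t, y, grid)
    po <- lsOracle(t, y, grid)
    worst <- max(worst, max(abs(p - po) / pmax(abs(po), 1e-12)))
  }
  expect_lt(worst, 1e-9)
})

test_that("a noiseless sinusoid is recovered at its period", {
  t <- seq(0, 164, by = 4)
  grid <- periodGrid(t)
  pw <- lombScargle(t, sin(2 * pi * t / 24), grid)
  step <- diff(grid)[findInterval(24, grid)]
  expect_lt(abs(grid[which.max(pw)] - 24), step)
})

test_that("white-noise power at a fixed frequency averages to ~1", {
  t <- seq(0, 164, by = 4)
  set.seed(5)
  pw <- replicate(400, lombScargle(t, rnorm(42), c(20, 24, 30)))
  expect_lt(max(abs(rowMeans(pw) - 1)), 3 / sqrt(400))  # Exp(1) spread
})

test_that("power is invariant to value offset/scale and time shifts", {
  set.seed(6)
  for (k in 1:20) {
    n <- sample(12:48, 1)
    t <- sort(runif(n, 0, 160))
    y <- rpois(n, 5) + runif(n)
    grid <- periodGrid(t, c(8, 48), 4)
    p0 <- lombScargle(t, y, grid)
    expect_equal(lombScargle(t, y + 7.3, grid), p0, tolerance = 1e-9)
    expect_equal(lombScargle(t, 3.1 * y, grid), p0, tolerance = 1e-9)
    expect_equal(lombScargle(t + 1000, y, grid), p0, tolerance = 1e-9)
  }
})

test_that("degenerate series are rejected", {
  t <- seq(0, 164, by = 4)
  expect_error(lombScargle(t, rep(2, 42), periodGrid(t)), "constant")
  expect_error(lombScargle(1:3, c(1, 2, 1), c(10, 20)), "at least 4")
  expect_error(significanceLines(t, rpois(42, 4), periodGrid(t),
                                 levels = c(0, 0.05)), "levels")
})

test_that("significance lines are deterministic, ordered quantiles", {
  t <- seq(0, 164, by = 4)
  set.seed(8)
  y <- rpois(42, 5)
  grid <- periodGrid(t)
  s1 <- significanceLines(t, y, grid, nRand = 300, seed = 9)
  s2 <- significanceLines(t, y, grid, nRand = 300, seed = 9)
  expect_identical(s1, s2)
  expect_gte(s1[["0.01"]], s1[["0.05"]])
  expect_false(identical(
    s1, significanceLines(t, y, grid, nRand = 300, seed = 10)))
  expect_warning(significanceLines(t, y, grid, nRand = 50, seed = 1),
                 "unstable")
})

test_that("value-shuffle test is calibrated on exchangeable series", {
  t <- seq(0, 164, by = 4)
  grid <- periodGrid(t)
  set.seed(12)
  hits <- replicate(300, {
    y <- rnorm(42)
    th <- significanceLines(t, y, grid, levels = 0.05, nRand = 400,
                            seed = sample.int(1e6, 1))
    max(lombScargle(t, y, grid)) > th
  })
  # 99% binomial band around 0.05 at 300 draws
  expect_gt(mean(hits), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(hits), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 300))
})

test_that("pipeline significance lines re-detrend shuffled raw counts", {
  t <- seq(0, 164, by = 4)
  grid <- periodGrid(t)
  set.seed(13)
  cts <- rpois(42, 6)
  s1 <- pipelineSigLines(cts, t, grid, nRand = 200, seed = 3)
  expect_identical(s1, pipelineSigLines(cts, t, grid, nRand = 200, seed = 3))
  expect_gte(s1[["0.01"]], s1[["0.05"]])
  # the re-detrending null sits above the value-shuffle null because the
  # detrending filter boosts noise power at intermediate periods
  d <- detrendRecord(cts, timesH = t)
  s0 <- significanceLines(t, seriesValues(d), grid, nRand = 200, seed = 3)
  expect_gt(s1[["0.05"]], s0[["0.05"]])
  # ragged input: a truncated fly is accepted
  expect_silent(pipelineSigLines(list(cts, cts[1:30]), t, grid,
                                 nRand = 100, seed = 4))
})

test_that("peak finding follows the prominence convention", {
  grid <- periodGrid(seq(0, 164, by = 4))
  # one dominant bump and one small ripple: ripple is below 20% prominence
  pw <- bumpCurve(grid, c(24, 18), c(10, 1.5), width = 0.8)
  pg <- makePg(grid, pw)
  pk <- findPeaks(pg, c(16, 32))
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$period_h - 24), 0.2)
  # lowering the prominence floor exposes the ripple
  expect_identical(nrow(findPeaks(pg, c(16, 32), prominenceFrac = 0.05)), 2L)
  # monotone curve: no local maxima in window
  expect_identical(nrow(findPeaks(makePg(grid, seq_along(grid) * 0.01),
                                  c(16, 32))), 0L)
  expect_error(findPeaks(pg, c(50, 60)), "outside")
  expect_error(findPeaks(pg, c(30, 20)), "ordered")
})

test_that("period estimation reports the top peak with HWHM uncertainty", {
  grid <- periodGrid(seq(0, 164, by = 4))
  pg <- makePg(grid, bumpCurve(grid, 24, 8, width = 1.5))
  est <- estimatePeriod(pg, c(16, 32))
  expect_lt(abs(est$period_h - 24), 0.2)
  # half-width at half prominence of a Gaussian bump: sigma*sqrt(2 ln 2)
  expect_lt(abs(est$uncertainty_h - 1.5 * sqrt(2 * log(2))), 0.2)
  expect_false(est$tie)

  # exact tie (uniform grid symmetric about 24): smaller period wins
  grid2 <- seq(14, 34, by = 0.25)
  sym <- bumpCurve(grid2, c(20, 28), c(5, 5))
  estT <- estimatePeriod(makePg(grid2, sym), c(16, 32))
  expect_true(estT$tie)
  expect_lt(abs(estT$period_h - 20), 0.2)

  none <- estimatePeriod(makePg(grid, seq_along(grid) * 0.01), c(16, 32))
  expect_true(is.na(none$period_h))
  expect_true(is.na(none$uncertainty_h))
})
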