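test_that("generator is deterministic and emits valid device records", {
  p <- GenParams(seed = 11)
  r1 <- generateFly(p, 3)
  r2 <- generateFly(p, 3)
  expect_identical(eggCounts(r1), eggCounts(r2))
  expect_true(validObject(r1))
  expect_length(eggCounts(r1), 42L)
  expect_true(all(eggCounts(r1) >= 0))
  expect_true(all(diff(binTimes(r1)) == 4))
  expect_true(all(lightLabels(r1) %in% c("L", "D", "DDsub")))
  # different fly index gives a different draw
  expect_false(identical(eggCounts(generateFly(p, 4)), eggCounts(r1)))
  expect_error(generateFly(GenParams(baselineRate = -1), 1), "baselineRate")
  expect_error(generateFly(GenParams(modDepth = 2), 1), "modDepth")
})

test_that("flat generator matches the homogeneous Poisson rate", {
  p <- GenParams(modDepth = 0, trendTau = Inf, baselineRate = 1, flyCV = 0,
                 phaseJitterH = 0, seed = 21)
  cts <- unlist(lapply(1:200, function(i) eggCounts(generateFly(p, i))))
  se <- sqrt(4 / length(cts))     # Poisson mean = var = rate x 4 h
  expect_lt(abs(mean(cts) - 4), 3 * se)
})

test_that("modulated counts peak at the configured phase", {
  p <- GenParams(modDepth = 0.5, periodH = 24, phaseH = 10, trendTau = Inf,
                 phaseJitterH = 0, flyCV = 0, seed = 31)
  tot <- Reduce(`+`, lapply(1:200, function(i)
    as.numeric(eggCounts(generateFly(p, i)))))
  t <- binTimes(generateFly(p, 1))
  # subtract the flat floor so the circular mean reflects the bump only,
  # then allow half a bin for discretization (bin centers at start + 2 h)
  ph <- circMeanPhase(t + 2, pmax(tot - min(tot), 0))
  expect_lt(min(abs(ph - 10), 24 - abs(ph - 10)), 4)
})

test_that("arrhythmic records have no time structure beyond the trend", {
  pFlat <- GenParams(modDepth = 0, trendTau = Inf, flyCV = 0,
                     phaseJitterH = 0, seed = 41)
  tot <- Reduce(`+`, lapply(1:300, function(i)
    as.numeric(eggCounts(generateFly(pFlat, i)))))
  t <- binTimes(generateFly(pFlat, 1))
  byTod <- tapply(tot, t %% 24, mean)
  # Poisson totals: var = mean, each time-of-day averages 7 bins
  se <- sqrt(mean(tot) / 7)
  expect_lt(max(byTod) - min(byTod), 6 * se)
})

test_that("population mixing rounds the arrhythmic fraction", {
  p <- GenParams(seed = 51)
  pop <- generatePopulation(p, 21, fracArrhythmic = 0)
  expect_length(pop, 21L)
  expect_length(unique(vapply(pop, flyId, "")), 21L)

  mix <- generatePopulation(p, 10, fracArrhythmic = 0.3)
  flat <- generatePopulation(GenParams(modDepth = 0, seed = 51), 10,
                             fracArrhythmic = 0)
  same <- vapply(1:10, function(i)
    identical(eggCounts(mix[[i]]), eggCounts(flat[[i]])), TRUE)
  expect_identical(which(same[1:3]), 1:3)   # exactly the first 3 are flat

  all0 <- generatePopulation(p, 5, fracArrhythmic = 1)
  flat5 <- generatePopulation(GenParams(modDepth = 0, seed = 51), 5)
  expect_identical(lapply(all0, eggCounts), lapply(flat5, eggCounts))
  expect_error(generatePopulation(p, 0), "nFlies")
})

test_that("expected daily totals decrease under a finite trend", {
  p <- GenParams(modDepth = 0, trendTau = 120, seed = 61)
  daily <- Reduce(`+`, lapply(1:200, function(i) {
    cts <- as.numeric(eggCounts(generateFly(p, i)))
    tapply(cts, rep(1:7, each = 6), sum)
  })) / 200
  se <- sqrt(max(daily) / 200)
  expect_true(all(diff(daily) < 3 * se))
  # and clearly decreasing overall
  expect_lt(daily[7], daily[1] * 0.5)
})

test_that("connectome fixtures realize the requested strength classes", {
  spec <- data.frame(pre_cluster = c("E1", "E3", "oviIN"),
                     post_cluster = c("oviIN", "pC1b", "E2"),
                     class = c("strong", "intermediate", "weak"))
  ed <- generateConnectomeFixture(spec, seed = 7)
  expect_identical(generateConnectomeFixture(spec, seed = 7), ed)
  e1 <- ed[ed$instance_pre %in% c("LNd4", "LNd5") &
             ed$instance_post == "oviIN", ]
  expect_identical(nrow(e1), 2L)
  expect_true(all(e1$weight > 9))
  e3 <- ed[ed$instance_pre %in% c("LNd1", "LNd2", "LNd3"), ]
  expect_true(all(e3$weight >= 3 & e3$weight <= 9))
  expect_true(all(ed$instance_post[ed$instance_pre == "oviIN"] %in%
                    c("LNd6", "5th-sLNv")))
  expect_true(all(ed$weight[ed$instance_pre == "oviIN"] <= 2))

  expect_identical(nrow(generateConnectomeFixture(spec[0, ], seed = 1)), 0L)
  bad <- data.frame(pre_cluster = "E1", post_cluster = "oviIN",
                    class = "huge")
  expect_error(generateConnectomeFixture(bad, 1), "strength class")
})
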