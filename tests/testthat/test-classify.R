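grid <- periodGrid(seq(0, 164, by = 4))

test_that("genotype rule: one significant peak in 16-32 h", {
  pg <- makePg(grid, bumpCurve(grid, 24, 8), sig = c(5, 6.5))
  call <- classifyGenotype(pg)
  expect_identical(callLabel(call), "strong")
  expect_lt(abs(callPeriod(call) - 24), 0.2)

  # a 12-h peak, however powerful, lies outside the window
  out <- classifyGenotype(makePg(grid, bumpCurve(grid, 12, 20), sig = c(5, 6.5)))
  expect_identical(callLabel(out), "arrhythmic")
  expect_match(out@ruleTrace, "no in-window peak")

  # two comparable significant peaks disqualify the genotype
  two <- classifyGenotype(makePg(grid, bumpCurve(grid, c(20, 28), c(8, 7)),
                                 sig = c(5, 6.5)))
  expect_identical(callLabel(two), "arrhythmic")
  expect_match(two@ruleTrace, "multiple peaks")

  # sub-threshold single peak
  low <- classifyGenotype(makePg(grid, bumpCurve(grid, 24, 3), sig = c(5, 6.5)))
  expect_identical(callLabel(low), "arrhythmic")
  expect_match(low@ruleTrace, "below")

  expect_error(classifyGenotype(makePg(grid, bumpCurve(grid, 24, 8))),
               "significance lines")
})

test_that("individual rule: strong takes precedence, then the weak clause", {
  # one 25-h peak, power 0.35, below the fly's 0.05 line -> weak
  weak <- classifyIndividual(makePg(grid, bumpCurve(grid, 25, 0.35),
                                    sig = c(2, 3)))
  expect_identical(callLabel(weak), "weak")
  expect_lt(abs(callPeriod(weak) - 25), 0.2)

  # same shape but power 0.15: below the 0.2 cutoff
  arr <- classifyIndividual(makePg(grid, bumpCurve(grid, 25, 0.15),
                                   sig = c(2, 3)))
  expect_identical(callLabel(arr), "arrhythmic")

  # significant 17-h peak: strong via the 16-32 clause even though it is
  # outside the 18-32 weak window
  st <- classifyIndividual(makePg(grid, bumpCurve(grid, 17, 8),
                                  sig = c(5, 6.5)))
  expect_identical(callLabel(st), "strong")
  expect_lt(abs(callPeriod(st) - 17), 0.2)

  # a 17-h NON-significant peak is not weak either (outside 18-32)
  ns <- classifyIndividual(makePg(grid, bumpCurve(grid, 17, 3), sig = c(5, 6.5)))
  expect_identical(callLabel(ns), "arrhythmic")
})

test_that("rhythmic proportion counts strong plus weak", {
  mk <- function(lbl, n) replicate(n, new(
    "RhythmCall", subject = "f", label = lbl,
    periodH = if (lbl == "arrhythmic") NA_real_ else 24,
    uncertaintyH = NA_real_, peakPower = NA_real_, ruleTrace = "t"))
  calls <- c(mk("strong", 7), mk("weak", 7), mk("arrhythmic", 6))
  pr <- percentRhythmic(calls)
  expect_equal(pr[["fraction"]], 0.70)
  expect_equal(pr[["n_rhythmic"]], 14)
  expect_equal(percentRhythmic(mk("arrhythmic", 4))[["fraction"]], 0)
  expect_equal(percentRhythmic(mk("strong", 3))[["fraction"]], 1)
  expect_error(percentRhythmic(list()), "at least one")
})

test_that("stronger modulation yields more strong calls per fly", {
  depths <- c(0, 0.5, 0.9)
  res <- vapply(depths, function(m) {
    labs <- unlist(lapply(1:15, function(k) {
      p <- GenParams(modDepth = m, seed = 900 + k)
      pop <- generatePopulation(p, 10)
      out <- runGenotypeAnalysis(pop, analysisConfig(seed = 900 + k,
                                                     nRand = 150))
      out@periods$label
    }))
    c(strong = mean(labs == "strong"),
      rhythmic = mean(labs != "arrhythmic"))
  }, numeric(2))
  # strong calls rise monotonically with depth and the rhythmic fraction is
  # clearly higher for a deeply modulated population than for a null one
  expect_true(all(diff(res["strong", ]) >= 0))
  expect_gt(res["strong", 3], res["strong", 1])
  expect_gt(res["rhythmic", 3], res["rhythmic", 1])
})
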