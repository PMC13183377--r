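---
title: "Detecting circadian rhythms in egg-laying records"
author: "ovirhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian rhythms in egg-laying records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovirhythm)
```

## The measurement problem

Egg laying by *Drosophila* females is under circadian control, but it is a
hard behavior to score for rhythmicity. A semi-automated collection device
yields, per fly, one egg count every 4 h (six bins per day) over about a
week — a short, discrete, low-count series. Three features dominate these
records:

* a clear **decreasing trend**: mated females lay fewer eggs as the
  experiment progresses;
* strong **individual noise**: the decision to lay an egg depends on much
  more than the time of day, and only a fraction of individuals show a
  detectable rhythm on their own;
* **sparse, discrete sampling**: 4-h bins and single-digit counts, so a
  record of N days has only 6N points.

`ovirhythm` implements a pipeline tailored to these records — detrend,
average across flies, Lomb-Scargle scan, randomization significance,
rule-based classification — together with a synthetic record generator so
that every stage can be exercised and calibrated without access to
experimental data.

## Detrending

The trend series `T` is a centered moving average of the counts with a
6-bin window (one day), and the detrended series is the pointwise ratio
`D(i) = E(i) / T(i)`. Two conventions are fixed by this package and pinned
by its tests:

* the even window is centered with three bins to the left of bin *i*, bin
  *i* itself, and two to the right;
* at the edges the mean is taken over the truncated window, so `D` keeps
  the full record length. Records are short (36–48 bins) and discarding
  five bins per fly would be costly.

Bins where `T(i) = 0` (a whole eggless day) become missing values, never
infinities; downstream stages simply omit missing bins. Over a stationary
record the mean of `D` is close to 1, and a multiplicative trend
`exp(-t/tau)` cancels in the ratio: the tests verify that imposing a
5-day-constant decay moves the recovered period by less than one grid step.

Averaging the detrended series across flies exploits the classical
signal-to-noise argument: the circadian component is (approximately) shared
while the noise is independent, so the mean of *n* flies improves the
power of the common rhythm. Truncated records (flies that die) contribute
only while they have data; the average tracks per-bin contributor counts.

## The periodogram

The spectral engine is the classical variance-normalized Lomb-Scargle
periodogram, written from first principles: at each scanned frequency the
power is the variance reduction of the least-squares sinusoid fit to the
mean-centered values, divided by twice the sample variance. The tests hold
it to a brute-force normal-equations oracle at every scanned frequency to
a relative error below 1e-9, and under this normalization white noise has
expected power ~1 at any fixed frequency. Power is invariant to adding a
constant to the values, to positive scaling, and to translating the times.

The default period grid spans 8 h (the Nyquist period at the 4-h cadence)
to 48 h, uniform in frequency with step `1/(10 * span)` — a ten-fold
oversampling of the natural resolution `1/span`. For a 7-day record that is
about 170 grid points with a spacing of ~0.35 h near 24 h.

Degenerate inputs fail loudly: a constant series has no defined power, and
fewer than four non-missing points are rejected.

## Randomization significance

Significance lines follow the randomization logic: shuffle, rescan, record
the **maximum power over the whole grid**, and threshold at the empirical
`1 - alpha` quantile over 1000 shuffles. Using the grid-wide maximum makes
the lines family-wise over the scanned band.

One design choice deserves emphasis. Dividing by a one-day moving average
is, to first order, a high-pass-like filter: it *colors* the noise
spectrum, boosting power at intermediate periods (roughly 12–20 h) and
suppressing it beyond ~28 h. If the already-detrended values are shuffled,
the shuffled series lose that coloring, the null maxima come out too low,
and the nominal 0.05 line is crossed by pure-noise records far too often.
`ovirhythm` therefore randomizes the **raw egg series** and re-runs the
detrending (and, for genotype averages, the per-fly detrend and the
averaging) on every shuffle (`pipelineSigLines()`). With this scheme the
acceptance checks find the empirical type-I error of the screen inside the
binomial bands of the nominal 0.05 and 0.01 levels over 2000 simulated
null records.

The plain value-shuffling form (`significanceLines()`) is kept for series
that are exchangeable as given — it is exactly calibrated there — and is
what you want when feeding the periodogram something other than the
detrending pipeline's output.

## Peaks, periods, and uncertainties

A *peak* is a strict local maximum of the power curve whose topographic
prominence is at least 20% of the maximum in-window power. The prominence
floor is this package's convention (the decision rules below only say "one
peak"): it ignores the small noise ripples that decorate any empirical
periodogram — on a strongly rhythmic average, ripples of power ~1 next to
a main peak of power ~13 — while preserving the qualitative behavior that
pure-noise periodograms frequently show two or more (non-significant)
in-window peaks. A substantially smaller floor (e.g. 5%) makes the
"exactly one peak" rule essentially never fire on realistic rhythmic data.

The reported period is that of the highest in-window peak. If two peaks tie
exactly in power, the smaller period is returned and a tie flag is set.
The uncertainty is the half-width of the peak at half its prominence
(linear interpolation on the power curve), a convention chosen because the
upstream analyses print periods as `x +/- y h` without stating a method.

## Classification rules

* **Genotype level** — a genotype is rhythmic (`strong`) when the
  periodogram of its population-averaged detrended series has exactly one
  peak between 16 and 32 h and that peak exceeds the 0.05 randomization
  line. Anything else is `arrhythmic`; there is no weak class at genotype
  level. When both 0.05 and 0.01 lines are configured, the call is gated
  at the least stringent level; the stricter line is only reported.
* **Individual level** — a fly is `strong` if its own periodogram passes
  the genotype rule against its own shuffle line; otherwise `weak` if it
  shows exactly one peak between 18 and 32 h with power above 0.2;
  otherwise `arrhythmic`. Strong takes precedence, so a significant 17-h
  peak is strong even though 17 h is outside the weak window. Both window
  bounds are inclusive. The 0.2 cutoff is interpreted on the variance
  normalization scale and kept configurable, since power cutoffs are only
  meaningful relative to a normalization convention.
* "Percent rhythmic" counts strong plus weak flies.

The weak rule has no significance gate, and its "exactly one peak" clause
interacts non-monotonically with emerging signal (a true peak coexisting
with noise peaks violates it). Consequently the individual-level rhythmic
fraction is a blunt instrument at low modulation depth; the property tests
assert what does hold robustly — strong calls increase with modulation
depth, and deeply modulated populations are clearly separated from null
ones.

## The synthetic generator

The papers that motivate this pipeline do not state a generative model for
egg records, so the generator is an explicit synthetic stand-in with the
statistical structure the analysis assumes. For fly *i*, counts per bin
are Poisson with mean equal to the integral over the bin of

    lambda_i(t) = B_i * exp(-t / trendTau) *
                  [1 + modDepth * g((t - phaseH - delta_i) mod periodH)]

where `g` is a zero-mean, unit-peak von Mises-style bump
(`exp(k cos) - mean`, rescaled; `k = concentration`, degenerating to a
cosine at `k = 0`), `B_i` is lognormal with mean `baselineRate` and CV
`flyCV`, and `delta_i` is a Gaussian phase offset. Defaults, chosen once as
realistic study conditions:

| parameter | default | reading |
|---|---|---|
| `baselineRate` | 2 eggs/h | ~8 eggs per 4-h bin at start, tens per day |
| `trendTau` | 120 h | clear decay over a week (factor ~4) |
| `periodH`, `phaseH` | 24 h, 10 h | evening egg-laying peak |
| `modDepth` | 0.5 | detectable but noisy modulation |
| `concentration` | 2 | smooth unimodal evening bump |
| `flyCV`, `phaseJitterH` | 0.3, 1 h | individual variability |
| `nDays`, `binsPerDay` | 7, 6 | one week at the 4-h device cadence |

`generatePopulation()` mixes rhythmic and arrhythmic (`modDepth = 0`)
individuals in a chosen proportion. Everything is deterministic given
`(seed, fly index)`.

What the generator does **not** emulate: oogenesis and retention dynamics,
mating-status effects, substrate choice, inter-bin correlation beyond the
smooth rate (counts are conditionally independent Poisson), mortality
(though truncated records are supported downstream), and the device's
20/24/28-h track-replacement jitter — simulated bins sit on an exact 4-h
grid. Passing tests therefore demonstrate that the pipeline recovers the
structure this model encodes, not that real egg records satisfy the model.

## Connectome module

The connectivity analysis is deliberately mechanical: synapse-count
strength classes (weak 0–2, intermediate 3–9, strong >9; weak excluded as
reconstruction-error-prone), a cluster map from instance names to clock and
oviposition clusters (with the evening-cell subgroups E1 = LNd4/LNd5,
E2 = LNd6/5th-sLNv, E3 = LNd1–3), directed cluster-pair totals across a
bipartition, and directional-balance summaries. Strength is classified on
the per-neuron-pair summed weight, matching the connection-table semantics
of neuPrint exports. All shipped edge lists are synthetic fixtures
(`inst/extdata/synthetic_clock_ovi_edges.csv` encodes the qualitative
clock-oviposition topology, with invented weights except the 135/16
oviIN-LPN asymmetry used as a worked input); real analyses should feed
edge lists exported from a connectome release, and no network access is
attempted anywhere.

## Numerical and scale choices in the checks

The packaged checks run at desk scale, chosen to give stable statistics:
2000 null records (1000 shuffles each) for the type-I calibration of both
significance lines; 50 replicate genotypes of 20 flies each for period
recovery at 24 h and at a short-period (20.6 h) setting; 200 random small
series for the oracle-equivalence bound; 10 paired series for trend
invariance. Ties in the grid argmax resolve to the smaller period;
significance quantiles use the default empirical (type 7) estimator.

## Known limitations

* Calibration is demonstrated under the generator's Poisson model; real
  records may be over-dispersed beyond what the lognormal baseline absorbs.
* The weak-rhythm class is sensitive to the prominence convention and has
  no significance gate (see above); treat individual-level percentages as
  descriptive.
* The period uncertainty (half-width at half prominence) reflects peak
  sharpness, not a confidence interval.
* The DD-segment option starts the analysis at the first subjective-day
  bin; it does not model transients after the light transition.

## A minimal session

```{r example, eval = FALSE}
pop <- generatePopulation(GenParams(seed = 5), nFlies = 21)
res <- runGenotypeAnalysis(pop, analysisConfig(seed = 5))
res
reportTotals(bipartiteConnectivity(readSynapseEdges(
  system.file("extdata", "synthetic_clock_ovi_edges.csv",
              package = "ovirhythm"))))
```
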