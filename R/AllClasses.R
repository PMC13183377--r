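#' @import methods
NULL

.LIGHT_LEVELS <- c("L", "D", "DDsub")

#' Generative parameters for synthetic egg-laying records
#'
#' Parameters of the inhomogeneous-Poisson model used to simulate the output
#' of the semi-automated egg collection device: a per-fly lognormal baseline
#' rate, an exponential downward trend, and a smooth unimodal (von
#' Mises-shaped) circadian modulation with an evening peak.
#'
#' The expected rate for fly \eqn{i} at time \eqn{t} (hours) is
#' \deqn{\lambda_i(t) = B_i \, e^{-t/\tau} \, [1 + m\, g((t - \phi - \delta_i)
#' \bmod P)]}
#' where \eqn{g} is a zero-mean, unit-peak periodic bump with sharpness
#' `concentration`, \eqn{B_i} is lognormal with mean `baselineRate` and
#' coefficient of variation `flyCV`, and \eqn{\delta_i \sim N(0,
#' \mathrm{phaseJitterH}^2)}. Counts per bin are Poisson with mean equal to
#' the integral of \eqn{\lambda_i} over the bin. No generative model is
#' implied by the analysis itself; every distributional choice here is a
#' synthetic stand-in (see the package vignette).
#'
#' @slot baselineRate expected eggs per hour at t = 0 (> 0).
#' @slot trendTau exponential-decay time constant in hours (> 0; `Inf` = no
#'   trend).
#' @slot periodH circadian period in hours (> 0).
#' @slot phaseH peak time within the cycle, hours after (subjective)
#'   lights-on.
#' @slot modDepth relative modulation amplitude in \[0, 1\]; 0 = arrhythmic.
#' @slot concentration sharpness of the circadian bump (>= 0; 0 gives a pure
#'   cosine).
#' @slot flyCV coefficient of variation of the per-fly baseline (>= 0).
#' @slot phaseJitterH SD of per-fly phase offsets in hours (>= 0).
#' @slot nDays record length in days (>= 1).
#' @slot binsPerDay samples per day (default 6, i.e. 4-h bins).
#' @slot seed integer RNG seed; together with the fly index it fully
#'   determines a record.
#' @seealso [GenParams()], [generateFly()], [generatePopulation()]
#' @exportClass GenParams
setClass("GenParams", representation(
  baselineRate = "numeric",
  trendTau = "numeric",
  periodH = "numeric",
  phaseH = "numeric",
  modDepth = "numeric",
  concentration = "numeric",
  flyCV = "numeric",
  phaseJitterH = "numeric",
  nDays = "numeric",
  binsPerDay = "numeric",
  seed = "integer"
))

setValidity("GenParams", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  one <- function(x) length(x) == 1L && !is.na(x)
  msgs <- c(
    chk(one(object@baselineRate) && object@baselineRate > 0,
        "baselineRate must be a single value > 0"),
    chk(one(object@trendTau) && object@trendTau > 0,
        "trendTau must be a single value > 0 (Inf allowed)"),
    chk(one(object@periodH) && object@periodH > 0,
        "periodH must be a single value > 0"),
    chk(one(object@phaseH) && is.finite(object@phaseH),
        "phaseH must be a single finite value"),
    chk(one(object@modDepth) && object@modDepth >= 0 && object@modDepth <= 1,
        "modDepth must be in [0, 1]"),
    chk(one(object@concentration) && object@concentration >= 0 &&
          is.finite(object@concentration),
        "concentration must be a single finite value >= 0"),
    chk(one(object@flyCV) && object@flyCV >= 0 && is.finite(object@flyCV),
        "flyCV must be a single finite value >= 0"),
    chk(one(object@phaseJitterH) && object@phaseJitterH >= 0 &&
          is.finite(object@phaseJitterH),
        "phaseJitterH must be a single finite value >= 0"),
    chk(one(object@nDays) && object@nDays >= 1,
        "nDays must be a single value >= 1"),
    chk(one(object@binsPerDay) && object@binsPerDay >= 1 &&
          object@binsPerDay == round(object@binsPerDay),
        "binsPerDay must be a single whole number >= 1"),
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed must be a single integer")
  )
  if (length(msgs)) msgs else TRUE
})

#' One fly's binned egg-count record
#'
#' A time series of non-negative integer egg counts in fixed-width bins
#' (4 h by default, six per day), with a per-bin light annotation:
#' `"L"` lights on, `"D"` lights off, `"DDsub"` subjective day under constant
#' darkness.
#'
#' @slot flyId character scalar identifying the fly.
#' @slot genotype character scalar.
#' @slot timesH strictly increasing bin-start times, hours from record start.
#' @slot binWidthH sampling interval in hours.
#' @slot counts non-negative integer counts, one per bin.
#' @slot light per-bin label in `c("L", "D", "DDsub")`.
#' @seealso [EggRecord()], [generateFly()], [readEggRecords()]
#' @exportClass EggRecord
setClass("EggRecord", representation(
  flyId = "character",
  genotype = "character",
  timesH = "numeric",
  binWidthH = "numeric",
  counts = "integer",
  light = "character"
))

setValidity("EggRecord", function(object) {
  n <- length(object@timesH)
  msgs <- character()
  if (length(object@counts) != n || length(object@light) != n)
    msgs <- c(msgs, "timesH, counts and light must have equal length")
  if (n > 1 && any(diff(object@timesH) <= 0))
    msgs <- c(msgs, "timesH must be strictly increasing")
  if (any(is.na(object@counts)) || any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (!all(object@light %in% .LIGHT_LEVELS))
    msgs <- c(msgs, sprintf("light labels must be in {%s}",
                            paste(.LIGHT_LEVELS, collapse = ", ")))
  if (length(object@binWidthH) != 1L || object@binWidthH <= 0)
    msgs <- c(msgs, "binWidthH must be a single value > 0")
  if (length(msgs)) msgs else TRUE
})

#' A detrended egg-count series
#'
#' Ratios D(i) = E(i)/T(i) of observed counts to a moving-average trend.
#' Bins where the trend is zero are missing (`NA`), never infinite. For
#' population averages (see [averagePopulation()]) the `nContrib` slot holds
#' the number of flies contributing to each bin; for single-fly series it is
#' empty.
#'
#' @slot timesH bin-start times, as in the source [EggRecord-class].
#' @slot values dimensionless ratios >= 0, `NA` where undefined.
#' @slot sourceFly id of the source fly, or `"average"`.
#' @slot nContrib integer count of contributing series per bin (averages
#'   only).
#' @exportClass DetrendedSeries
setClass("DetrendedSeries", representation(
  timesH = "numeric",
  values = "numeric",
  sourceFly = "character",
  nContrib = "integer"
))

setValidity("DetrendedSeries", function(object) {
  msgs <- character()
  if (length(object@values) != length(object@timesH))
    msgs <- c(msgs, "values and timesH must have equal length")
  if (length(object@timesH) > 1 && any(diff(object@timesH) <= 0))
    msgs <- c(msgs, "timesH must be strictly increasing")
  if (any(object@values < 0, na.rm = TRUE))
    msgs <- c(msgs, "detrended values must be >= 0 or NA")
  if (length(object@nContrib) &&
      length(object@nContrib) != length(object@timesH))
    msgs <- c(msgs, "nContrib must be empty or match timesH in length")
  if (length(msgs)) msgs else TRUE
})

#' Lomb-Scargle periodogram with randomization significance lines
#'
#' Scanned periods (a grid uniform in frequency), classical
#' variance-normalized Lomb-Scargle powers, shuffle-derived power thresholds
#' at the requested significance levels, and the local maxima of the power
#' curve with their topographic prominences.
#'
#' @slot periodsH scanned periods in hours, increasing (frequency
#'   decreasing).
#' @slot power normalized power per period (>= 0).
#' @slot sigLines named numeric, significance level -> power threshold
#'   (names are the levels, e.g. `"0.05"`); empty if not computed.
#' @slot nRand number of value shuffles behind `sigLines`.
#' @slot seed RNG seed used for the shuffles.
#' @slot peaks data.frame of all local maxima: `period_h`, `power`,
#'   `prominence`.
#' @seealso [computePeriodogram()], [lombScargle()], [findPeaks()]
#' @exportClass Periodogram
setClass("Periodogram", representation(
  periodsH = "numeric",
  power = "numeric",
  sigLines = "numeric",
  nRand = "integer",
  seed = "integer",
  peaks = "data.frame"
))

setValidity("Periodogram", function(object) {
  msgs <- character()
  if (length(object@power) != length(object@periodsH))
    msgs <- c(msgs, "power and periodsH must have equal length")
  if (any(object@power < -1e-12, na.rm = TRUE))
    msgs <- c(msgs, "powers must be >= 0")
  if (length(object@sigLines) >= 2) {
    lv <- as.numeric(names(object@sigLines))
    if (any(is.na(lv)))
      msgs <- c(msgs, "sigLines must be named by numeric levels")
    else if (any(diff(object@sigLines[order(lv)]) > 1e-12))
      msgs <- c(msgs, "stricter levels must have thresholds at least as high")
  }
  if (length(msgs)) msgs else TRUE
})

#' A rhythmicity call for a fly or a genotype
#'
#' @slot subject fly id or genotype name.
#' @slot label one of `"strong"`, `"weak"`, `"arrhythmic"`.
#' @slot periodH estimated period in hours (`NA` when arrhythmic).
#' @slot uncertaintyH half-width of the decisive peak at half prominence
#'   (`NA` when arrhythmic).
#' @slot peakPower power of the decisive peak (`NA` when no peak).
#' @slot ruleTrace which decision clause fired.
#' @seealso [classifyGenotype()], [classifyIndividual()]
#' @exportClass RhythmCall
setClass("RhythmCall", representation(
  subject = "character",
  label = "character",
  periodH = "numeric",
  uncertaintyH = "numeric",
  peakPower = "numeric",
  ruleTrace = "character"
))

setValidity("RhythmCall", function(object) {
  msgs <- character()
  if (!object@label %in% c("strong", "weak", "arrhythmic"))
    msgs <- c(msgs, "label must be strong, weak or arrhythmic")
  if (object@label != "arrhythmic" && is.na(object@periodH))
    msgs <- c(msgs, "rhythmic calls must carry a period")
  if (length(msgs)) msgs else TRUE
})

#' Cluster-level bipartite connectivity between neuron sets
#'
#' Directed cluster-pair totals of retained synapse counts between two sides
#' of a bipartite network (e.g. circadian clock clusters vs oviposition
#' clusters), the retained per-neuron edges, and the names that could not be
#' resolved to a cluster. Weak connections (<= 2 synapses) never contribute.
#'
#' @slot totals data.frame `cluster_pre`, `cluster_post`, `weight`,
#'   `n_edges`.
#' @slot edges data.frame of retained neuron-level edges with resolved
#'   clusters.
#' @slot unresolved neuron names present in the edge list but absent from the
#'   cluster map.
#' @slot minClass minimum retained strength class (`"intermediate"` or
#'   `"strong"`).
#' @seealso [bipartiteConnectivity()], [bidirectionality()]
#' @exportClass ConnectivityReport
setClass("ConnectivityReport", representation(
  totals = "data.frame",
  edges = "data.frame",
  unresolved = "character",
  minClass = "character"
))

setValidity("ConnectivityReport", function(object) {
  msgs <- character()
  if (!object@minClass %in% c("intermediate", "strong"))
    msgs <- c(msgs, "minClass must be 'intermediate' or 'strong'")
  need <- c("cluster_pre", "cluster_post", "weight", "n_edges")
  if (!all(need %in% names(object@totals)))
    msgs <- c(msgs, "totals must have cluster_pre, cluster_post, weight, n_edges")
  if (length(msgs)) msgs else TRUE
})

#' Analysis configuration for the egg-laying rhythm pipeline
#'
#' Bundles the tunable constants of the pipeline: the detrending window, the
#' period grid, significance levels and number of randomizations, the
#' genotype and individual classification windows, and the weak-rhythm power
#' cutoff.
#'
#' @slot detrendWindow moving-average window in bins (default 6).
#' @slot periodRange scanned period range in hours, `c(low, high)`.
#' @slot oversampling frequency oversampling factor relative to 1/span.
#' @slot levels significance levels for the shuffle lines.
#' @slot nRand number of value shuffles per significance line.
#' @slot genotypeWindow period window (hours) for the genotype rule.
#' @slot individualWindow period window (hours) for the weak-rhythm rule.
#' @slot weakPowerCutoff minimum peak power for a weak call.
#' @slot prominenceFrac peak prominence threshold as a fraction of the
#'   maximum in-window power.
#' @slot seed master seed for all randomized stages.
#' @slot segment `"full"` to analyze whole records, `"DD"` to restrict to
#'   bins in constant darkness.
#' @seealso [analysisConfig()], [runGenotypeAnalysis()]
#' @exportClass AnalysisConfig
setClass("AnalysisConfig", representation(
  detrendWindow = "integer",
  periodRange = "numeric",
  oversampling = "numeric",
  levels = "numeric",
  nRand = "integer",
  genotypeWindow = "numeric",
  individualWindow = "numeric",
  weakPowerCutoff = "numeric",
  prominenceFrac = "numeric",
  seed = "integer",
  segment = "character"
))

setValidity("AnalysisConfig", function(object) {
  msgs <- character()
  if (object@detrendWindow < 2)
    msgs <- c(msgs, "detrendWindow must be >= 2")
  okWin <- function(w) length(w) == 2 && all(is.finite(w)) && w[1] < w[2]
  if (!okWin(object@periodRange) || object@periodRange[1] <= 0)
    msgs <- c(msgs, "periodRange must be 0 < low < high")
  if (!okWin(object@genotypeWindow))
    msgs <- c(msgs, "genotypeWindow must be an ordered pair")
  if (!okWin(object@individualWindow))
    msgs <- c(msgs, "individualWindow must be an ordered pair")
  if (any(object@levels <= 0 | object@levels >= 1))
    msgs <- c(msgs, "significance levels must lie in (0, 1)")
  if (object@oversampling < 1)
    msgs <- c(msgs, "oversampling must be >= 1")
  if (!object@segment %in% c("full", "DD"))
    msgs <- c(msgs, "segment must be 'full' or 'DD'")
  if (length(msgs)) msgs else TRUE
})

#' Result bundle of a genotype-level analysis
#'
#' @slot genotype genotype analyzed.
#' @slot averaged the population-averaged [DetrendedSeries-class].
#' @slot genotypePg [Periodogram-class] of the averaged series, with
#'   significance lines.
#' @slot genotypeCall [RhythmCall-class] at genotype level.
#' @slot flyCalls list of per-fly [RhythmCall-class] objects.
#' @slot periods data.frame per fly: `fly_id`, `label`, `period_h`,
#'   `peak_power`.
#' @slot proportions named numeric: `n_rhythmic`, `n_total`, `fraction`.
#' @slot config the [AnalysisConfig-class] used.
#' @exportClass PopulationResult
setClass("PopulationResult", representation(
  genotype = "character",
  averaged = "DetrendedSeries",
  genotypePg = "Periodogram",
  genotypeCall = "RhythmCall",
  flyCalls = "list",
  periods = "data.frame",
  proportions = "numeric",
  config = "AnalysisConfig"
))
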