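#' Construct generative parameters
#'
#' Convenience constructor for [GenParams-class] with defaults that emulate a
#' week-long run of the egg collection device: 4-h bins (6/day) over 7 days,
#' a baseline of 2 eggs/h that decays with a 120-h time constant (the clear
#' downward trend of egg deposition by mated females), and a 24-h modulation
#' peaking 10 h after lights-on (an evening egg-laying peak).
#'
#' @param baselineRate expected eggs per hour at t = 0.
#' @param trendTau trend time constant in hours (`Inf` disables the trend).
#' @param periodH circadian period in hours.
#' @param phaseH peak time, hours after (subjective) lights-on.
#' @param modDepth modulation depth in \[0, 1\]; 0 gives arrhythmic records.
#' @param concentration bump sharpness (0 = cosine).
#' @param flyCV coefficient of variation of per-fly baselines.
#' @param phaseJitterH SD of per-fly phase offsets (hours).
#' @param nDays record length in days.
#' @param binsPerDay bins per day.
#' @param seed integer RNG seed.
#' @return a validated [GenParams-class] object.
#' @examples
#' p <- GenParams(modDepth = 0, trendTau = Inf)
#' generateFly(p, 1)
#' @export
GenParams <- function(baselineRate = 2, trendTau = 120, periodH = 24,
                      phaseH = 10, modDepth = 0.5, concentration = 2,
                      flyCV = 0.3, phaseJitterH = 1, nDays = 7,
                      binsPerDay = 6, seed = 1L) {
  new("GenParams", baselineRate = baselineRate, trendTau = trendTau,
      periodH = periodH, phaseH = phaseH, modDepth = modDepth,
      concentration = concentration, flyCV = flyCV,
      phaseJitterH = phaseJitterH, nDays = nDays, binsPerDay = binsPerDay,
      seed = as.integer(seed))
}

#' Construct an egg record
#'
#' @param flyId,genotype identifiers.
#' @param timesH bin-start times in hours.
#' @param counts non-negative integer counts per bin.
#' @param binWidthH bin width in hours.
#' @param light per-bin light labels (`"L"`, `"D"`, `"DDsub"`); defaults to
#'   an LD 12:12 labelling of the times.
#' @return an [EggRecord-class].
#' @export
EggRecord <- function(flyId, genotype, timesH, counts, binWidthH = 4,
                      light = NULL) {
  if (is.null(light)) light <- lightLabelsFor(timesH, ldDays = Inf)
  new("EggRecord", flyId = as.character(flyId),
      genotype = as.character(genotype), timesH = as.numeric(timesH),
      binWidthH = as.numeric(binWidthH), counts = as.integer(round(counts)),
      light = light)
}

# Zero-mean, unit-peak periodic bump with sharpness kappa, evaluated at phase
# angle theta (radians; peak at theta = 0). kappa = 0 degenerates to cos.
circadianBump <- function(theta, kappa) {
  if (kappa < 1e-8) return(cos(theta))
  i0 <- besselI(kappa, 0)
  (exp(kappa * cos(theta)) - i0) / (exp(kappa) - i0)
}

# Expected rate (eggs/h) at time t for one fly.
flyRate <- function(t, baseline, trendTau, periodH, phaseH, modDepth, kappa) {
  trend <- if (is.finite(trendTau)) exp(-t / trendTau) else 1
  theta <- 2 * pi * ((t - phaseH) %% periodH) / periodH
  baseline * trend * (1 + modDepth * circadianBump(theta, kappa))
}

# Integral of the rate over each bin (composite Simpson, 8 subintervals).
binMeans <- function(starts, width, baseline, trendTau, periodH, phaseH,
                     modDepth, kappa) {
  nSub <- 8L
  h <- width / nSub
  wts <- c(1, rep(c(4, 2), length.out = nSub - 1L), 1)
  offs <- seq(0, width, by = h)
  vapply(starts, function(t0) {
    y <- flyRate(t0 + offs, baseline, trendTau, periodH, phaseH, modDepth,
                 kappa)
    sum(wts * y) * h / 3
  }, numeric(1))
}

# LD 12:12 light labels: lights on during the first half of each day; after
# `ldDays` days the record is in constant darkness and the subjective day is
# labelled DDsub.
lightLabelsFor <- function(timesH, ldDays = Inf) {
  tod <- timesH %% 24
  day <- floor(timesH / 24)
  ifelse(tod < 12, ifelse(day < ldDays, "L", "DDsub"), "D")
}

#' Simulate one fly's egg-count record
#'
#' Draws a single record from the generative model in [GenParams-class]:
#' the fly's baseline is lognormal with mean `baselineRate` and CV `flyCV`,
#' its phase offset is Gaussian with SD `phaseJitterH`, and each bin's count
#' is Poisson with mean equal to the integral of the rate over the bin.
#' The output is fully determined by `(params@seed, flyIndex)`.
#'
#' @param params a [GenParams-class] object.
#' @param flyIndex positive integer index of the fly; distinct indices give
#'   independent flies under the same seed.
#' @param genotype genotype label stored in the record.
#' @param ldDays number of initial days under LD 12:12; later days are
#'   labelled as constant darkness (default: whole record in LD).
#' @return an [EggRecord-class].
#' @examples
#' rec <- generateFly(GenParams(seed = 7), 1)
#' sum(eggCounts(rec))
#' @export
generateFly <- function(params, flyIndex, genotype = "synthetic",
                        ldDays = Inf) {
  validObject(params)
  stopIfNot1(length(flyIndex) == 1 && flyIndex >= 1 &&
               flyIndex == round(flyIndex),
             "flyIndex must be a single positive integer")
  binWidth <- 24 / params@binsPerDay
  nBins <- as.integer(round(params@nDays * params@binsPerDay))
  starts <- (seq_len(nBins) - 1) * binWidth
  withSeed(mixSeed(params@seed, flyIndex), {
    sdlog <- sqrt(log(1 + params@flyCV^2))
    b <- stats::rlnorm(1, meanlog = log(params@baselineRate) - sdlog^2 / 2,
                       sdlog = sdlog)
    delta <- stats::rnorm(1, 0, params@phaseJitterH)
    mu <- binMeans(starts, binWidth, b, params@trendTau, params@periodH,
                   params@phaseH + delta, params@modDepth,
                   params@concentration)
    counts <- stats::rpois(nBins, mu)
  })
  new("EggRecord", flyId = sprintf("fly_%03d", as.integer(flyIndex)),
      genotype = genotype, timesH = starts, binWidthH = binWidth,
      counts = as.integer(counts),
      light = lightLabelsFor(starts, ldDays))
}

#' Simulate a mixed population of rhythmic and arrhythmic flies
#'
#' Generates `nFlies` records; `round(fracArrhythmic * nFlies)` of them are
#' drawn with the modulation depth forced to zero (their expected counts
#' depend on time only through the trend), the rest with `params@modDepth`.
#' Arrhythmic flies take the lowest indices; all records are reproducible
#' under `params@seed`.
#'
#' @param params a [GenParams-class] object.
#' @param nFlies number of flies (>= 1).
#' @param fracArrhythmic fraction in \[0, 1\] generated without a circadian
#'   component.
#' @param genotype genotype label for all records.
#' @param ldDays as in [generateFly()].
#' @return a list of [EggRecord-class] with unique fly ids.
#' @examples
#' pop <- generatePopulation(GenParams(seed = 2), nFlies = 5,
#'                           fracArrhythmic = 0.4)
#' vapply(pop, flyId, "")
#' @export
generatePopulation <- function(params, nFlies, fracArrhythmic = 0,
                               genotype = "synthetic", ldDays = Inf) {
  stopIfNot1(length(nFlies) == 1 && nFlies >= 1, "nFlies must be >= 1")
  stopIfNot1(fracArrhythmic >= 0 && fracArrhythmic <= 1,
             "fracArrhythmic must be in [0, 1]")
  nArr <- round(fracArrhythmic * nFlies)
  flat <- GenParams(baselineRate = params@baselineRate,
                    trendTau = params@trendTau, periodH = params@periodH,
                    phaseH = params@phaseH, modDepth = 0,
                    concentration = params@concentration,
                    flyCV = params@flyCV,
                    phaseJitterH = params@phaseJitterH, nDays = params@nDays,
                    binsPerDay = params@binsPerDay, seed = params@seed)
  lapply(seq_len(nFlies), function(i) {
    p <- if (i <= nArr) flat else params
    generateFly(p, i, genotype = genotype, ldDays = ldDays)
  })
}

# Neuron rosters used by the connectome fixture generator. Clock-neuron names
# follow the common cluster nomenclature (LNd1-6, 5th-sLNv, LPN-L for the
# left-hemisphere LPN); oviposition-circuit neurons use their instance names.
fixtureRosters <- function() {
  list(
    sLNv = paste0("sLNv-", 1:4),
    lLNv = paste0("lLNv-", 1:4),
    E1 = c("LNd4", "LNd5"),
    E2 = c("LNd6", "5th-sLNv"),
    E3 = c("LNd1", "LNd2", "LNd3"),
    DN1a = paste0("DN1a-", 1:2),
    DN1p = paste0("DN1p-", 1:2),
    LPN = c("LPN-1", "LPN-2", "LPN-3", "LPN-L"),
    oviIN = "oviIN",
    oviEN = "oviEN",
    oviDN = paste0("oviDN-", 1:5),
    pC1a = "pC1a", pC1b = "pC1b", pC1c = "pC1c", pC1d = "pC1d", pC1e = "pC1e",
    U = "U-1",
    G = "G-1"
  )
}

.STRENGTH_RANGES <- list(weak = c(1L, 2L), intermediate = c(3L, 9L),
                         strong = c(10L, 40L))

#' Generate a synthetic connectome edge-list fixture
#'
#' Emits neuPrint-style connection rows (one per pre/post neuron pair) whose
#' summed weights fall in a requested strength class per directed cluster
#' pair: weak = 1-2, intermediate = 3-9, strong = > 9 synapses. Neuron
#' rosters follow the standard clock / oviposition cluster nomenclature. The
#' weights are synthetic; only the topology and the strength classes are
#' meaningful.
#'
#' @param spec data.frame with columns `pre_cluster`, `post_cluster`,
#'   `class` (one of weak/intermediate/strong); one row per directed cluster
#'   pair to realize. A zero-row spec yields an empty edge list.
#' @param seed integer seed making the fixture reproducible.
#' @return data.frame with columns `bodyId_pre`, `instance_pre`,
#'   `bodyId_post`, `instance_post`, `weight`.
#' @examples
#' spec <- data.frame(pre_cluster = "E1", post_cluster = "oviIN",
#'                    class = "strong")
#' generateConnectomeFixture(spec, seed = 1)
#' @export
generateConnectomeFixture <- function(spec, seed = 1L) {
  cols <- c("pre_cluster", "post_cluster", "class")
  stopIfNot1(is.data.frame(spec) && all(cols %in% names(spec)),
             "spec must be a data.frame with pre_cluster, post_cluster, class")
  empty <- data.frame(bodyId_pre = integer(), instance_pre = character(),
                      bodyId_post = integer(), instance_post = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (!nrow(spec)) return(empty)
  bad <- setdiff(unique(spec$class), names(.STRENGTH_RANGES))
  stopIfNot1(length(bad) == 0, "unknown strength class: %s",
             paste(bad, collapse = ", "))
  rosters <- fixtureRosters()
  badCl <- setdiff(unique(c(spec$pre_cluster, spec$post_cluster)),
                   names(rosters))
  stopIfNot1(length(badCl) == 0, "unknown cluster: %s",
             paste(badCl, collapse = ", "))
  allNames <- unlist(rosters, use.names = FALSE)
  bodyIds <- stats::setNames(1000000L + seq_along(allNames) * 101L, allNames)
  withSeed(mixSeed(seed, 0L), {
    out <- lapply(seq_len(nrow(spec)), function(k) {
      pre <- rosters[[spec$pre_cluster[k]]]
      post <- rosters[[spec$post_cluster[k]]]
      rng <- .STRENGTH_RANGES[[spec$class[k]]]
      grid <- expand.grid(instance_pre = pre, instance_post = post,
                          stringsAsFactors = FALSE)
      grid$weight <- sample(seq(rng[1], rng[2]), nrow(grid), replace = TRUE)
      grid
    })
  })
  out <- do.call(rbind, out)
  data.frame(bodyId_pre = unname(bodyIds[out$instance_pre]),
             instance_pre = out$instance_pre,
             bodyId_post = unname(bodyIds[out$instance_post]),
             instance_post = out$instance_post,
             weight = as.integer(out$weight), stringsAsFactors = FALSE)
}
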