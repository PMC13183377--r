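#' Period grid for spectral scanning
#'
#' Builds the default scanning grid: uniform in frequency between
#' 1/`range[2]` and 1/`range[1]` cycles/h with a step of
#' 1/(`oversampling` * span), returned as periods in increasing order. The
#' default range 8-48 h starts at the Nyquist period of the 4-h sampling
#' cadence and covers the circadian band.
#'
#' @param timesH observation times in hours (only their span matters).
#' @param range period range in hours, `c(low, high)`.
#' @param oversampling frequency oversampling factor relative to 1/span.
#' @return numeric vector of periods in hours, increasing.
#' @export
periodGrid <- function(timesH, range = c(8, 48), oversampling = 10) {
  stopIfNot1(length(range) == 2 && range[1] > 0 && range[1] < range[2],
             "range must be 0 < low < high")
  span <- diff(base::range(timesH))
  stopIfNot1(is.finite(span) && span > 0, "times must span a positive range")
  df <- 1 / (oversampling * span)
  freqs <- seq(1 / range[2], 1 / range[1], by = df)
  rev(1 / freqs)
}

# Per-frequency orthogonal sinusoid basis with the classical time-offset tau
# (tan 2*omega*tau = sum sin 2*omega*t / sum cos 2*omega*t), rows normalized
# to unit sum of squares. Power at a frequency is then the squared projection
# of the centered values onto the two rows, over twice the sample variance.
lsBasis <- function(timesH, periodsH) {
  omega <- 2 * pi / periodsH
  wt <- outer(omega, timesH)            # nfreq x n
  tau <- atan2(rowSums(sin(2 * wt)), rowSums(cos(2 * wt))) / (2 * omega)
  arg <- wt - omega * tau
  C <- cos(arg)
  S <- sin(arg)
  C <- C / sqrt(rowSums(C^2))
  S <- S / sqrt(rowSums(S^2))
  list(C = C, S = S)
}

# Shared input scrubbing: drop missing pairs, check size and variance.
lsClean <- function(timesH, values) {
  keep <- is.finite(timesH) & is.finite(values)
  timesH <- timesH[keep]
  values <- values[keep]
  stopIfNot1(length(values) >= 4,
             "need at least 4 non-missing points (got %d)", length(values))
  stopIfNot1(stats::var(values) > 0, "series is constant: power is undefined")
  list(timesH = timesH, values = values)
}

#' Lomb-Scargle power spectrum
#'
#' Classical variance-normalized Lomb-Scargle periodogram for unevenly or
#' sparsely sampled series: at each scanned frequency, the variance reduction
#' of the least-squares sinusoid fit to the mean-centered values, divided by
#' twice the sample variance (n - 1 denominator). Under this normalization
#' the expected power of white noise at a fixed frequency is ~1, and the
#' power is invariant to adding a constant to the values, to positive
#' scaling, and to translating all times. Missing values are omitted
#' pairwise.
#'
#' @param timesH observation times in hours.
#' @param values series values (same length; `NA` allowed).
#' @param periodsH periods to scan, e.g. from [periodGrid()].
#' @return numeric power per period (>= 0).
#' @examples
#' t <- seq(0, 164, by = 4)
#' y <- sin(2 * pi * t / 24) + rnorm(length(t), 0, 0.1)
#' p <- periodGrid(t)
#' p[which.max(lombScargle(t, y, p))]
#' @export
lombScargle <- function(timesH, values, periodsH) {
  cl <- lsClean(timesH, values)
  b <- lsBasis(cl$timesH, periodsH)
  yc <- cl$values - mean(cl$values)
  drop((b$C %*% yc)^2 + (b$S %*% yc)^2) / (2 * stats::var(cl$values))
}

#' Randomization significance lines for the periodogram
#'
#' Thresholds the maximum scanned power against its null distribution under
#' repeated shuffling of the series: the values are permuted uniformly
#' without replacement while the times stay fixed, the maximum power over
#' the whole grid is recorded for each shuffle, and the threshold at level
#' alpha is the empirical (1 - alpha) quantile of those maxima. Because the
#' statistic is the grid-wide maximum, the lines control the family-wise
#' error over the scanned band. Deterministic given `seed`.
#'
#' @param timesH,values,periodsH as in [lombScargle()].
#' @param levels significance levels in (0, 1); default `c(0.05, 0.01)`.
#' @param nRand number of shuffles (default 1000; < 100 draws a warning).
#' @param seed integer seed for the shuffles.
#' @return named numeric vector of power thresholds, names = levels.
#' @export
significanceLines <- function(timesH, values, periodsH,
                              levels = c(0.05, 0.01), nRand = 1000L,
                              seed = 1L) {
  stopIfNot1(all(levels > 0 & levels < 1), "levels must lie in (0, 1)")
  nRand <- as.integer(nRand)
  if (nRand < 100L)
    warning("nRand < 100 gives unstable significance lines", call. = FALSE)
  cl <- lsClean(timesH, values)
  b <- lsBasis(cl$timesH, periodsH)
  n <- length(cl$values)
  yc <- cl$values - mean(cl$values)
  perm <- withSeed(mixSeed(seed, 0L),
                   vapply(seq_len(nRand), function(k) sample.int(n),
                          integer(n)))
  Y <- matrix(yc[perm], nrow = n)
  pw <- ((b$C %*% Y)^2 + (b$S %*% Y)^2) / (2 * stats::var(cl$values))
  maxp <- apply(pw, 2L, max)
  th <- stats::quantile(maxp, 1 - levels, names = FALSE, type = 7)
  stats::setNames(th, as.character(levels))
}

# Linear operator of the truncated centered moving average as an n x n
# matrix, matching movingAverage() exactly.
smoothingMatrix <- function(n, window) {
  window <- as.integer(window)
  left <- window %/% 2L
  right <- window - left - 1L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(i - left, 1L)
    hi <- min(i + right, n)
    M[i, lo:hi] <- 1 / (hi - lo + 1L)
  }
  M
}

#' Pipeline-aware significance lines from raw counts
#'
#' Randomization thresholds for the *detrended* analysis: each shuffle
#' permutes a fly's raw counts (times fixed), re-applies the moving-average
#' detrending, re-averages across flies, and records the maximum Lomb-Scargle
#' power over the grid. This keeps the spectral coloring introduced by the
#' detrending filter inside the null distribution: dividing by a one-day
#' moving average boosts noise power at intermediate periods and suppresses
#' it at long ones, so shuffling the already-detrended values (as
#' [significanceLines()] does) understates the null maximum and inflates the
#' false-positive rate of the screen. Deterministic given `seed`.
#'
#' @param counts numeric vector of one fly's counts, a matrix with one
#'   column per fly (bins in rows), or a list of count vectors each aligned
#'   to a prefix of `timesH` (truncated records of dead flies).
#' @param timesH bin times in hours (length = number of bins).
#' @param periodsH scanned period grid.
#' @param window moving-average detrending window (default 6).
#' @param levels significance levels in (0, 1).
#' @param nRand number of shuffles (default 1000).
#' @param seed integer seed.
#' @param keepIdx optional integer index of bins retained for the spectral
#'   step (defaults to all bins), e.g. to mirror missing bins in the
#'   observed series.
#' @return named numeric vector of power thresholds, names = levels.
#' @seealso [significanceLines()] for the plain value-shuffling form.
#' @export
pipelineSigLines <- function(counts, timesH, periodsH, window = 6L,
                             levels = c(0.05, 0.01), nRand = 1000L,
                             seed = 1L, keepIdx = NULL) {
  stopIfNot1(all(levels > 0 & levels < 1), "levels must lie in (0, 1)")
  if (!is.list(counts)) {
    counts <- as.matrix(counts)
    counts <- lapply(seq_len(ncol(counts)), function(j) counts[, j])
  }
  n <- length(timesH)
  stopIfNot1(all(lengths(counts) >= 1) && max(lengths(counts)) == n,
             "the longest record must match timesH in length")
  nRand <- as.integer(nRand)
  if (nRand < 100L)
    warning("nRand < 100 gives unstable significance lines", call. = FALSE)
  if (is.null(keepIdx)) keepIdx <- seq_len(n)
  b <- lsBasis(timesH[keepIdx], periodsH)
  smooth <- list()
  sumD <- matrix(0, n, nRand)
  cntD <- matrix(0, n, nRand)
  withSeed(mixSeed(seed, 0L), {
    for (j in seq_along(counts)) {
      nj <- length(counts[[j]])
      key <- as.character(nj)
      if (is.null(smooth[[key]])) smooth[[key]] <- smoothingMatrix(nj, window)
      perm <- vapply(seq_len(nRand), function(k) sample.int(nj), integer(nj))
      Pj <- matrix(counts[[j]][perm], nrow = nj)
      Dj <- Pj / (smooth[[key]] %*% Pj)
      ok <- is.finite(Dj)
      Dj[!ok] <- 0
      sumD[seq_len(nj), ] <- sumD[seq_len(nj), ] + Dj
      cntD[seq_len(nj), ] <- cntD[seq_len(nj), ] + ok
    }
  })
  Davg <- sumD / cntD
  Davg[cntD == 0] <- 0
  Davg <- Davg[keepIdx, , drop = FALSE]
  m <- nrow(Davg)
  Dc <- sweep(Davg, 2L, colMeans(Davg))
  v <- colSums(Dc^2) / (m - 1)
  v[v <= 0] <- Inf
  pw <- ((b$C %*% Dc)^2 + (b$S %*% Dc)^2) / rep(2 * v, each = nrow(b$C))
  maxp <- apply(pw, 2L, max)
  th <- stats::quantile(maxp, 1 - levels, names = FALSE, type = 7)
  stats::setNames(th, as.character(levels))
}

#' Compute a full periodogram object
#'
#' Convenience wrapper producing a [Periodogram-class]: power on the scanned
#' grid via [lombScargle()], shuffle significance lines via
#' [significanceLines()], and the local maxima of the power curve with their
#' topographic prominences.
#'
#' @param x a [DetrendedSeries-class], or numeric times when `values` is
#'   given.
#' @param values series values when `x` is a numeric time vector.
#' @param periodsH scan grid; defaults to [periodGrid()] of the times.
#' @param levels,nRand,seed passed to [significanceLines()]; set
#'   `nRand = 0` to skip the lines.
#' @return a [Periodogram-class].
#' @examples
#' rec <- generateFly(GenParams(seed = 3), 1)
#' pg <- computePeriodogram(detrendRecord(rec), nRand = 200)
#' pg
#' @export
computePeriodogram <- function(x, values = NULL, periodsH = NULL,
                               levels = c(0.05, 0.01), nRand = 1000L,
                               seed = 1L) {
  if (is(x, "DetrendedSeries")) {
    timesH <- x@timesH
    values <- x@values
  } else {
    stopIfNot1(is.numeric(x) && !is.null(values),
               "need a DetrendedSeries, or numeric times plus values")
    timesH <- x
  }
  if (is.null(periodsH)) periodsH <- periodGrid(timesH)
  power <- lombScargle(timesH, values, periodsH)
  sig <- if (nRand > 0)
    significanceLines(timesH, values, periodsH, levels, nRand, seed)
  else stats::setNames(numeric(0), character(0))
  new("Periodogram", periodsH = periodsH, power = power, sigLines = sig,
      nRand = as.integer(nRand), seed = as.integer(seed),
      peaks = peakCandidates(periodsH, power))
}

# All strict local maxima of the power curve with topographic prominence:
# height above the higher of the two saddle minima separating the peak from
# the nearest higher ground (or the grid edge).
peakCandidates <- function(periodsH, power) {
  n <- length(power)
  if (n < 3)
    return(data.frame(period_h = numeric(), power = numeric(),
                      prominence = numeric()))
  isMax <- Filter(function(i) power[i] > power[i - 1] && power[i] > power[i + 1],
                  seq(2L, n - 1L))
  prom <- vapply(isMax, function(i) {
    p <- power[i]
    left <- power[seq_len(i - 1)]
    higherL <- which(left > p)
    baseL <- min(left[seq(if (length(higherL)) max(higherL) else 1, i - 1)])
    right <- power[seq(i + 1, n)]
    higherR <- which(right > p)
    baseR <- min(right[seq_len(if (length(higherR)) min(higherR) else
      length(right))])
    p - max(baseL, baseR)
  }, numeric(1))
  data.frame(period_h = periodsH[isMax], power = power[isMax],
             prominence = prom)
}

#' Peaks of a periodogram inside a period window
#'
#' Local maxima of the power curve whose period lies in `[window[1],
#' window[2]]` (bounds inclusive) and whose topographic prominence is at
#' least `prominenceFrac` times the maximum in-window power. Maxima are
#' determined on the full grid, so a window endpoint counts only if it is
#' locally maximal within the whole scan. Sorted by power, descending.
#'
#' @param pg a [Periodogram-class].
#' @param window period window in hours, `c(low, high)`.
#' @param prominenceFrac prominence threshold as a fraction of the maximum
#'   in-window power (default 0.2).
#' @return data.frame `period_h`, `power`, `prominence` (possibly 0 rows).
#' @export
findPeaks <- function(pg, window, prominenceFrac = 0.2) {
  stopIfNot1(length(window) == 2 && window[1] < window[2],
             "window must be an ordered pair")
  rng <- range(pg@periodsH)
  stopIfNot1(window[2] > rng[1] && window[1] < rng[2],
             "scan window [%g, %g] is outside the scanned range", window[1],
             window[2])
  inWin <- pg@periodsH >= window[1] & pg@periodsH <= window[2]
  stopIfNot1(any(inWin), "no scanned periods fall inside the window")
  pk <- pg@peaks
  pk <- pk[pk$period_h >= window[1] & pk$period_h <= window[2], , drop = FALSE]
  thr <- prominenceFrac * max(pg@power[inWin])
  pk <- pk[pk$prominence >= thr, , drop = FALSE]
  pk[order(-pk$power, pk$period_h), , drop = FALSE]
}

#' Period of the dominant in-window peak
#'
#' Period of the highest peak found by [findPeaks()] inside the window. The
#' uncertainty is the half-width of that peak at half its prominence, read
#' off the power curve by linear interpolation. When two in-window peaks tie
#' exactly in power, the smaller period is returned and `tie` is set. With no
#' in-window peak the result carries `NA`s rather than raising an error.
#'
#' @inheritParams findPeaks
#' @return list with `period_h`, `uncertainty_h`, `power`, `tie`.
#' @export
estimatePeriod <- function(pg, window, prominenceFrac = 0.2) {
  pk <- findPeaks(pg, window, prominenceFrac)
  if (!nrow(pk))
    return(list(period_h = NA_real_, uncertainty_h = NA_real_,
                power = NA_real_, tie = FALSE))
  best <- pk[pk$power == max(pk$power), , drop = FALSE]
  tie <- nrow(best) > 1
  best <- best[which.min(best$period_h), , drop = FALSE]
  i <- which(pg@periodsH == best$period_h)[1]
  level <- best$power - best$prominence / 2
  list(period_h = best$period_h,
       uncertainty_h = peakHalfWidth(pg@periodsH, pg@power, i, level),
       power = best$power, tie = tie)
}

# Half-width of the peak at index i at the given power level, via linear
# interpolation of the crossings on either side (grid edge if no crossing).
peakHalfWidth <- function(periodsH, power, i, level) {
  n <- length(power)
  cross <- function(idx, dir) {
    j <- idx
    while (j + dir >= 1 && j + dir <= n && power[j + dir] > level) j <- j + dir
    if (j + dir < 1 || j + dir > n) return(periodsH[j])
    p1 <- power[j]; p2 <- power[j + dir]
    frac <- (p1 - level) / (p1 - p2)
    periodsH[j] + frac * (periodsH[j + dir] - periodsH[j])
  }
  (cross(i, 1L) - cross(i, -1L)) / 2
}
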