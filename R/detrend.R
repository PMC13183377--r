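#' Moving-average trend of an egg-count series
#'
#' Estimates the slow trend T of a count series with a centered moving
#' average (default window 6 bins, one day at the 4-h cadence). For an even
#' window of width w the window at bin i spans the w/2 bins to the left, the
#' bin itself and the w/2 - 1 bins to the right; near the edges the mean is
#' taken over the truncated window, so the trend has the same length as the
#' input. These centering and edge conventions are fixed by the package and
#' pinned by its tests.
#'
#' @param x numeric vector of counts, or an [EggRecord-class].
#' @param window window width in bins (>= 2; default 6).
#' @return numeric trend vector, same length as the input.
#' @examples
#' movingAverage(rep(c(0, 0, 6, 0, 0, 0), 7))
#' @export
setGeneric("movingAverage", function(x, window = 6L)
  standardGeneric("movingAverage"))

#' @rdname movingAverage
setMethod("movingAverage", "numeric", function(x, window = 6L) {
  window <- as.integer(window)
  stopIfNot1(window >= 2, "window must be >= 2")
  n <- length(x)
  stopIfNot1(n >= window,
             "record (%d points) is shorter than the window (%d)", n, window)
  left <- window %/% 2L
  right <- window - left - 1L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - left, 1L)
  hi <- pmin(i + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
})

#' @rdname movingAverage
setMethod("movingAverage", "EggRecord", function(x, window = 6L) {
  movingAverage(as.numeric(x@counts), window)
})

# Core ratio: D = E / T with T = 0 mapped to NA (missing), never Inf.
detrendRatio <- function(values, trend) {
  stopIfNot1(length(values) == length(trend),
             "series and trend lengths differ (%d vs %d)",
             length(values), length(trend))
  ifelse(trend > 0, values / trend, NA_real_)
}

#' Detrend an egg-count record
#'
#' Divides the observed counts E pointwise by the moving-average trend T,
#' giving the dimensionless series D(i) = E(i)/T(i). Bins where T(i) = 0
#' (a whole window without eggs) are marked missing. Over a long stationary
#' record the mean of D is close to 1.
#'
#' @param record an [EggRecord-class], or a numeric vector of values when
#'   `timesH` is given.
#' @param window moving-average window passed to [movingAverage()] when
#'   `trend` is not supplied.
#' @param trend optional precomputed trend (same length as the record).
#' @param timesH bin times when `record` is a plain numeric vector.
#' @return a [DetrendedSeries-class].
#' @examples
#' rec <- generateFly(GenParams(seed = 1), 1)
#' d <- detrendRecord(rec)
#' mean(seriesValues(d), na.rm = TRUE)
#' @export
detrendRecord <- function(record, window = 6L, trend = NULL, timesH = NULL) {
  if (is(record, "EggRecord")) {
    values <- as.numeric(record@counts)
    times <- record@timesH
    id <- record@flyId
  } else {
    stopIfNot1(is.numeric(record) && !is.null(timesH),
               "need an EggRecord, or a numeric vector plus timesH")
    values <- as.numeric(record)
    times <- as.numeric(timesH)
    id <- "series"
  }
  if (is.null(trend)) trend <- movingAverage(values, window)
  new("DetrendedSeries", timesH = times,
      values = detrendRatio(values, trend), sourceFly = id,
      nContrib = integer(0))
}

#' Average detrended series across flies
#'
#' Per-bin mean of the detrended series over all flies with a non-missing
#' value at that bin, on a shared time grid. Averaging individual replicates
#' improves the signal-to-noise ratio of the common circadian component,
#' which is the basis of the genotype-level rhythmicity assessment. Truncated
#' records (e.g. flies that died) contribute only while they have data. Bins
#' where no series contributes are missing.
#'
#' @param series list of [DetrendedSeries-class] sharing one bin grid (a
#'   shorter series must match a prefix of the longest grid).
#' @return a [DetrendedSeries-class] with `sourceFly = "average"` and
#'   per-bin contributor counts in `nContrib`.
#' @export
averagePopulation <- function(series) {
  stopIfNot1(is.list(series) && length(series) >= 1,
             "need at least one detrended series")
  stopIfNot1(all(vapply(series, is, TRUE, "DetrendedSeries")),
             "all elements must be DetrendedSeries")
  grids <- lapply(series, binTimes)
  ref <- grids[[which.max(lengths(grids))]]
  ok <- vapply(grids, function(g)
    isTRUE(all.equal(g, ref[seq_along(g)], tolerance = 1e-8)), TRUE)
  stopIfNot1(all(ok), "series do not share a common time grid")
  mat <- matrix(NA_real_, nrow = length(ref), ncol = length(series))
  for (j in seq_along(series))
    mat[seq_along(series[[j]]@values), j] <- series[[j]]@values
  nContrib <- as.integer(rowSums(!is.na(mat)))
  avg <- rowMeans(mat, na.rm = TRUE)
  avg[nContrib == 0L] <- NA_real_
  new("DetrendedSeries", timesH = ref, values = avg, sourceFly = "average",
      nContrib = nContrib)
}
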