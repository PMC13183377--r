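#' Accessors for package classes
#'
#' Small accessor generics so user code never reaches into slots: `flyId()`,
#' `genotypeOf()`, `binTimes()`, `eggCounts()`, `lightLabels()`, `seriesValues()`,
#' `scannedPeriods()`, `lsPower()`, `sigLines()`, `peakTable()`, `callLabel()`,
#' `callPeriod()`, `reportTotals()`, `reportEdges()`.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flyId", function(x) standardGeneric("flyId"))
#' @rdname accessors
#' @export
setGeneric("genotypeOf", function(x) standardGeneric("genotypeOf"))
#' @rdname accessors
#' @export
setGeneric("binTimes", function(x) standardGeneric("binTimes"))
#' @rdname accessors
#' @export
setGeneric("eggCounts", function(x) standardGeneric("eggCounts"))
#' @rdname accessors
#' @export
setGeneric("lightLabels", function(x) standardGeneric("lightLabels"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("scannedPeriods", function(x) standardGeneric("scannedPeriods"))
#' @rdname accessors
#' @export
setGeneric("lsPower", function(x) standardGeneric("lsPower"))
#' @rdname accessors
#' @export
setGeneric("sigLines", function(x) standardGeneric("sigLines"))
#' @rdname accessors
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))
#' @rdname accessors
#' @export
setGeneric("callLabel", function(x) standardGeneric("callLabel"))
#' @rdname accessors
#' @export
setGeneric("callPeriod", function(x) standardGeneric("callPeriod"))
#' @rdname accessors
#' @export
setGeneric("reportTotals", function(x) standardGeneric("reportTotals"))
#' @rdname accessors
#' @export
setGeneric("reportEdges", function(x) standardGeneric("reportEdges"))

#' @rdname accessors
setMethod("flyId", "EggRecord", function(x) x@flyId)
#' @rdname accessors
setMethod("genotypeOf", "EggRecord", function(x) x@genotype)
#' @rdname accessors
setMethod("binTimes", "EggRecord", function(x) x@timesH)
#' @rdname accessors
setMethod("eggCounts", "EggRecord", function(x) x@counts)
#' @rdname accessors
setMethod("lightLabels", "EggRecord", function(x) x@light)
#' @rdname accessors
setMethod("binTimes", "DetrendedSeries", function(x) x@timesH)
#' @rdname accessors
setMethod("seriesValues", "DetrendedSeries", function(x) x@values)
#' @rdname accessors
setMethod("flyId", "DetrendedSeries", function(x) x@sourceFly)
#' @rdname accessors
setMethod("scannedPeriods", "Periodogram", function(x) x@periodsH)
#' @rdname accessors
setMethod("lsPower", "Periodogram", function(x) x@power)
#' @rdname accessors
setMethod("sigLines", "Periodogram", function(x) x@sigLines)
#' @rdname accessors
setMethod("peakTable", "Periodogram", function(x) x@peaks)
#' @rdname accessors
setMethod("callLabel", "RhythmCall", function(x) x@label)
#' @rdname accessors
setMethod("callPeriod", "RhythmCall", function(x) x@periodH)
#' @rdname accessors
setMethod("reportTotals", "ConnectivityReport", function(x) x@totals)
#' @rdname accessors
setMethod("reportEdges", "ConnectivityReport", function(x) x@edges)

setMethod("show", "EggRecord", function(object) {
  cat(sprintf("EggRecord: fly %s (%s), %d bins of %g h, %d eggs total\n",
              object@flyId, object@genotype, length(object@counts),
              object@binWidthH, sum(object@counts)))
})

setMethod("show", "DetrendedSeries", function(object) {
  cat(sprintf("DetrendedSeries [%s]: %d bins, %d missing\n",
              object@sourceFly, length(object@values),
              sum(is.na(object@values))))
})

setMethod("show", "Periodogram", function(object) {
  cat(sprintf("Periodogram: %d periods in [%.3g, %.3g] h, max power %.3g\n",
              length(object@periodsH), min(object@periodsH),
              max(object@periodsH), max(object@power)))
  if (length(object@sigLines))
    cat("  significance lines:",
        paste(sprintf("%s -> %.3g", names(object@sigLines), object@sigLines),
              collapse = ", "),
        sprintf(" (%d shuffles)\n", object@nRand))
})

setMethod("show", "RhythmCall", function(object) {
  per <- if (is.na(object@periodH)) "" else
    sprintf(", period %.2f +/- %.2f h", object@periodH, object@uncertaintyH)
  cat(sprintf("RhythmCall [%s]: %s%s (%s)\n",
              object@subject, object@label, per, object@ruleTrace))
})

setMethod("show", "ConnectivityReport", function(object) {
  cat(sprintf(
    "ConnectivityReport: %d cluster pairs, %d retained edges (min class %s)\n",
    nrow(object@totals), nrow(object@edges), object@minClass))
  if (length(object@unresolved))
    cat("  unresolved names:", paste(object@unresolved, collapse = ", "), "\n")
})

setMethod("show", "PopulationResult", function(object) {
  cat(sprintf("PopulationResult for genotype '%s'\n", object@genotype))
  cat("  genotype call: ")
  show(object@genotypeCall)
  p <- object@proportions
  cat(sprintf("  individuals: %d/%d rhythmic (%.0f%%)\n",
              p[["n_rhythmic"]], p[["n_total"]], 100 * p[["fraction"]]))
})
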