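#' Write egg records to CSV
#'
#' Device-format CSV, one row per bin, header
#' `fly_id,genotype,time_h,bin_width_h,count,light`. Writing the same records
#' twice yields byte-identical files.
#'
#' @param records list of [EggRecord-class] (or a single record).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEggRecords <- function(records, path) {
  if (is(records, "EggRecord")) records <- list(records)
  rows <- lapply(records, function(r) {
    data.frame(fly_id = r@flyId, genotype = r@genotype, time_h = r@timesH,
               bin_width_h = r@binWidthH, count = r@counts, light = r@light,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read egg records from CSV
#'
#' Inverse of [writeEggRecords()]: groups rows by `fly_id` (preserving file
#' order) and rebuilds one [EggRecord-class] per fly.
#'
#' @param path CSV file with header
#'   `fly_id,genotype,time_h,bin_width_h,count,light`.
#' @return list of [EggRecord-class].
#' @export
readEggRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fly_id", "genotype", "time_h", "bin_width_h", "count", "light")
  stopIfNot1(all(need %in% names(df)),
             "egg-record CSV must have columns: %s", paste(need, collapse = ","))
  ids <- unique(df$fly_id)
  lapply(ids, function(id) {
    d <- df[df$fly_id == id, , drop = FALSE]
    new("EggRecord", flyId = as.character(id),
        genotype = as.character(d$genotype[1]), timesH = as.numeric(d$time_h),
        binWidthH = as.numeric(d$bin_width_h[1]),
        counts = as.integer(d$count), light = as.character(d$light))
  })
}

#' Read / write neuPrint-style connection tables
#'
#' Edge-list CSV with header
#' `bodyId_pre,instance_pre,bodyId_post,instance_post,weight`, the dialect of
#' neuPrint connection-table exports (one row per connected neuron pair,
#' `weight` = total synapse count between the pair).
#'
#' @param path CSV file path.
#' @return `readSynapseEdges`: a data.frame with the five columns above.
#' @export
readSynapseEdges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bodyId_pre", "instance_pre", "bodyId_post", "instance_post",
            "weight")
  stopIfNot1(all(need %in% names(df)),
             "edge-list CSV must have columns: %s", paste(need, collapse = ","))
  df$weight <- as.integer(df$weight)
  df
}

#' @param edges data.frame as returned by [readSynapseEdges()] or
#'   [generateConnectomeFixture()].
#' @rdname readSynapseEdges
#' @return `writeSynapseEdges`: `path`, invisibly.
#' @export
writeSynapseEdges <- function(edges, path) {
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
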