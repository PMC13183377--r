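.STRENGTH_LEVELS <- c("weak", "intermediate", "strong")

#' Classify synaptic connection strength
#'
#' Synapse-count thresholds for a neuron-pair connection: 0-2 synapses is
#' weak, 3-9 intermediate, more than 9 strong. Weak connections are prone to
#' reconstruction error and are excluded from connectivity analyses
#' downstream.
#'
#' @param weight non-negative integer synapse count(s); vectorized.
#' @return character vector in `c("weak", "intermediate", "strong")`.
#' @examples
#' classifyStrength(c(2, 3, 9, 10))
#' @export
classifyStrength <- function(weight) {
  stopIfNot1(all(is.finite(weight)) && all(weight >= 0) &&
               all(weight == round(weight)),
             "weights must be non-negative integers")
  ifelse(weight > 9, "strong", ifelse(weight >= 3, "intermediate", "weak"))
}

#' Default clock / oviposition cluster map
#'
#' Maps neuron instance names to analysis clusters. Clock neurons: the small
#' and large ventrolateral clusters (sLNv, lLNv), the dorsolateral neurons
#' grouped into evening-cell subgroups (E1 = LNd4, LNd5; E2 = LNd6 and the
#' 5th sLNv; E3 = LNd1-LNd3), the anterior/posterior dorsal neurons (DN1a,
#' DN1p) and the lateral posterior neurons (LPN, including the
#' left-hemisphere LPN-L). Oviposition-circuit neurons: oviIN, oviEN, oviDN,
#' the five pC1 types (each its own cluster, since only pC1b contacts the
#' clock) and the auxiliary U and G groups.
#'
#' @param eSubgroups if `TRUE` (default) LNd/5th-sLNv map to E1/E2/E3; if
#'   `FALSE` they map to a single LNd cluster.
#' @return named character vector, instance name -> cluster.
#' @export
defaultClusterMap <- function(eSubgroups = TRUE) {
  rosters <- fixtureRosters()
  if (!eSubgroups) {
    rosters$LNd <- c(rosters$E1, rosters$E2, rosters$E3)
    rosters$E1 <- rosters$E2 <- rosters$E3 <- NULL
  }
  unlist(lapply(names(rosters), function(cl)
    stats::setNames(rep(cl, length(rosters[[cl]])), rosters[[cl]])))
}

#' Clock-side and oviposition-side cluster names
#'
#' Convenience cluster sets for [bipartiteConnectivity()].
#'
#' @return character vector of cluster names.
#' @export
clockClusters <- function() c("sLNv", "lLNv", "E1", "E2", "E3", "LNd",
                              "DN1a", "DN1p", "LPN")

#' @rdname clockClusters
#' @export
oviClusters <- function() c("oviIN", "oviEN", "oviDN",
                            paste0("pC1", letters[1:5]), "U", "G")

#' Bipartite cluster-level connectivity
#'
#' Retains the edges whose endpoints resolve to clusters on opposite sides of
#' a bipartition (either direction) and whose strength class is at least
#' `minClass`; weak connections never contribute. Aggregates the retained
#' synapse counts per directed cluster pair. Instance names absent from the
#' cluster map are collected in the report's `unresolved` slot and their
#' edges excluded.
#'
#' @param edges data.frame with `instance_pre`, `instance_post`, `weight`
#'   (e.g. from [readSynapseEdges()] or [generateConnectomeFixture()]).
#' @param cmap named character vector, instance name -> cluster (default
#'   [defaultClusterMap()]).
#' @param sideA,sideB non-empty character vectors of cluster names forming
#'   the two sides (defaults: clock vs oviposition clusters).
#' @param minClass `"intermediate"` (default) or `"strong"`.
#' @return a [ConnectivityReport-class].
#' @examples
#' spec <- data.frame(pre_cluster = c("E1", "oviIN"),
#'                    post_cluster = c("oviIN", "E1"),
#'                    class = c("strong", "intermediate"))
#' edges <- generateConnectomeFixture(spec, seed = 1)
#' reportTotals(bipartiteConnectivity(edges))
#' @export
bipartiteConnectivity <- function(edges, cmap = defaultClusterMap(),
                                  sideA = clockClusters(),
                                  sideB = oviClusters(),
                                  minClass = "intermediate") {
  stopIfNot1(length(sideA) >= 1 && length(sideB) >= 1,
             "cluster sets must be non-empty")
  stopIfNot1(minClass %in% c("intermediate", "strong"),
             "minClass must be 'intermediate' or 'strong'")
  need <- c("instance_pre", "instance_post", "weight")
  stopIfNot1(is.data.frame(edges) && all(need %in% names(edges)),
             "edges must have columns instance_pre, instance_post, weight")
  unresolved <- sort(unique(c(
    setdiff(edges$instance_pre, names(cmap)),
    setdiff(edges$instance_post, names(cmap)))))
  e <- edges[edges$instance_pre %in% names(cmap) &
               edges$instance_post %in% names(cmap), , drop = FALSE]
  if (nrow(e)) {
    e$cluster_pre <- unname(cmap[e$instance_pre])
    e$cluster_post <- unname(cmap[e$instance_post])
    e$strength <- classifyStrength(e$weight)
    minRank <- match(minClass, .STRENGTH_LEVELS)
    opposite <- (e$cluster_pre %in% sideA & e$cluster_post %in% sideB) |
      (e$cluster_pre %in% sideB & e$cluster_post %in% sideA)
    e <- e[opposite & match(e$strength, .STRENGTH_LEVELS) >= minRank, ,
           drop = FALSE]
  } else {
    e$cluster_pre <- e$cluster_post <- e$strength <- character(0)
  }
  aggregateReport(e, minClass, unresolved)
}

# Aggregate retained, cluster-resolved edges into a ConnectivityReport.
aggregateReport <- function(e, minClass, unresolved = character()) {
  if (nrow(e)) {
    agg <- stats::aggregate(weight ~ cluster_pre + cluster_post, data = e,
                            FUN = sum)
    cnt <- stats::aggregate(weight ~ cluster_pre + cluster_post, data = e,
                            FUN = length)
    totals <- data.frame(cluster_pre = agg$cluster_pre,
                         cluster_post = agg$cluster_post,
                         weight = as.integer(agg$weight),
                         n_edges = as.integer(cnt$weight),
                         stringsAsFactors = FALSE)
    totals <- totals[order(totals$cluster_pre, totals$cluster_post), ,
                     drop = FALSE]
    rownames(totals) <- NULL
    e <- e[order(e$instance_pre, e$instance_post), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    totals <- data.frame(cluster_pre = character(), cluster_post = character(),
                         weight = integer(), n_edges = integer(),
                         stringsAsFactors = FALSE)
  }
  new("ConnectivityReport", totals = totals, edges = e,
      unresolved = unresolved, minClass = minClass)
}

#' Directional balance of a cluster pair
#'
#' Compares the retained synapse totals in the two directions between
#' clusters `pair[1]` and `pair[2]`. A pair absent from the report gives
#' zeros (direction `"none"`), equal non-zero totals give `"balanced"`.
#'
#' @param report a [ConnectivityReport-class].
#' @param pair character vector `c(clusterA, clusterB)`.
#' @return list with `weight_ab`, `weight_ba`, `dominant_direction`.
#' @export
bidirectionality <- function(report, pair) {
  stopIfNot1(length(pair) == 2, "pair must name two clusters")
  tot <- report@totals
  pick <- function(a, b) {
    w <- tot$weight[tot$cluster_pre == a & tot$cluster_post == b]
    if (length(w)) sum(w) else 0L
  }
  ab <- pick(pair[1], pair[2])
  ba <- pick(pair[2], pair[1])
  dom <- if (ab == 0 && ba == 0) "none"
  else if (ab == ba) "balanced"
  else if (ab > ba) sprintf("%s->%s", pair[1], pair[2])
  else sprintf("%s->%s", pair[2], pair[1])
  list(weight_ab = ab, weight_ba = ba, dominant_direction = dom)
}
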