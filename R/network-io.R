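#' Export a connectivity report as a network file
#'
#' Writes the retained neuron-level network: nodes are neurons annotated with
#' their cluster and body id, edges carry the synapse count and its strength
#' class. Formats: GraphML (via igraph), JSON (nodes/edges arrays), or DOT.
#' Every format round-trips through [importNetwork()].
#'
#' @param report a [ConnectivityReport-class].
#' @param path output file path.
#' @param format one of `"graphml"`, `"json"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(report, path, format = c("graphml", "json", "dot")) {
  format <- match.arg(format)
  e <- report@edges
  nodes <- networkNodes(e)
  if (format == "graphml") {
    if (nrow(e)) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = e$instance_pre, to = e$instance_post,
                   weight = e$weight, strength = e$strength,
                   stringsAsFactors = FALSE),
        directed = TRUE, vertices = nodes)
    } else {
      g <- igraph::make_empty_graph(directed = TRUE)
    }
    g <- igraph::set_graph_attr(g, "minClass", report@minClass)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "json") {
    jsonlite::write_json(
      list(min_class = report@minClass, nodes = nodes,
           edges = if (nrow(e))
             e[, c("instance_pre", "instance_post", "weight")]
           else data.frame(instance_pre = character(),
                           instance_post = character(), weight = integer())),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- c("digraph connectivity {",
               sprintf("  graph [minClass=\"%s\"];", report@minClass),
               sprintf("  \"%s\" [cluster=\"%s\", bodyId=%.0f];",
                       nodes$name, nodes$cluster, nodes$bodyId),
               if (nrow(e))
                 sprintf("  \"%s\" -> \"%s\" [weight=%d, strength=\"%s\"];",
                         e$instance_pre, e$instance_post, e$weight,
                         e$strength),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}

networkNodes <- function(e) {
  if (!nrow(e))
    return(data.frame(name = character(), cluster = character(),
                      bodyId = integer(), stringsAsFactors = FALSE))
  nodes <- unique(rbind(
    data.frame(name = e$instance_pre, cluster = e$cluster_pre,
               bodyId = e$bodyId_pre, stringsAsFactors = FALSE),
    data.frame(name = e$instance_post, cluster = e$cluster_post,
               bodyId = e$bodyId_post, stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes
}

#' Import a network file back into a connectivity report
#'
#' Reads a file written by [exportNetwork()] and rebuilds the
#' [ConnectivityReport-class] (strength classes are re-derived from the
#' weights, totals re-aggregated).
#'
#' @param path file written by [exportNetwork()].
#' @param format one of `"graphml"`, `"json"`, `"dot"`.
#' @return a [ConnectivityReport-class].
#' @export
importNetwork <- function(path, format = c("graphml", "json", "dot")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    minClass <- igraph::graph_attr(g, "minClass")
    nodes <- if (igraph::vcount(g))
      data.frame(name = igraph::V(g)$name, cluster = igraph::V(g)$cluster,
                 bodyId = as.numeric(igraph::V(g)$bodyId),
                 stringsAsFactors = FALSE)
    else networkNodes(data.frame())
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(instance_pre = el$from, instance_post = el$to,
                        weight = as.integer(el$weight),
                        stringsAsFactors = FALSE)
  } else if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    minClass <- obj$min_class
    nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
    if (!nrow(nodes))
      nodes <- networkNodes(data.frame())
    if (nrow(edges)) edges$weight <- as.integer(edges$weight)
    else edges <- data.frame(instance_pre = character(),
                             instance_post = character(), weight = integer())
  } else {
    lines <- readLines(path)
    minClass <- sub('.*minClass="([^"]+)".*', "\\1",
                    grep("minClass=", lines, value = TRUE)[1])
    nodeLines <- grep('^\\s*"[^"]+" \\[cluster=', lines, value = TRUE)
    nodes <- data.frame(
      name = sub('^\\s*"([^"]+)".*', "\\1", nodeLines),
      cluster = sub('.*cluster="([^"]+)".*', "\\1", nodeLines),
      bodyId = as.numeric(sub(".*bodyId=([0-9]+).*", "\\1", nodeLines)),
      stringsAsFactors = FALSE)
    if (!length(nodeLines)) nodes <- networkNodes(data.frame())
    edgeLines <- grep("->", lines, value = TRUE)
    if (length(edgeLines)) {
      edges <- data.frame(
        instance_pre = sub('^\\s*"([^"]+)" ->.*', "\\1", edgeLines),
        instance_post = sub('.*-> "([^"]+)".*', "\\1", edgeLines),
        weight = as.integer(sub(".*weight=([0-9]+).*", "\\1", edgeLines)),
        stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(instance_pre = character(),
                          instance_post = character(), weight = integer())
    }
  }
  rebuildReport(edges, nodes, minClass)
}

rebuildReport <- function(edges, nodes, minClass) {
  if (nrow(edges)) {
    idx <- function(nm) match(nm, nodes$name)
    e <- data.frame(
      bodyId_pre = nodes$bodyId[idx(edges$instance_pre)],
      instance_pre = edges$instance_pre,
      bodyId_post = nodes$bodyId[idx(edges$instance_post)],
      instance_post = edges$instance_post,
      weight = edges$weight,
      cluster_pre = nodes$cluster[idx(edges$instance_pre)],
      cluster_post = nodes$cluster[idx(edges$instance_post)],
      strength = classifyStrength(edges$weight),
      stringsAsFactors = FALSE)
  } else {
    e <- data.frame(bodyId_pre = integer(), instance_pre = character(),
                    bodyId_post = integer(), instance_post = character(),
                    weight = integer(), cluster_pre = character(),
                    cluster_post = character(), strength = character(),
                    stringsAsFactors = FALSE)
  }
  aggregateReport(e, minClass)
}
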