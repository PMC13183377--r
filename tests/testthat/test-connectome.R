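synthEdges <- function() {
  readSynapseEdges(system.file("extdata", "synthetic_clock_ovi_edges.csv",
                               package = "ovirhythm"))
}

test_that("strength thresholds are exact at every boundary", {
  w <- 0:20
  got <- classifyStrength(w)
  expect_identical(got, ifelse(w <= 2, "weak",
                               ifelse(w <= 9, "intermediate", "strong")))
  # quoted boundaries
  expect_identical(classifyStrength(2), "weak")
  expect_identical(classifyStrength(3), "intermediate")
  expect_identical(classifyStrength(9), "intermediate")
  expect_identical(classifyStrength(10), "strong")
  expect_error(classifyStrength(-1), "non-negative")
})

test_that("bipartite extraction retains only cross-side, non-weak edges", {
  rep1 <- bipartiteConnectivity(synthEdges())
  tot <- reportTotals(rep1)

  # E1 <-> oviIN present in both directions
  expect_true(any(tot$cluster_pre == "E1" & tot$cluster_post == "oviIN"))
  expect_true(any(tot$cluster_pre == "oviIN" & tot$cluster_post == "E1"))
  expect_equal(tot$weight[tot$cluster_pre == "E1" &
                            tot$cluster_post == "oviIN"], 55)

  # E2 makes no retained contacts with oviposition neurons (weak only)
  expect_false(any(tot$cluster_pre == "E2" | tot$cluster_post == "E2"))

  # E3 contacts only pC1b among oviposition clusters
  e3post <- tot$cluster_post[tot$cluster_pre == "E3"]
  expect_identical(unique(e3post), "pC1b")
  expect_equal(tot$weight[tot$cluster_pre == "E3"], 22)

  # clock-side internal edges would be dropped; weak sLNv->oviDN dropped too
  expect_false(any(tot$cluster_pre == "sLNv"))

  # single intermediate edge fixture
  one <- data.frame(bodyId_pre = 1L, instance_pre = "LNd2", bodyId_post = 2L,
                    instance_post = "pC1b", weight = 5L)
  r1 <- bipartiteConnectivity(one)
  expect_identical(nrow(reportTotals(r1)), 1L)
  expect_equal(reportTotals(r1)$weight, 5)

  # all-weak list gives an empty report
  allWeak <- transform(one, weight = 2L)
  expect_identical(nrow(reportTotals(bipartiteConnectivity(allWeak))), 0L)

  # unresolved names are collected and excluded
  odd <- data.frame(bodyId_pre = 1L, instance_pre = "mystery-7",
                    bodyId_post = 2L, instance_post = "oviIN", weight = 12L)
  r2 <- bipartiteConnectivity(rbind(one, odd))
  expect_identical(r2@unresolved, "mystery-7")
  expect_identical(nrow(reportTotals(r2)), 1L)

  expect_error(bipartiteConnectivity(one, sideA = character()), "non-empty")
  expect_error(bipartiteConnectivity(one, minClass = "mild"), "minClass")
})

test_that("strengthening the filter never increases pair totals", {
  ed <- synthEdges()
  ti <- reportTotals(bipartiteConnectivity(ed, minClass = "intermediate"))
  ts <- reportTotals(bipartiteConnectivity(ed, minClass = "strong"))
  for (k in seq_len(nrow(ts))) {
    m <- ti$weight[ti$cluster_pre == ts$cluster_pre[k] &
                     ti$cluster_post == ts$cluster_post[k]]
    expect_gte(m, ts$weight[k])
  }
  expect_lte(sum(ts$weight), sum(ti$weight))

  # row order of the edge list is irrelevant
  set.seed(1)
  shuf <- ed[sample.int(nrow(ed)), ]
  expect_equal(reportTotals(bipartiteConnectivity(shuf)),
               reportTotals(bipartiteConnectivity(ed)))
})

test_that("directional totals identify the dominant direction", {
  rep1 <- bipartiteConnectivity(synthEdges())
  lp <- bidirectionality(rep1, c("oviIN", "LPN"))
  expect_equal(lp$weight_ab, 135)
  expect_equal(lp$weight_ba, 16)
  expect_identical(lp$dominant_direction, "oviIN->LPN")

  # symmetric pair: balanced
  symE <- data.frame(bodyId_pre = c(1L, 2L), instance_pre = c("LNd4", "oviIN"),
                     bodyId_post = c(2L, 1L), instance_post = c("oviIN", "LNd4"),
                     weight = c(7L, 7L))
  bal <- bidirectionality(bipartiteConnectivity(symE), c("E1", "oviIN"))
  expect_identical(bal$dominant_direction, "balanced")

  none <- bidirectionality(rep1, c("DN1a", "oviEN"))
  expect_equal(none$weight_ab + none$weight_ba, 0)
  expect_identical(none$dominant_direction, "none")
})

test_that("network export round-trips through the package reader", {
  rep1 <- bipartiteConnectivity(synthEdges())
  empty <- bipartiteConnectivity(synthEdges()[0, ])
  for (fmt in c("graphml", "json", "dot")) {
    f <- tempfile(fileext = paste0(".", fmt))
    exportNetwork(rep1, f, fmt)
    back <- importNetwork(f, fmt)
    expect_equal(reportTotals(back), reportTotals(rep1))
    expect_equal(reportEdges(back)[order(reportEdges(back)$weight), ],
                 reportEdges(rep1)[order(reportEdges(rep1)$weight), ],
                 ignore_attr = TRUE)
    expect_identical(back@minClass, rep1@minClass)

    f0 <- tempfile(fileext = paste0(".", fmt))
    exportNetwork(empty, f0, fmt)
    expect_identical(nrow(reportEdges(importNetwork(f0, fmt))), 0L)
  }
  # node count matches the fixture's neuron count
  f <- tempfile(fileext = ".graphml")
  exportNetwork(rep1, f, "graphml")
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g),
               length(unique(c(reportEdges(rep1)$instance_pre,
                               reportEdges(rep1)$instance_post))))
  expect_error(exportNetwork(rep1, tempfile(), "gexf"))
})
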