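# hand-built igraph helper for topology tests (bypasses scoring)
graph_from_edges <- function(edges, nodes = NULL) {
  df <- data.frame(from = edges[, 1], to = edges[, 2],
                   rs = if (ncol(edges) > 2) as.numeric(edges[, 3]) else 50,
                   lc = 6)
  df$weight <- df$rs
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = nodes %||% unique(c(df$from, df$to)))
}

test_that("build_network keeps isolated genes and recovers planted cliques", {
  cfg <- small_config(seed = 3)
  # add a planted clique among genes 5..8
  cl <- t(utils::combn(sprintf("G%04d", 5:8), 2))
  cfg2 <- generator_config(
    n_genes = 20, n_diseases = 8, n_drugs = 4, n_docs = 400,
    background_rate = 0.02, seed = 3,
    planted_pairs = rbind(cfg$pairs,
                          data.frame(a = cl[, 1], b = cl[, 2], q = 0.05,
                                     role = "clique")))
  sim <- generate_corpus(cfg2)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  net <- build_network(cfg2$genes, idx, lit_thresholds(30, 5))
  expect_setequal(igraph::V(net)$name, cfg2$genes)
  rep <- connectivity_report(net)
  expect_equal(rep$total, 20)
  expect_gte(rep$isolated, 1)   # most background genes have no edges
  sub <- igraph::induced_subgraph(net, sprintf("G%04d", 5:8))
  expect_equal(igraph::ecount(sub), 6)  # full clique recovered
  # node-set ordering does not matter
  net2 <- build_network(rev(cfg2$genes), idx, lit_thresholds(30, 5))
  expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
  el <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(el(net2), el(net))
  # edge weights are rs in (0, 100]
  expect_true(all(igraph::E(net)$rs > 0 & igraph::E(net)$rs <= 100))
})

test_that("annotation stores per-gene keyword rs without touching topology", {
  cfg <- small_config(seed = 9, q = 0.06)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  net <- build_network(cfg$genes, idx, lit_thresholds(0, 0))
  net_a <- annotate_nodes(net, idx, "D0001", "rs_d1", lit_thresholds(30, 5))
  vals <- igraph::vertex_attr(net_a, "rs_d1")
  names(vals) <- igraph::V(net_a)$name
  expect_gt(vals[["G0001"]], 0)          # planted gene-disease link
  expect_equal(unname(vals[["G0015"]]), 0)  # background gene: below thresholds
  expect_equal(igraph::ecount(net_a), igraph::ecount(net))
  # idempotent
  net_b <- annotate_nodes(net_a, idx, "D0001", "rs_d1", lit_thresholds(30, 5))
  expect_identical(igraph::vertex_attr(net_b, "rs_d1"), vals, ignore_attr = TRUE)
  expect_error(annotate_nodes(net, idx, "NOPE", "x"), "unknown keyword")
})

test_that("hubs are strict-degree exceedances and shrink with the threshold", {
  star <- graph_from_edges(cbind("hub", sprintf("leaf%02d", 1:10)))
  da <- degree_analysis(star, hub_min_degree = 5)
  expect_identical(da$hubs, "hub")
  expect_equal(unname(da$degrees["hub"]), 10)
  prev <- Inf
  for (h in c(0, 2, 5, 9, 10)) {
    nh <- length(degree_analysis(star, hub_min_degree = h)$hubs)
    expect_lte(nh, prev)
    prev <- nh
  }
  expect_length(degree_analysis(star, hub_min_degree = 10)$hubs, 0)
})

test_that("CCDF regression recovers a planted power-law exponent", {
  set.seed(101)
  k <- 1:5000
  deg <- sample(k, 300, replace = TRUE, prob = k^-2.5)
  fit <- fit_power_law_ccdf(deg)
  # CCDF slope for exponent 2.5 is -(2.5 - 1) = -1.5
  expect_lt(abs(fit$slope - (-1.5)), 0.5)
  expect_lt(fit$p_value, 0.001)
  # Erdos-Renyi-like degrees fit the log-log line worse at the same n
  wins <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    pl <- fit_power_law_ccdf(sample(k, 300, replace = TRUE, prob = k^-2.5))
    er <- fit_power_law_ccdf(pmax(1, stats::rbinom(300, 299, 10 / 299)))
    wins <- wins + (pl$r_squared > er$r_squared)
  }
  expect_gt(wins, 10)
  # MLE alternative is exposed
  g <- graph_from_edges(cbind(sprintf("a%d", 1:50), sprintf("b%d", rep(1:5, 10))))
  mle <- degree_analysis(g, method = "mle")$fit
  expect_true(is.numeric(mle$alpha))
})

test_that("betweenness equals brute-force shortest-path enumeration", {
  # path a-b-c: middle carries the single shortest path
  path3 <- graph_from_edges(rbind(c("a", "b"), c("b", "c")))
  b3 <- betweenness_centrality(path3)
  expect_equal(unname(b3[c("a", "b", "c")]), c(0, 1, 0))
  # complete graph: all zero
  k4 <- graph_from_edges(t(utils::combn(letters[1:4], 2)))
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  # 5-node barbell (two triangles joined at a bridge): bridge node maximal
  barbell <- graph_from_edges(rbind(
    c("a", "b"), c("a", "m"), c("b", "m"),
    c("m", "c"), c("m", "d"), c("c", "d")))
  bb <- betweenness_centrality(barbell)
  expect_equal(names(which.max(bb)), "m")
  expect_equal(unname(bb[c("a", "b", "c", "d")]), rep(0, 4))
  # random graphs up to 30 nodes against the matrix-power oracle
  for (s in 1:6) {
    set.seed(300 + s)
    n <- sample(5:30, 1)
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, 0.2)
    A <- A + t(A)
    dimnames(A) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    igraph::E(g)$rs <- 50; igraph::E(g)$lc <- 6
    expect_equal(unname(betweenness_centrality(g)), brute_betweenness(A),
                 tolerance = 1e-12)
  }
})

test_that("neighborhood subnetworks are induced on seeds plus neighbors", {
  g <- graph_from_edges(rbind(
    c("s", "n1"), c("s", "n2"), c("n1", "n2"), c("n2", "far"),
    c("far", "farther")))
  sub <- neighborhood_subnetwork(g, "s")
  expect_setequal(igraph::V(sub)$name, c("s", "n1", "n2"))
  expect_equal(igraph::ecount(sub), 3)  # includes the n1-n2 edge
  all_nodes <- igraph::V(g)$name
  expect_setequal(igraph::V(neighborhood_subnetwork(g, all_nodes))$name,
                  all_nodes)
  expect_error(neighborhood_subnetwork(g, "missing"), "unknown seed")
})

test_that("network exports round-trip and follow the declared formats", {
  g <- graph_from_edges(rbind(c("g1", "g2", 80), c("g2", "g3", 40)),
                        nodes = c("g1", "g2", "g3", "iso"))
  g <- igraph::set_vertex_attr(g, "rs_dex", value = c(10, 20, 30, 0))
  # SIF: one interaction line per edge, bare lines for isolated nodes
  sif <- tempfile(fileext = ".sif")
  export_network(g, sif, "sif")
  expect_setequal(readLines(sif),
                  c("g1 cooccurs g2", "g2 cooccurs g3", "iso"))
  # edge TSV row count = edge count
  etsv <- tempfile(fileext = ".tsv")
  export_network(g, etsv, "edge_tsv")
  expect_equal(nrow(utils::read.delim(etsv)), igraph::ecount(g))
  # GraphML round-trip preserves nodes, edges, weights, attributes
  gml <- tempfile(fileext = ".graphml")
  export_network(g, gml, "graphml")
  g2 <- import_network(gml)
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  ord <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::vertex_attr(g2, "rs_dex")[ord],
               igraph::vertex_attr(g, "rs_dex"))
  e2 <- igraph::as_edgelist(g2)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_equal(igraph::E(g2)$rs[order(key(e2))],
               igraph::E(g)$rs[order(key(igraph::as_edgelist(g)))])
})
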