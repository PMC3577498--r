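# Literature gene network: undirected graph whose nodes are genes and whose
# edges connect genes with a significant co-occurrence (rs, lc passing
# thresholds). Edge weight is the pair's rs; lc is kept as a secondary
# attribute. Node attributes hold per-keyword rs annotations (e.g. the
# strength of each gene's link with a drug such as dexamethasone, or a
# disease term such as inflammation). Backed by igraph; isolated nodes are
# retained so connected-versus-isolated counts can be reported.

#' Build the gene-gene literature network
#'
#' Nodes are the input genes; edges are gene pairs whose co-occurrence
#' passes the thresholds. Scoring (and its scale_ref) is run over the
#' given gene set. Isolated genes stay in the graph.
#'
#' @param gene_set Non-empty character vector of gene concept ids.
#' @param index A `lit_index`.
#' @param thresholds A [lit_thresholds()] (default rs > 30, lc > 5).
#' @return An igraph object with vertex attribute `name`, edge attributes
#'   `rs` (= `weight`) and `lc`, and graph attributes `scale_ref`,
#'   `rs_min`, `lc_min`.
#' @export
build_network <- function(gene_set, index, thresholds = lit_thresholds()) {
  if (!length(gene_set)) stop_litnet("empty gene set")
  gene_set <- unique(sort(gene_set))
  sc <- score_category_pairs(index, "gene", "gene", thresholds,
                             restrict_a = gene_set, restrict_b = gene_set)
  edges <- data.frame(from = sc$concept_a, to = sc$concept_b,
                      rs = sc$rs, lc = sc$lc, weight = sc$rs,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = gene_set))
  g <- igraph::set_graph_attr(g, "scale_ref", attr(sc, "scale_ref"))
  g <- igraph::set_graph_attr(g, "rs_min", thresholds$rs_min)
  g <- igraph::set_graph_attr(g, "lc_min", thresholds$lc_min)
  g
}

#' Count connected (non-isolated) nodes
#'
#' @param network An igraph literature network.
#' @return List with `connected`, `isolated`, `total` and the isolated ids.
#' @export
connectivity_report <- function(network) {
  deg <- igraph::degree(network)
  list(connected = sum(deg > 0), isolated = sum(deg == 0),
       total = length(deg), isolated_ids = names(deg)[deg == 0])
}

#' Annotate network nodes with their rs against one keyword
#'
#' Each node gains a numeric attribute holding its rs with the keyword, or
#' 0 when the pair is below the thresholds. The rs values come from one
#' scoring run of the network's genes against the keyword's whole category
#' (so they share a scale_ref). Topology is unchanged; re-annotating with
#' the same keyword is idempotent.
#'
#' @param network An igraph literature network.
#' @param index A `lit_index`.
#' @param keyword_id Concept id of the keyword (any non-gene category).
#' @param attribute_name Vertex attribute to write.
#' @param thresholds A [lit_thresholds()].
#' @return The annotated igraph object.
#' @export
annotate_nodes <- function(network, index, keyword_id, attribute_name,
                           thresholds = lit_thresholds()) {
  if (is.null(index$by_concept[[keyword_id]])) {
    stop_litnet("unknown keyword: %s", keyword_id)
  }
  genes <- igraph::V(network)$name
  kw_cat <- index$categories[[keyword_id]]
  sc <- score_category_pairs(index, "gene", kw_cat, thresholds,
                             restrict_a = genes)
  sel <- sc$concept_a == keyword_id | sc$concept_b == keyword_id
  sc <- sc[sel, , drop = FALSE]
  partner <- ifelse(sc$concept_a == keyword_id, sc$concept_b, sc$concept_a)
  vals <- stats::setNames(rep(0, length(genes)), genes)
  vals[partner[partner %in% genes]] <- sc$rs[partner %in% genes]
  igraph::set_vertex_attr(network, attribute_name, value = unname(vals[genes]))
}

#' Degree distribution, hubs and power-law fit
#'
#' Hubs are nodes with degree strictly above `hub_min_degree` (the
#' conventional screen for highly connected genes such as the insulin
#' signalling core of a disease network). The default fit regresses
#' log-CCDF (P(D >= d)) on log-degree over observed degrees >= 1 by least
#' squares; its p-value is the two-sided t-test on the slope. A discrete
#' maximum-likelihood alternative (igraph's power-law fit) is available
#' via `method = "mle"`.
#'
#' @param network An igraph literature network.
#' @param hub_min_degree Hub threshold (default 100, the usual screen for
#'   literature-network hubs).
#' @param method `"ccdf"` (default, least-squares on the log-log CCDF) or
#'   `"mle"` (discrete maximum likelihood via igraph).
#' @return List with `degrees` (named), `hubs`, and `fit` (slope,
#'   intercept, p_value, r_squared, n_points for "ccdf"; alpha, xmin, KS
#'   p-value for "mle"). With no positive-degree node, `fit` is NULL.
#' @export
degree_analysis <- function(network, hub_min_degree = 100,
                            method = c("ccdf", "mle")) {
  method <- match.arg(method)
  deg <- igraph::degree(network)
  hubs <- names(deg)[deg > hub_min_degree]
  pos <- deg[deg >= 1]
  fit <- NULL
  if (length(pos)) {
    fit <- switch(method,
      ccdf = fit_power_law_ccdf(pos),
      mle = {
        f <- igraph::fit_power_law(pos, implementation = "plfit")
        list(alpha = f$alpha, xmin = f$xmin, p_value = f$KS.p,
             method = "mle")
      })
  }
  list(degrees = deg, hubs = sort(hubs), fit = fit)
}

#' Least-squares power-law fit on the log-log CCDF
#'
#' For degrees d_1..d_n (>= 1), computes the empirical complementary CDF
#' P(D >= d) at each distinct degree and fits log P(D >= d) ~ log d. For a
#' power-law degree distribution P(k) ~ k^-a the CCDF slope estimates
#' -(a - 1).
#'
#' @param degrees Integer vector of degrees >= 1.
#' @return List: slope, intercept, p_value (two-sided t-test on the
#'   slope), r_squared, n_points. NULL-slope cases (fewer than 3 distinct
#'   degrees) return p_value = NA.
#' @export
fit_power_law_ccdf <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  d <- as.numeric(names(tab))
  n <- sum(tab)
  ccdf <- rev(cumsum(rev(as.numeric(tab)))) / n # P(D >= d)
  if (length(d) < 3) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
                r_squared = NA_real_, n_points = length(d), method = "ccdf"))
  }
  fit <- stats::lm(log(ccdf) ~ log(d))
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = sm$coefficients[2, 4],
       r_squared = sm$r.squared,
       n_points = length(d), method = "ccdf")
}

#' Betweenness centrality of network nodes
#'
#' Fraction of shortest paths passing through each node, computed on the
#' unweighted topology (rs is a similarity, not a path cost) and
#' normalized by the number of ordered node pairs excluding the node,
#' (n-1)(n-2)/2 for undirected graphs.
#'
#' @param network An igraph literature network.
#' @return Named numeric vector of normalized betweenness values.
#' @export
betweenness_centrality <- function(network) {
  igraph::betweenness(network, directed = FALSE, weights = NA,
                      normalized = TRUE)
}

#' Induced subnetwork around seed genes
#'
#' The induced subgraph on the seeds plus their direct neighbours (used
#' e.g. to inspect a small enzyme family and its immediate literature
#' context within the full network).
#'
#' @param network An igraph literature network.
#' @param seed_nodes Character vector of node names, all present in the
#'   network.
#' @return igraph subgraph; edges are exactly the original edges with both
#'   ends retained.
#' @export
neighborhood_subnetwork <- function(network, seed_nodes) {
  missing <- setdiff(seed_nodes, igraph::V(network)$name)
  if (length(missing)) {
    stop_litnet("unknown seed node(s): %s", paste(missing, collapse = ", "))
  }
  nb <- unlist(lapply(seed_nodes, function(s) {
    igraph::neighbors(network, s)$name
  }))
  keep <- union(seed_nodes, nb)
  igraph::induced_subgraph(network, keep)
}

#' Export a network to GraphML, SIF or edge TSV
#'
#' GraphML round-trips nodes, edges, weights and node attributes (see
#' [import_network()]). SIF writes `source cooccurs target` lines plus
#' bare names for isolated nodes (Cytoscape convention). Edge TSV writes
#' source, target, rs, lc.
#'
#' @param network An igraph literature network.
#' @param path Output path.
#' @param format One of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else if (format == "sif") {
    el <- igraph::as_edgelist(network)
    lines <- if (nrow(el)) paste(el[, 1], "cooccurs", el[, 2]) else character(0)
    iso <- connectivity_report(network)$isolated_ids
    writeLines(c(lines, iso), path)
  } else {
    el <- igraph::as_edgelist(network)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     rs = igraph::E(network)$rs, lc = igraph::E(network)$lc)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a network exported as GraphML
#'
#' @param path Path to a GraphML file written by [export_network()].
#' @return igraph object with the exported attributes.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
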