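# Neighbor-weighted literature score.
#
# For gene g and term d (say a drug or a disease), let g1 be the direct rs
# of g with d, and for each network neighbor i of g let g_i be that
# neighbor's rs with d and rg_i the rs of the edge between g and the
# neighbor. The neighbor component is the edge-weighted mean
#
#     Ns = sum_i rg_i * g_i / sum_i rg_i,
#
# and the literature score averages the direct and neighborhood evidence:
#
#     literature_score = (g1 + Ns) / 2.
#
# A gene with no direct link to d can thus acquire score through strongly
# linked neighbors, and conversely a direct link is tempered by an
# indifferent neighborhood. For isolated genes (no neighbors) the score
# is g1 itself: halving a lone direct score would penalize missing
# neighborhood data rather than add evidence.

#' Neighbor component of the literature score
#'
#' The rs-weighted mean of the neighbors' term scores. Always within
#' [min(g_i), max(g_i)].
#'
#' @param g Numeric vector of neighbor term scores (each in [0, 100]),
#'   non-empty.
#' @param rg Numeric vector of edge weights to those neighbors (each in
#'   (0, 100]), same length as `g`.
#' @return Ns, a single number.
#' @export
neighbor_component <- function(g, rg) {
  if (!length(g)) stop_litnet("empty neighbor list: Ns undefined")
  if (length(g) != length(rg)) stop_litnet("g and rg lengths differ")
  if (any(rg <= 0)) stop_litnet("edge weights must be positive")
  if (any(g < 0 | g > 100)) stop_litnet("neighbor scores must be in [0, 100]")
  sum(rg * g) / sum(rg)
}

#' Literature score of one gene with one term
#'
#' @param g1 Direct rs of the gene with the term, in [0, 100].
#' @param neighbors_g Numeric vector of neighbor term scores (may be
#'   empty: the score is then `g1`).
#' @param neighbors_rg Edge weights to those neighbors.
#' @return The literature score, in [0, 100].
#' @export
literature_score <- function(g1, neighbors_g = numeric(0),
                             neighbors_rg = numeric(0)) {
  if (g1 < 0 || g1 > 100) stop_litnet("g1 must be in [0, 100]")
  if (!length(neighbors_g)) return(g1)
  (g1 + neighbor_component(neighbors_g, neighbors_rg)) / 2
}

#' Score every network gene for one annotated term
#'
#' Reads the per-node term annotation (see [annotate_nodes()]) and the
#' incident edge weights, and computes for each gene its direct rs, Ns and
#' literature score with that term.
#'
#' @param network An igraph literature network whose vertices carry
#'   `term_attribute`.
#' @param term_attribute Name of the vertex attribute holding rs with the
#'   term.
#' @return Data.frame: gene, direct, ns (NA for isolated genes),
#'   literature_score, n_neighbors.
#' @export
score_genes_for_term <- function(network, term_attribute) {
  vals <- igraph::vertex_attr(network, term_attribute)
  if (is.null(vals)) stop_litnet("missing vertex attribute '%s'", term_attribute)
  genes <- igraph::V(network)$name
  vals <- stats::setNames(as.numeric(vals), genes)
  inc <- igraph::as_adj_edge_list(network)
  out <- lapply(seq_along(genes), function(i) {
    es <- inc[[i]]
    if (!length(es)) {
      return(data.frame(gene = genes[[i]], direct = vals[[i]], ns = NA_real_,
                        literature_score = vals[[i]], n_neighbors = 0L))
    }
    ends <- igraph::ends(network, es)
    nb <- ifelse(ends[, 1] == genes[[i]], ends[, 2], ends[, 1])
    rg <- es$rs
    ns <- neighbor_component(unname(vals[nb]), rg)
    data.frame(gene = genes[[i]], direct = vals[[i]], ns = ns,
               literature_score = (vals[[i]] + ns) / 2,
               n_neighbors = length(nb))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select candidate genes by two-term quadrant
#'
#' Genes scoring high with one term (e.g. a drug of interest, score > hi)
#' and low with another (e.g. an unwanted process, score < lo). Selection
#' can use the direct rs or the neighbor-weighted literature score; the
#' contrast between the two modes shows which apparently exclusive
#' markers acquire the unwanted association through their neighborhood.
#'
#' @param scores_hi Data.frame from [score_genes_for_term()] for the
#'   high-side term.
#' @param scores_lo Same, for the low-side term (same gene universe).
#' @param hi Threshold the high-side score must exceed (default 25).
#' @param lo Threshold the low-side score must stay under (default 25).
#' @param mode `"literature"` (default) or `"direct"`.
#' @return Data.frame of selected genes with both scores, sorted by
#'   high-side score descending.
#' @export
select_candidates <- function(scores_hi, scores_lo, hi = 25, lo = 25,
                              mode = c("literature", "direct")) {
  mode <- match.arg(mode)
  if (!setequal(scores_hi$gene, scores_lo$gene)) {
    stop_litnet("gene universes differ between the two score sets")
  }
  scores_lo <- scores_lo[match(scores_hi$gene, scores_lo$gene), , drop = FALSE]
  col <- if (mode == "literature") "literature_score" else "direct"
  sel <- scores_hi[[col]] > hi & scores_lo[[col]] < lo
  out <- data.frame(gene = scores_hi$gene,
                    score_hi = scores_hi[[col]],
                    score_lo = scores_lo[[col]],
                    mode = mode, stringsAsFactors = FALSE)[sel, , drop = FALSE]
  out <- out[order(-out$score_hi, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene-term scores or candidate lists to TSV
#'
#' @param df Data.frame ([score_genes_for_term()] or [select_candidates()]
#'   output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
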