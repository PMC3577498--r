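# Keyword over-representation of a gene set against a drug or disease
# vocabulary. A gene is "linked" to a keyword when the gene-keyword pair
# passes the association thresholds; the null model is the hypergeometric
# distribution: drawing n query genes from a background of N_bg tagged
# genes of which K are linked to the keyword, the p-value is the upper
# tail P(X >= k). Raw p-values are filtered at alpha (mirroring the usual
# reporting convention for such tables), with Benjamini-Hochberg q-values
# always emitted alongside so FDR control remains available.

#' Keyword enrichment of a gene set
#'
#' @param gene_set Character vector of gene concept ids (non-empty, all in
#'   the background).
#' @param index A `lit_index`.
#' @param category `"drug"` or `"disease"`: the keyword vocabulary tested.
#' @param thresholds A [lit_thresholds()] defining "linked".
#' @param alpha Raw p-value cutoff for reporting (default 0.05).
#' @return Data.frame with one row per keyword passing `p_value < alpha`,
#'   sorted by p-value: keyword_id, category, k (query genes linked), K
#'   (background genes linked), n (query size), N_bg (background size),
#'   p_value, q_value (BH over all keywords tested, before filtering).
#' @export
enrich <- function(gene_set, index, category = c("drug", "disease"),
                   thresholds = lit_thresholds(), alpha = 0.05) {
  category <- match.arg(category)
  if (!length(gene_set)) stop_litnet("empty gene set")
  stopifnot(inherits(index, "lit_index"))
  # background: thesaurus genes mentioned in at least one document
  genes_all <- names(index$categories)[index$categories == "gene"]
  background <- genes_all[lengths(index$by_concept[genes_all]) > 0]
  outside <- setdiff(gene_set, background)
  if (length(outside)) {
    stop_litnet("gene(s) outside the tagged background: %s",
                paste(outside, collapse = ", "))
  }
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  N_bg <- length(background)
  sc <- score_category_pairs(index, "gene", category, thresholds,
                             restrict_a = background)
  g <- ifelse(sc$concept_a %in% background, sc$concept_a, sc$concept_b)
  kw <- ifelse(sc$concept_a %in% background, sc$concept_b, sc$concept_a)
  keywords <- names(index$categories)[index$categories == category]
  link_by_kw <- split(g, factor(kw, levels = keywords))
  K <- vapply(link_by_kw, length, 0L)
  k <- vapply(link_by_kw, function(x) sum(x %in% gene_set), 0L)
  p <- stats::phyper(k - 1L, K, N_bg - K, n, lower.tail = FALSE)
  res <- data.frame(keyword_id = keywords, category = category,
                    k = k, K = K, n = n, N_bg = N_bg,
                    p_value = p, q_value = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[res$p_value < alpha, , drop = FALSE]
  res <- res[order(res$p_value, res$keyword_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results to TSV
#'
#' @param results Data.frame from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
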