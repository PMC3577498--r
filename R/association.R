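# Pairwise co-occurrence association scoring.
#
# For a concept pair (a, b): c_a and c_b are the numbers of documents
# mentioning each concept, lc the number mentioning both ("literature
# count"), N the corpus size. The association strength is the lift
# lc*N/(c_a*c_b) (observed/expected joint count under independence),
# rescaled onto 0-100 as
#
#     rs = 100 * ln(lift) / scale_ref,   clipped to [0, 100],
#
# where scale_ref is the maximum ln(lift) over pairs meeting the
# literature-count floor in the same scoring run. rs = 0 whenever lc = 0 or
# lift <= 1. NOTE: this rescaled log-lift is a reimplementation choice --
# the historical R-scaled score of thesaurus-based Medline mining systems
# was never published in closed form. It reproduces the documented 0-100
# range and monotonicity in association strength, and is deterministic
# given a corpus, but rs values are comparable only within one scoring run
# (the run records its scale_ref for reproducibility).
#
# Threshold conventions are strict inequalities: a pair passes when
# rs > rs_min AND lc > lc_min (defaults 30 and 5 for gene-gene work, 35
# and 5 for gene-disease extraction).

#' Association thresholds
#'
#' @param rs_min Minimum R-scaled score (strict: pairs need rs > rs_min),
#'   in [0, 100].
#' @param lc_min Minimum literature count (strict: lc > lc_min).
#' @return A list with class `lit_thresholds`.
#' @export
lit_thresholds <- function(rs_min = 30, lc_min = 5) {
  stopifnot(is.numeric(rs_min), length(rs_min) == 1L, rs_min >= 0, rs_min <= 100,
            is.numeric(lc_min), length(lc_min) == 1L, lc_min >= 0)
  structure(list(rs_min = rs_min, lc_min = as.integer(lc_min)),
            class = "lit_thresholds")
}

#' Raw pair counts for two concepts
#'
#' @param index A `lit_index`.
#' @param a,b Distinct concept ids.
#' @return List with concept_a, concept_b (canonically ordered), c_a, c_b,
#'   lc, n_docs. Symmetric in (a, b).
#' @export
pair_stats <- function(index, a, b) {
  stopifnot(inherits(index, "lit_index"))
  if (identical(a, b)) stop_litnet("self-pair (%s, %s): undefined", a, b)
  if (is.null(index$by_concept[[a]])) stop_litnet("unknown concept: %s", a)
  if (is.null(index$by_concept[[b]])) stop_litnet("unknown concept: %s", b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  da <- index$by_concept[[a]]; db <- index$by_concept[[b]]
  list(concept_a = a, concept_b = b,
       c_a = length(da), c_b = length(db),
       lc = length(intersect(da, db)), n_docs = index$n_docs)
}

#' Score one concept pair
#'
#' @param stats Pair counts from [pair_stats()].
#' @param scale_ref Maximum ln(lift) of the scoring run this pair belongs
#'   to; must be > 0 when the run contains any pair with lift > 1.
#' @return `stats` extended with `lift` and `rs`.
#' @export
score_pair <- function(stats, scale_ref) {
  lift <- if (stats$c_a > 0 && stats$c_b > 0) {
    (stats$lc * stats$n_docs) / (stats$c_a * stats$c_b)
  } else 0
  rs <- 0
  if (lift > 1 && stats$lc >= 1) {
    if (!is.numeric(scale_ref) || scale_ref <= 0) {
      stop_litnet("scale_ref must be > 0 when a pair has lift > 1")
    }
    rs <- min(100, max(0, 100 * log(lift) / scale_ref))
  }
  c(stats, list(lift = lift, rs = rs))
}

# incidence matrix (concepts x docs) over a set of concept ids
incidence_matrix <- function(index, ids) {
  doc_pos <- stats::setNames(seq_along(index$doc_ids), index$doc_ids)
  docs <- index$by_concept[ids]
  i <- rep.int(seq_along(ids), lengths(docs))
  j <- doc_pos[unlist(docs, use.names = FALSE)]
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(ids), length(index$doc_ids)),
                       dimnames = list(ids, NULL))
}

#' Score all pairs between two concept categories
#'
#' Computes counts for every cross-category pair with lc >= 1, derives the
#' run's scale_ref as the maximum ln(lift) among pairs with lc >= lc_min,
#' and returns the pairs passing `rs > rs_min` and `lc > lc_min`. When the
#' two categories coincide, unordered pairs (a < b) are scored once. If no
#' pair exceeds independence the result is empty (with a message, not an
#' error).
#'
#' @param index A `lit_index` (carries concept categories).
#' @param cat_a,cat_b Category names.
#' @param thresholds A [lit_thresholds()].
#' @param restrict_a,restrict_b Optional concept-id subsets (used e.g. to
#'   score only the genes of a candidate network); the run's scale_ref is
#'   computed over the restricted pair set.
#' @return A `lit_scores` data.frame with columns concept_a, concept_b,
#'   c_a, c_b, lc, n_docs, lift, rs, ordered by rs desc, lc desc, then ids;
#'   attributes `scale_ref` and `thresholds` record the run.
#' @export
score_category_pairs <- function(index, cat_a, cat_b,
                                 thresholds = lit_thresholds(),
                                 restrict_a = NULL, restrict_b = NULL) {
  stopifnot(inherits(index, "lit_index"), inherits(thresholds, "lit_thresholds"))
  ids_a <- names(index$categories)[index$categories == cat_a]
  ids_b <- names(index$categories)[index$categories == cat_b]
  if (!is.null(restrict_a)) ids_a <- intersect(ids_a, restrict_a)
  if (!is.null(restrict_b)) ids_b <- intersect(ids_b, restrict_b)
  if (!length(ids_a) || !length(ids_b)) {
    stop_litnet("no concepts in category '%s' x '%s' to score", cat_a, cat_b)
  }
  same <- identical(cat_a, cat_b) && identical(sort(ids_a), sort(ids_b))
  A <- incidence_matrix(index, ids_a)
  B <- if (same) A else incidence_matrix(index, ids_b)
  joint <- as(Matrix::tcrossprod(A, B), "generalMatrix")
  tri <- Matrix::mat2triplet(joint) # i, j, x for nonzero joint counts
  tri <- data.frame(i = tri$i, j = tri$j, x = tri$x)
  if (same) tri <- tri[ids_a[tri$i] < ids_b[tri$j], , drop = FALSE]
  ca <- lengths(index$by_concept[ids_a])
  cb <- lengths(index$by_concept[ids_b])
  out <- data.frame(concept_a = ids_a[tri$i], concept_b = ids_b[tri$j],
                    c_a = as.integer(ca[tri$i]), c_b = as.integer(cb[tri$j]),
                    lc = as.integer(tri$x), n_docs = index$n_docs,
                    stringsAsFactors = FALSE)
  out$lift <- (out$lc * out$n_docs) / (out$c_a * out$c_b)
  eligible <- out$lift[out$lc >= thresholds$lc_min & out$lift > 0]
  scale_ref <- if (length(eligible)) max(log(eligible)) else -Inf
  if (!is.finite(scale_ref) || scale_ref <= 0) {
    message("no pair exceeds independence; empty score set")
    out <- out[0, , drop = FALSE]
    out$rs <- numeric(0)
    return(finish_scores(out, NA_real_, thresholds))
  }
  out$rs <- ifelse(out$lift > 1,
                   pmin(100, pmax(0, 100 * log(out$lift) / scale_ref)), 0)
  out <- out[out$rs > thresholds$rs_min & out$lc > thresholds$lc_min, ,
             drop = FALSE]
  finish_scores(out, scale_ref, thresholds)
}

finish_scores <- function(out, scale_ref, thresholds) {
  if (nrow(out)) {
    out <- out[order(-out$rs, -out$lc, out$concept_a, out$concept_b), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "scale_ref") <- scale_ref
  attr(out, "thresholds") <- thresholds
  class(out) <- c("lit_scores", "data.frame")
  out
}

#' Literature neighbours of one concept
#'
#' All partners of `concept_id` within `category_filter` passing the
#' thresholds, ranked by rs descending (ties: lc descending, then partner
#' id). Consistent with [score_category_pairs()]: the neighbour list is
#' exactly that run's rows involving the query concept, so rs values share
#' the run's scale_ref.
#'
#' @param index A `lit_index`.
#' @param concept_id Query concept id.
#' @param category_filter Category of the partners to return.
#' @param thresholds A [lit_thresholds()].
#' @return A `lit_scores` data.frame with a `partner` column added.
#' @export
literature_neighbours <- function(index, concept_id, category_filter,
                                  thresholds = lit_thresholds()) {
  stopifnot(inherits(index, "lit_index"))
  if (is.null(index$by_concept[[concept_id]])) {
    stop_litnet("unknown concept: %s", concept_id)
  }
  cat_q <- index$categories[[concept_id]]
  sc <- score_category_pairs(index, cat_q, category_filter, thresholds)
  sel <- sc$concept_a == concept_id | sc$concept_b == concept_id
  out <- sc[sel, , drop = FALSE]
  out$partner <- ifelse(out$concept_a == concept_id, out$concept_b, out$concept_a)
  out <- out[order(-out$rs, -out$lc, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale_ref") <- attr(sc, "scale_ref")
  attr(out, "thresholds") <- thresholds
  out
}

#' Write a score table to TSV
#'
#' The header records the run's scale_ref, thresholds and, when given, the
#' corpus hash, so scores can be traced and reproduced.
#'
#' @param scores A `lit_scores` data.frame.
#' @param path Output path.
#' @param corpus_hash Optional corpus fingerprint (see [corpus_hash()]).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, corpus_hash = NULL) {
  th <- attr(scores, "thresholds")
  hdr <- sprintf("#scale_ref=%.12g rs_min=%g lc_min=%d corpus_hash=%s",
                 attr(scores, "scale_ref") %||% NA_real_,
                 th$rs_min %||% NA_real_, th$lc_min %||% NA_integer_,
                 corpus_hash %||% "NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(scores), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Build a gene x disease profile matrix from passing scores
#'
#' Entry (g, d) holds the pair's rs when it passed the scoring thresholds,
#' else 0. Columns are disease profiles over genes; this matrix is the
#' input to disease clustering.
#'
#' @param scores A `lit_scores` data.frame (typically from
#'   `score_category_pairs(index, "gene", "disease", lit_thresholds(35, 5))`).
#' @param genes,diseases Row and column concept ids (non-empty).
#' @return Numeric matrix with gene rownames and disease colnames.
#' @export
build_profile_matrix <- function(scores, genes, diseases) {
  if (!length(genes)) stop_litnet("empty gene list")
  if (!length(diseases)) stop_litnet("empty disease list")
  m <- matrix(0, length(genes), length(diseases),
              dimnames = list(genes, diseases))
  sc <- scores[scores$concept_a %in% genes & scores$concept_b %in% diseases |
               scores$concept_b %in% genes & scores$concept_a %in% diseases, ,
               drop = FALSE]
  if (nrow(sc)) {
    g <- ifelse(sc$concept_a %in% genes, sc$concept_a, sc$concept_b)
    d <- ifelse(sc$concept_a %in% genes, sc$concept_b, sc$concept_a)
    keep <- g %in% genes & d %in% diseases
    m[cbind(g[keep], d[keep])] <- sc$rs[keep]
  }
  m
}

#' Keep the top-k disease columns by number of gene associations
#'
#' @param profile Matrix from [build_profile_matrix()].
#' @param k Number of columns to keep (ties broken by column name).
#' @return The column-subset matrix, ordered by association count.
#' @export
top_k_diseases <- function(profile, k) {
  counts <- colSums(profile > 0)
  ord <- order(-counts, colnames(profile))
  profile[, ord[seq_len(min(k, ncol(profile)))], drop = FALSE]
}

#' Write a profile matrix as dense TSV
#'
#' @param profile Matrix from [build_profile_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(profile, path) {
  df <- data.frame(gene = rownames(profile), profile, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_matrix()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames.
#' @export
read_profile_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
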