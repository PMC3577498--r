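# Synthetic thesaurus + corpus generator with planted, known structure.
#
# The generative model: every document mentions every concept
# independently with probability background_rate; in addition, for each
# planted pair (a, b, q) a document co-mentions both members with
# probability q (a "forced" co-mention event, independent per document and
# per pair). Planted structure built from such pairs:
#   * independent gene-disease pairs (association-recovery truth),
#   * disease blocks sharing gene partners (clustering truth),
#   * a hub gene with many gene partners and a small gene clique
#     (topology truth),
#   * a drug linked to a known gene set (enrichment truth).
# Mentions are injected as literal synonym strings embedded in template
# sentences, so the tagger is exercised rather than bypassed: the planted
# truth flows through the text. Synonym tokens are generated collision-free
# by construction (letter prefix + zero-padded number, disjoint from the
# lowercase filler vocabulary). No natural-language realism is claimed.

filler_words <- function() {
  c("the", "of", "in", "and", "was", "were", "with", "for", "after",
    "during", "observed", "measured", "levels", "subjects", "patients",
    "controls", "baseline", "treatment", "response", "effects", "analysis",
    "study", "cohort", "plasma", "tissue", "cells", "expression",
    "significant", "increased", "decreased", "compared", "groups")
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults are the package's reference study conditions: a 200-concept
#' vocabulary (120 genes, 50 diseases, 30 drugs) over 2,000 documents with
#' a 1% per-concept background mention rate, and planted excess
#' co-mention probabilities of 0.010-0.015. Under the closed-form model
#' (see [expected_pair_stats()]) the independent planted gene-disease
#' pairs then have expected lift ~ 25 and expected literature count ~ 20.
#'
#' @param n_genes,n_diseases,n_drugs Vocabulary sizes.
#' @param n_docs Number of documents.
#' @param background_rate Per-concept per-document mention probability.
#' @param seed Integer seed (mandatory; the generator is fully
#'   deterministic given the config).
#' @param plant Logical: plant the default structure (pairs, blocks, hub,
#'   clique, enriched drug)? If FALSE only background text is generated.
#' @param planted_pairs Optional data.frame (a, b, q) replacing the
#'   default planted pair set; `plant` is then ignored.
#' @return A `lit_generator_config` list; `$pairs` holds every planted
#'   pair and `$truth_groups` the structured truth (blocks, hub, clique,
#'   enriched keyword).
#' @export
generator_config <- function(n_genes = 120, n_diseases = 50, n_drugs = 30,
                             n_docs = 2000, background_rate = 0.01,
                             seed, plant = TRUE, planted_pairs = NULL) {
  if (missing(seed)) stop_litnet("seed is mandatory")
  stopifnot(background_rate >= 0, background_rate <= 1,
            n_genes >= 1, n_diseases >= 1, n_drugs >= 0, n_docs >= 1)
  genes <- sprintf("G%04d", seq_len(n_genes))
  diseases <- sprintf("D%04d", seq_len(n_diseases))
  drugs <- sprintf("R%04d", seq_len(n_drugs))
  pairs <- data.frame(a = character(0), b = character(0), q = numeric(0),
                      role = character(0), stringsAsFactors = FALSE)
  truth_groups <- list()
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("a", "b", "q") %in% names(planted_pairs)))
    pairs <- planted_pairs
    if (is.null(pairs$role)) pairs$role <- "custom"
  } else if (plant) {
    stopifnot(n_genes >= 112, n_diseases >= 16, n_drugs >= 1)
    # independent gene-disease pairs
    ind <- data.frame(a = genes[1:10], b = diseases[1:10], q = 0.010,
                      role = "independent")
    # two disease blocks sharing gene partners
    blk1 <- expand.grid(a = genes[11:14], b = diseases[11:13],
                        stringsAsFactors = FALSE)
    blk2 <- expand.grid(a = genes[15:18], b = diseases[14:16],
                        stringsAsFactors = FALSE)
    blocks <- rbind(cbind(blk1, q = 0.012, role = "block1"),
                    cbind(blk2, q = 0.012, role = "block2"))
    # hub gene with many partners
    hub <- data.frame(a = genes[100], b = genes[101:112], q = 0.010,
                      role = "hub")
    # clique of four genes
    cl <- t(utils::combn(genes[30:33], 2))
    clique <- data.frame(a = cl[, 1], b = cl[, 2], q = 0.012, role = "clique")
    # enriched drug keyword over a known gene set
    enr <- data.frame(a = genes[40:49], b = drugs[1], q = 0.015,
                      role = "enriched_drug")
    pairs <- rbind(ind, blocks, hub, clique, enr)
    truth_groups <- list(
      blocks = list(list(diseases = diseases[11:13], genes = genes[11:14]),
                    list(diseases = diseases[14:16], genes = genes[15:18])),
      hub = list(gene = genes[100], partners = genes[101:112]),
      clique = genes[30:33],
      enriched = list(keyword = drugs[1], genes = genes[40:49]))
  }
  vocab <- c(genes, diseases, drugs)
  bad <- setdiff(unique(c(pairs$a, pairs$b)), vocab)
  if (length(bad)) stop_litnet("planted ids outside vocabulary: %s",
                               paste(bad, collapse = ", "))
  stopifnot(all(pairs$q >= 0 & pairs$q <= 1))
  structure(list(n_genes = n_genes, n_diseases = n_diseases,
                 n_drugs = n_drugs, n_docs = n_docs,
                 background_rate = background_rate, seed = as.integer(seed),
                 genes = genes, diseases = diseases, drugs = drugs,
                 pairs = pairs, truth_groups = truth_groups),
            class = "lit_generator_config")
}

synthetic_thesaurus <- function(config) {
  mk <- function(ids, category, prefix) {
    lapply(seq_along(ids), function(i) {
      nm <- sprintf("%s%04d", prefix, i)
      list(concept_id = ids[[i]], category = category, preferred_name = nm,
           synonyms = c(nm, paste0(nm, "X")))
    })
  }
  lit_thesaurus(c(mk(config$genes, "gene", "GEN"),
                  mk(config$diseases, "disease", "DIS"),
                  mk(config$drugs, "drug", "DRG")))
}

#' Generate a synthetic thesaurus, corpus and planted truth
#'
#' Deterministic given the config (same config + seed gives a
#' byte-identical corpus). See [generator_config()] for the model.
#'
#' @param config A `lit_generator_config`.
#' @return List with `thesaurus` (`lit_thesaurus`), `corpus`
#'   (`lit_corpus`) and `truth` (planted pairs and structured groups).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "lit_generator_config"))
  set.seed(config$seed)
  th <- synthetic_thesaurus(config)
  vocab <- names(th$concepts)
  n_docs <- config$n_docs
  n_con <- length(vocab)
  M <- matrix(stats::runif(n_docs * n_con) < config$background_rate,
              n_docs, n_con, dimnames = list(NULL, vocab))
  for (j in seq_len(nrow(config$pairs))) {
    force <- stats::runif(n_docs) < config$pairs$q[[j]]
    M[force, config$pairs$a[[j]]] <- TRUE
    M[force, config$pairs$b[[j]]] <- TRUE
  }
  # synonym strings per mention: preferred name or its X-variant
  syn1 <- vapply(th$concepts, function(cc) cc$synonyms[[1]], "")
  syn2 <- vapply(th$concepts, function(cc) cc$synonyms[[2]], "")
  w <- which(M, arr.ind = TRUE)
  pick <- stats::runif(nrow(w)) < 0.7
  mention_str <- ifelse(pick, syn1[w[, 2]], syn2[w[, 2]])
  by_doc <- split(mention_str, factor(w[, 1], levels = seq_len(n_docs)))
  words <- filler_words()
  fill <- matrix(sample(words, n_docs * 8, replace = TRUE), n_docs, 8)
  abstracts <- vapply(seq_len(n_docs), function(i) {
    lead <- paste(fill[i, 1:4], collapse = " ")
    tail_ <- paste(fill[i, 5:8], collapse = " ")
    ms <- by_doc[[i]]
    if (length(ms)) {
      paste0("The role of ", paste(ms, collapse = ", "),
             " ", lead, ". Further ", tail_, ".")
    } else {
      paste0("The ", lead, ". Further ", tail_, ".")
    }
  }, "")
  titles <- paste("Observations", fill[, 1], fill[, 2], "cohort")
  docs <- data.frame(doc_id = sprintf("%07d", seq_len(n_docs)),
                     title = titles, abstract = abstracts,
                     year = sample(1990:2013, n_docs, replace = TRUE),
                     stringsAsFactors = FALSE)
  truth <- c(list(pairs = config$pairs), config$truth_groups)
  list(thesaurus = th, corpus = new_corpus(docs), truth = truth)
}

#' Closed-form expected pair statistics under the generative model
#'
#' For concepts a and b with background rate b0 and planted pair excesses
#' q_j: the marginal mention probability of a concept c is
#' 1 - (1 - b0) * prod(1 - q_j) over pairs containing c; the joint
#' probability follows by inclusion-exclusion with
#' P(neither) = (1 - b0)^2 * prod(1 - q_j) over pairs touching a or b.
#' Expected lift is P(both) / (P(a) P(b)); a background-only pair has
#' lift exactly 1. Used by tests to decide which planted pairs are strong
#' enough to demand recovery at given thresholds.
#'
#' @param config A `lit_generator_config`.
#' @param a,b Concept ids from the config vocabulary.
#' @return List: m_a, m_b (marginals), p_joint, lift, expected_lc.
#' @export
expected_pair_stats <- function(config, a, b) {
  stopifnot(inherits(config, "lit_generator_config"))
  vocab <- c(config$genes, config$diseases, config$drugs)
  if (!all(c(a, b) %in% vocab)) stop_litnet("pair not in vocabulary")
  P <- config$pairs
  b0 <- config$background_rate
  marg <- function(cc) {
    qs <- P$q[P$a == cc | P$b == cc]
    1 - (1 - b0) * prod(1 - qs)
  }
  m_a <- marg(a); m_b <- marg(b)
  touch <- P$a %in% c(a, b) | P$b %in% c(a, b)
  p_neither <- (1 - b0)^2 * prod(1 - P$q[touch])
  p_joint <- m_a + m_b - 1 + p_neither
  lift <- if (m_a > 0 && m_b > 0) p_joint / (m_a * m_b) else 0
  list(m_a = m_a, m_b = m_b, p_joint = p_joint, lift = lift,
       expected_lc = config$n_docs * p_joint)
}

#' Expected lift of a pair under the generative model
#'
#' @inheritParams expected_pair_stats
#' @return A single number; 1 for background-only pairs.
#' @export
expected_pair_lift <- function(config, a, b) {
  expected_pair_stats(config, a, b)$lift
}

#' Simulate a profile matrix with planted disease blocks
#'
#' Direct generator of a gene x disease rs-profile matrix with a known
#' block-correlation structure, for studying the clustering stage in
#' isolation: columns within a block share a per-gene latent factor with
#' loading sqrt(rho); between-block correlation is 0. Values are mapped
#' to the rs scale as 50 + 15 z, clipped to [0, 100] (the clip binds with
#' probability < 1e-3 per entry, so column correlations stay within
#' sampling error of rho).
#'
#' @param n_genes Number of rows.
#' @param block_sizes Integer vector: diseases per block.
#' @param rho Within-block profile correlation target (default 0.9).
#' @param n_noise_cols Extra unblocked (pure noise) disease columns.
#' @param seed Integer seed.
#' @return List: `profile` (matrix) and `blocks` (list of column-id sets).
#' @export
simulate_profile_matrix <- function(n_genes = 40, block_sizes = c(5, 5),
                                    rho = 0.9, n_noise_cols = 0, seed) {
  if (missing(seed)) stop_litnet("seed is mandatory")
  stopifnot(rho >= 0, rho <= 1, all(block_sizes >= 2))
  set.seed(as.integer(seed))
  n_cols <- sum(block_sizes) + n_noise_cols
  cols <- sprintf("D%04d", seq_len(n_cols))
  z <- matrix(0, n_genes, n_cols)
  blocks <- list()
  at <- 0L
  for (k in seq_along(block_sizes)) {
    f <- stats::rnorm(n_genes)
    for (j in seq_len(block_sizes[[k]])) {
      at <- at + 1L
      z[, at] <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n_genes)
    }
    blocks[[k]] <- cols[(at - block_sizes[[k]] + 1L):at]
  }
  while (at < n_cols) { # unblocked noise columns
    at <- at + 1L
    z[, at] <- stats::rnorm(n_genes)
  }
  profile <- matrix(pmin(100, pmax(0, 50 + 15 * z)), n_genes, n_cols,
                    dimnames = list(sprintf("G%04d", seq_len(n_genes)), cols))
  list(profile = profile, blocks = blocks)
}

#' Write planted truth as a JSON sidecar
#'
#' @param truth Truth list from [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
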