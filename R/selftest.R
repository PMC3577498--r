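# End-to-end selftest: runs the bundled synthetic fixture through every
# pipeline stage (simulate -> tag -> associations -> network -> enrich ->
# cluster -> score) with a fixed seed, checks each stage against the
# planted truth, and verifies that the final candidate gene list is
# byte-identical to the copy shipped in inst/extdata/ (a regression
# fingerprint of the whole pipeline).

SELFTEST_SEED <- 20130204L

#' Run the end-to-end pipeline selftest
#'
#' @param out_dir Directory for stage outputs (created if needed).
#' @param seed Seed for the bundled fixture (fixed by default; changing it
#'   invalidates the byte-identity check against the shipped candidate
#'   list).
#' @return List: `ok` (all stages passed), `failed` (stage names),
#'   `stages` (data.frame stage/ok/detail), `out_dir`.
#' @export
run_selftest <- function(out_dir = tempfile("litnet_selftest_"),
                         seed = SELFTEST_SEED) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, ok, detail) {
    cli_log("selftest %-12s %s (%s)", stage, if (ok) "ok" else "FAIL", detail)
    stages[[length(stages) + 1L]] <<- data.frame(stage = stage, ok = ok,
                                                 detail = detail)
  }

  cfg <- generator_config(seed = seed)
  sim <- generate_corpus(cfg)
  write_thesaurus(sim$thesaurus, file.path(out_dir, "thesaurus.tsv"))
  write_corpus(sim$corpus, file.path(out_dir, "corpus.jsonl"))
  reread <- load_corpus(file.path(out_dir, "corpus.jsonl"))
  note("simulate", identical(reread, sim$corpus),
       sprintf("%d docs round-trip", sim$corpus$n_docs))

  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  inv_ok <- all(vapply(names(idx$by_concept), function(cc) {
    all(vapply(idx$by_concept[[cc]],
               function(d) cc %in% idx$by_doc[[d]], TRUE))
  }, TRUE))
  note("tag", inv_ok && idx$n_docs == cfg$n_docs,
       sprintf("%d mention links", sum(lengths(idx$by_concept))))

  sc_gd <- score_category_pairs(idx, "gene", "disease", lit_thresholds(35, 5))
  planted_gd <- cfg$pairs[cfg$pairs$role %in% c("independent", "block1", "block2"), ]
  found <- paste(sc_gd$concept_a, sc_gd$concept_b) # genes sort before diseases
  hit <- mean(paste(planted_gd$a, planted_gd$b) %in% found)
  note("associations", hit >= 0.9,
       sprintf("%.0f%% planted gene-disease pairs recovered", 100 * hit))

  net <- build_network(cfg$genes, idx, lit_thresholds(30, 5))
  deg <- igraph::degree(net)
  hub_ok <- names(which.max(deg)) == cfg$truth_groups$hub$gene
  export_network(net, file.path(out_dir, "network.graphml"), "graphml")
  note("network", hub_ok,
       sprintf("%d edges, max degree %d at %s", igraph::ecount(net),
               max(deg), names(which.max(deg))))

  enr <- enrich(cfg$truth_groups$enriched$genes, idx, "drug",
                lit_thresholds(30, 5), alpha = 0.05)
  write_enrichment(enr, file.path(out_dir, "enrichment.tsv"))
  enr_ok <- nrow(enr) > 0 &&
    enr$keyword_id[[1]] == cfg$truth_groups$enriched$keyword
  note("enrich", enr_ok,
       sprintf("top keyword %s (p=%.3g)",
               if (nrow(enr)) enr$keyword_id[[1]] else "none",
               if (nrow(enr)) enr$p_value[[1]] else NA))

  pm <- build_profile_matrix(sc_gd, cfg$genes, cfg$diseases)
  pm <- top_k_diseases(pm, 20)
  pm <- pm[, apply(pm, 2, stats::sd) > 0, drop = FALSE]
  cl_ok <- FALSE
  cl_detail <- "fewer than 2 disease profiles"
  if (ncol(pm) >= 2) {
    sup <- bootstrap_support(pm, B = 100, seed = seed)
    export_dendrogram(sup, file.path(out_dir, "diseases.nwk"))
    block_keys <- vapply(cfg$truth_groups$blocks, function(b) {
      paste(sort(intersect(b$diseases, colnames(pm))), collapse = "|")
    }, "")
    block_keys <- block_keys[vapply(strsplit(block_keys, "|", fixed = TRUE),
                                    length, 0L) >= 2]
    in_tree <- block_keys %in% sup$table$members
    cl_ok <- length(block_keys) > 0 && all(in_tree)
    cl_detail <- sprintf("%d/%d planted blocks in dendrogram",
                         sum(in_tree), length(block_keys))
  }
  note("cluster", cl_ok, cl_detail)

  th <- lit_thresholds(30, 5)
  hi_term <- cfg$truth_groups$enriched$keyword # the planted drug
  lo_term <- cfg$diseases[[11]]                # a planted block disease
  net <- annotate_nodes(net, idx, hi_term, "term_hi", th)
  net <- annotate_nodes(net, idx, lo_term, "term_lo", th)
  s_hi <- score_genes_for_term(net, "term_hi")
  s_lo <- score_genes_for_term(net, "term_lo")
  cand <- select_candidates(s_hi, s_lo, hi = 25, lo = 25, mode = "literature")
  cand_path <- file.path(out_dir, "candidates.tsv")
  write_gene_scores(cand, cand_path)
  ref <- system.file("extdata", "selftest_candidates.tsv", package = "litnet")
  if (nzchar(ref) && identical(seed, SELFTEST_SEED)) {
    same <- identical(readLines(cand_path), readLines(ref))
    note("score", same && nrow(cand) > 0,
         sprintf("%d candidates, fixture match: %s", nrow(cand), same))
  } else {
    note("score", nrow(cand) > 0,
         sprintf("%d candidates (no fixture comparison)", nrow(cand)))
  }

  stages <- do.call(rbind, stages)
  list(ok = all(stages$ok), failed = stages$stage[!stages$ok],
       stages = stages, out_dir = out_dir)
}
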