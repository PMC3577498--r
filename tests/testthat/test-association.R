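# Toy index used throughout: docs d1..d5; A in {d1,d2,d3}; B in {d1,d2,d4};
# C untagged. Counts were derived by hand from these sets.
toy_index <- function() {
  th <- lit_thesaurus(list(
    list(concept_id = "A", category = "gene", preferred_name = "AAA1",
         synonyms = "AAA1"),
    list(concept_id = "B", category = "disease", preferred_name = "BBB1",
         synonyms = "BBB1"),
    list(concept_id = "C", category = "drug", preferred_name = "CCC1",
         synonyms = "CCC1")))
  corpus <- toy_corpus(c("AAA1 BBB1", "AAA1 BBB1", "AAA1", "BBB1", "nothing"))
  tag_corpus(corpus, th)
}

test_that("pair_stats counts from set sizes and intersections", {
  idx <- toy_index()
  st <- pair_stats(idx, "A", "B")
  expect_equal(st[c("c_a", "c_b", "lc", "n_docs")],
               list(c_a = 3L, c_b = 3L, lc = 2L, n_docs = 5L))
  # symmetric after canonical ordering
  expect_identical(pair_stats(idx, "B", "A"), st)
  # disjoint concepts
  expect_equal(pair_stats(idx, "A", "C")$lc, 0)
  # self-pairs are undefined
  expect_error(pair_stats(idx, "A", "A"), "self-pair")
})

test_that("score_pair applies the rescaled log-lift with clipping", {
  st <- list(concept_a = "A", concept_b = "B", c_a = 3L, c_b = 3L, lc = 2L,
             n_docs = 5L)
  # lift = 2*5/9 = 10/9; if this pair carries the run's maximum log-lift,
  # rs = 100 exactly
  sc <- score_pair(st, scale_ref = log(10 / 9))
  expect_equal(sc$lift, 10 / 9)
  expect_equal(sc$rs, 100)
  # lc = 0 forces lift = 0, rs = 0
  st0 <- modifyList(st, list(lc = 0L))
  expect_equal(score_pair(st0, 1)[c("lift", "rs")], list(lift = 0, rs = 0))
  # independence boundary lift = 1 -> rs = 0
  sti <- list(concept_a = "A", concept_b = "B", c_a = 2L, c_b = 2L, lc = 2L,
              n_docs = 2L)
  expect_equal(score_pair(sti, 1)$rs, 0)
  # monotone in lift at fixed scale_ref
  lifts <- vapply(1:4, function(lc) {
    score_pair(modifyList(st, list(lc = lc)), scale_ref = log(4))$rs
  }, 0)
  expect_true(all(diff(lifts) >= 0))
})

test_that("category scoring matches the naive double-loop count oracle", {
  cfg <- small_config(seed = 31, n_docs = 250)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  oracle <- naive_pair_counts(idx, cfg$genes, cfg$diseases)
  for (key in names(oracle)) {
    ab <- strsplit(key, " ")[[1]]
    st <- pair_stats(idx, ab[[1]], ab[[2]])
    counts <- stats::setNames(c(st$c_a, st$c_b), c(st$concept_a, st$concept_b))
    expect_identical(unname(oracle[[key]]),
                     c(unname(counts[ab]), st$lc))
  }
  # the sparse-matrix run agrees with pair_stats on every returned row
  # (pair_stats orders ids canonically; match counts by concept id)
  sc <- score_category_pairs(idx, "gene", "disease", lit_thresholds(0, 0))
  for (i in seq_len(nrow(sc))) {
    st <- pair_stats(idx, sc$concept_a[[i]], sc$concept_b[[i]])
    counts <- stats::setNames(c(st$c_a, st$c_b),
                              c(st$concept_a, st$concept_b))
    expect_identical(sc$lc[[i]], st$lc)
    expect_identical(sc$c_a[[i]], unname(counts[sc$concept_a[[i]]]))
    expect_identical(sc$c_b[[i]], unname(counts[sc$concept_b[[i]]]))
  }
})

test_that("thresholds filter strictly and monotonically", {
  cfg <- small_config(seed = 13)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  sc30 <- score_category_pairs(idx, "gene", "disease", lit_thresholds(30, 5))
  expect_true(all(sc30$rs > 30 & sc30$lc > 5))
  # planted pairs dominate the passing set
  expect_true(all(paste(cfg$pairs$a, cfg$pairs$b) %in%
                  paste(sc30$concept_a, sc30$concept_b)))
  # raising lc_min never enlarges the result
  for (lc_min in c(0, 2, 5, 10, 20)) {
    sc <- score_category_pairs(idx, "gene", "disease",
                               lit_thresholds(30, lc_min))
    expect_true(all(paste(sc$concept_a, sc$concept_b) %in%
                    paste(sc30$concept_a, sc30$concept_b)) || lc_min < 5)
    if (lc_min >= 5) expect_lte(nrow(sc), nrow(sc30))
  }
  # rs = 100 boundary: only the maximal-lift pair(s) can pass rs_min = 100
  # with a non-strict clip, so a strict 100 threshold empties the set
  sc100 <- score_category_pairs(idx, "gene", "disease", lit_thresholds(100, 0))
  expect_equal(nrow(sc100), 0)
})

test_that("rs is invariant under document relabeling", {
  cfg <- small_config(seed = 17, n_docs = 150)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  relabeled <- sim$corpus
  relabeled$documents$doc_id <- sprintf("Z%05d", rev(seq_len(150)))
  idx2 <- tag_corpus(relabeled, sim$thesaurus)
  a <- score_category_pairs(idx, "gene", "disease", lit_thresholds(0, 0))
  b <- score_category_pairs(idx2, "gene", "disease", lit_thresholds(0, 0))
  cols <- c("concept_a", "concept_b", "c_a", "c_b", "lc", "lift", "rs")
  expect_identical(as.data.frame(a)[cols], as.data.frame(b)[cols])
})

test_that("literature_neighbours ranks a concept's passing partners", {
  cfg <- small_config(seed = 19)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  th <- lit_thresholds(30, 5)
  nb <- literature_neighbours(idx, "G0001", "disease", th)
  expect_true("D0001" %in% nb$partner)  # planted partner recovered
  # consistency: exactly the full run's rows touching the query
  sc <- score_category_pairs(idx, "gene", "disease", th)
  sel <- sc[sc$concept_a == "G0001" | sc$concept_b == "G0001", ]
  expect_setequal(nb$partner,
                  ifelse(sel$concept_a == "G0001", sel$concept_b,
                         sel$concept_a))
  # sorted by rs desc, ties lc desc then id
  expect_true(all(diff(nb$rs) <= 0))
  # concept with no passing partner yields an empty list
  iso <- literature_neighbours(idx, "G0020", "disease", th)
  expect_equal(nrow(iso), 0)
  expect_error(literature_neighbours(idx, "NOPE", "disease", th),
               "unknown concept")
})

test_that("profile matrix places rs values and selects top-k columns", {
  sc <- data.frame(concept_a = "g1", concept_b = "d1", c_a = 5L, c_b = 5L,
                   lc = 3L, n_docs = 10L, lift = 2, rs = 60)
  m <- build_profile_matrix(sc, c("g1", "g2"), c("d1", "d2"))
  expect_equal(m, matrix(c(60, 0, 0, 0), 2, 2,
                         dimnames = list(c("g1", "g2"), c("d1", "d2"))))
  expect_equal(colnames(top_k_diseases(m, 1)), "d1")
  expect_error(build_profile_matrix(sc, character(0), "d1"), "empty gene")

  # column nonzero counts equal per-disease result sizes of the score run
  cfg <- small_config(seed = 37)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  th <- lit_thresholds(35, 5)
  scr <- score_category_pairs(idx, "gene", "disease", th)
  pm <- build_profile_matrix(scr, cfg$genes, cfg$diseases)
  per_disease <- table(factor(scr$concept_b, levels = cfg$diseases))
  expect_equal(unname(colSums(pm > 0)), as.vector(per_disease))
})

test_that("score TSV header records the run metadata", {
  cfg <- small_config(seed = 41)
  sim <- generate_corpus(cfg)
  idx <- tag_corpus(sim$corpus, sim$thesaurus)
  sc <- score_category_pairs(idx, "gene", "disease", lit_thresholds(30, 5))
  p <- tempfile(fileext = ".tsv")
  write_scores(sc, p, corpus_hash = corpus_hash(sim$corpus))
  lines <- readLines(p)
  expect_match(lines[[1]], "^#scale_ref=")
  expect_match(lines[[1]], "rs_min=30")
  expect_match(lines[[1]], "corpus_hash=[0-9a-f]{8}")
  expect_equal(length(lines), nrow(sc) + 2L)
})
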