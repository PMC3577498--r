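# Shared fixtures: a small hand-written thesaurus/corpus pair used across
# module tests, and writers for the on-disk formats.

toy_thesaurus <- function() {
  lit_thesaurus(list(
    list(concept_id = "G1", category = "gene", preferred_name = "PCK2",
         synonyms = c("PCK2", "PEPCK-M")),
    list(concept_id = "G2", category = "gene", preferred_name = "INSR",
         synonyms = c("INSR", "insulin receptor")),
    list(concept_id = "G3", category = "gene", preferred_name = "GPD1",
         synonyms = "GPD1"),
    list(concept_id = "R1", category = "drug", preferred_name = "dexamethasone",
         synonyms = "dexamethasone"),
    list(concept_id = "D1", category = "disease",
         preferred_name = "insulin resistance",
         synonyms = c("insulin resistance", "IR")),
    list(concept_id = "D2", category = "disease", preferred_name = "insulin",
         synonyms = "insulin")))
}

toy_corpus <- function(texts, titles = NULL) {
  n <- length(texts)
  docs <- data.frame(
    doc_id = sprintf("d%d", seq_len(n)),
    title = titles %||% rep("A title", n),
    abstract = texts,
    year = NA_integer_,
    stringsAsFactors = FALSE)
  litnet:::new_corpus(docs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# small generator config used where the full default would be overkill
small_config <- function(seed, n_docs = 300, q = 0.05) {
  genes <- sprintf("G%04d", 1:20)
  diseases <- sprintf("D%04d", 1:8)
  planted <- data.frame(a = genes[1:3], b = diseases[1:3], q = q)
  generator_config(n_genes = 20, n_diseases = 8, n_drugs = 4,
                   n_docs = n_docs, background_rate = 0.02, seed = seed,
                   planted_pairs = planted)
}
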