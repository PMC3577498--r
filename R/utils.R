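# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a term for dictionary matching
#'
#' Lowercases, trims leading/trailing whitespace and collapses internal
#' whitespace runs to a single space. No stemming is applied: matching is
#' exact on normalized synonyms, so morphological variants must be listed
#' explicitly in the thesaurus.
#'
#' @param x Character vector of terms.
#' @return Character vector of normalized terms.
#' @export
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Concept categories recognized by default
#'
#' The controlled vocabulary is closed over four categories: gene, disease,
#' drug and pathway. Loaders accept a custom category set for extensions.
#'
#' @return Character vector of category names.
#' @export
concept_categories <- function() c("gene", "disease", "drug", "pathway")

# 32-bit FNV-1a over a character scalar; returns 8-hex-digit string.
# Used to fingerprint corpora in score file headers (reproducibility aid,
# not cryptographic).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261 # stored as double; xor applied to the low byte only
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Fingerprint a corpus
#'
#' Deterministic hash of document ids and text lengths, recorded in score
#' file headers so downstream results can be traced to their input corpus.
#'
#' @param corpus A `lit_corpus`.
#' @return Single hex string.
#' @export
corpus_hash <- function(corpus) {
  stopifnot(inherits(corpus, "lit_corpus"))
  d <- corpus$documents
  fnv1a32(paste(d$doc_id, nchar(d$title), nchar(d$abstract), collapse = ";"))
}

stop_litnet <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
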