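# Corpus: ordered collection of titled abstracts with PMID-like ids.
#
# Two on-disk dialects are supported: JSONL (one object per line with keys
# pmid, title, abstract, optional year) and a Medline-XML subset
# (PubmedArticle/MedlineCitation/PMID, ArticleTitle, Abstract/AbstractText).
# Both load to field-identical documents. The corpus size N is the
# denominator of every association score downstream.

new_corpus <- function(documents) {
  stopifnot(is.data.frame(documents))
  need <- c("doc_id", "title", "abstract", "year")
  if (!all(need %in% names(documents))) {
    stop_litnet("corpus documents need columns: %s", paste(need, collapse = ", "))
  }
  documents <- documents[, need, drop = FALSE]
  rownames(documents) <- NULL
  dup <- documents$doc_id[duplicated(documents$doc_id)]
  if (length(dup)) {
    stop_litnet("duplicate doc_id(s): %s", paste(unique(dup), collapse = ", "))
  }
  blank <- !nzchar(documents$title) & !nzchar(documents$abstract)
  if (any(blank)) {
    stop_litnet("document(s) with empty title and empty abstract: %s",
                paste(documents$doc_id[blank], collapse = ", "))
  }
  structure(list(documents = documents, n_docs = nrow(documents)),
            class = "lit_corpus")
}

#' Load a corpus of titled abstracts
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` (one JSON object per line, keys `pmid`, `title`,
#'   `abstract`, optional `year`) or `"medline_xml"` (PubmedArticle records;
#'   PMID, ArticleTitle and Abstract/AbstractText are read, all other
#'   elements ignored; multiple AbstractText sections are concatenated).
#' @return A `lit_corpus`: list with `documents` (data.frame with columns
#'   doc_id, title, abstract, year) and `n_docs`.
#' @export
load_corpus <- function(path, format = c("jsonl", "medline_xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_litnet("corpus file not found: %s", path)
  docs <- switch(format,
    jsonl = read_corpus_jsonl(path),
    medline_xml = read_corpus_medline(path))
  new_corpus(docs)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_litnet("empty corpus file: %s", path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stop_litnet("unparseable JSONL record %d: %s", i,
                                  conditionMessage(e))
                    })
    if (is.null(rec$pmid)) stop_litnet("JSONL record %d lacks 'pmid'", i)
    recs[[i]] <- data.frame(
      doc_id = as.character(rec$pmid),
      title = as.character(rec$title %||% ""),
      abstract = as.character(rec$abstract %||% ""),
      year = as.integer(rec$year %||% NA_integer_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

read_corpus_medline <- function(path) {
  xml <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_litnet("unparseable Medline XML: %s",
                                                  conditionMessage(e)))
  arts <- xml2::xml_find_all(xml, ".//PubmedArticle")
  if (!length(arts)) stop_litnet("no PubmedArticle records in %s", path)
  recs <- lapply(seq_along(arts), function(i) {
    art <- arts[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      stop_litnet("Medline record %d lacks a PMID", i)
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle"))
    if (is.na(title)) title <- ""
    abst <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    abstract <- if (length(abst)) paste(xml2::xml_text(abst), collapse = " ") else ""
    yr <- xml2::xml_text(xml2::xml_find_first(art, ".//PubDate/Year"))
    data.frame(doc_id = pmid, title = title, abstract = abstract,
               year = if (is.na(yr) || !nzchar(yr)) NA_integer_ else as.integer(yr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Write a corpus as JSONL
#'
#' Inverse of `load_corpus(format = "jsonl")`; round-trips unchanged.
#'
#' @param corpus A `lit_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "lit_corpus"))
  d <- corpus$documents
  lines <- vapply(seq_len(nrow(d)), function(i) {
    rec <- list(pmid = d$doc_id[[i]], title = d$title[[i]],
                abstract = d$abstract[[i]])
    if (!is.na(d$year[[i]])) rec$year <- d$year[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' @export
print.lit_corpus <- function(x, ...) {
  cat(sprintf("<lit_corpus> %d documents (%d with abstracts)\n",
              x$n_docs, sum(nzchar(x$documents$abstract))))
  invisible(x)
}
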