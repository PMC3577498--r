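# Tagger: scan titles+abstracts for thesaurus synonyms and build the
# document<->concept mention index that all counting rests on.
#
# Matching semantics: case-insensitive, exact on normalized synonyms, with
# token boundaries (a hit must be flanked by non-alphanumeric characters or
# the string ends). Overlapping candidate hits are resolved longest-match
# first, so "insulin receptor" claims its span before "insulin" can. A
# concept counts at most once per document: the unit of co-occurrence is
# the abstract, and presence, not frequency, is recorded.

syn_to_pattern <- function(syn) {
  # escape regex metacharacters, then let internal whitespace match runs
  esc <- gsub("([][{}()*+?.\\\\^$|])", "\\\\\\1", syn)
  esc <- gsub(" ", "[[:space:]]+", esc, fixed = TRUE)
  paste0("(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
}

#' Tag a corpus against a thesaurus
#'
#' Links each document to every concept one of whose synonyms occurs in the
#' title or abstract (concatenated with a separator) as a token-boundary,
#' case-insensitive match. Multiple hits of one concept in one document
#' count once. Where candidate matches overlap in the text, the longest
#' match wins (ties: earlier start); shorter synonyms are not additionally
#' linked from a claimed span.
#'
#' @param corpus A `lit_corpus`.
#' @param thesaurus A `lit_thesaurus`.
#' @return A `lit_index`: list with `by_concept` (concept_id -> sorted
#'   doc_ids), `by_doc` (doc_id -> sorted concept_ids), `n_docs`,
#'   `doc_ids`, and `categories` (concept_id -> category, carried from the
#'   thesaurus for downstream category-restricted scoring).
#' @export
tag_corpus <- function(corpus, thesaurus) {
  stopifnot(inherits(corpus, "lit_corpus"), inherits(thesaurus, "lit_thesaurus"))
  texts <- paste(corpus$documents$title, corpus$documents$abstract, sep = " \r ")
  syn_names <- names(thesaurus$name_index)
  n_docs <- corpus$n_docs
  doc_ids <- corpus$documents$doc_id
  categories <- vapply(thesaurus$concepts, `[[`, "", "category")
  if (all(grepl("^[a-z0-9]+$", syn_names))) {
    # Every synonym is a single alphanumeric token: token-boundary matches
    # are whole maximal alphanumeric runs, so no two candidate matches can
    # overlap and a hash lookup of document tokens is exact. Same results
    # as the general span-matching path, much faster.
    toks <- strsplit(tolower(texts), "[^a-z0-9]+")
    ndup <- lengths(toks)
    hit_syn <- match(unlist(toks, use.names = FALSE), syn_names)
    hit_doc <- rep.int(seq_len(n_docs), ndup)
    keep <- !is.na(hit_syn)
    pairs <- unique(data.frame(doc = hit_doc[keep], syn = hit_syn[keep]))
  } else {
    hits <- list()
    for (k in seq_along(syn_names)) {
      m <- gregexpr(syn_to_pattern(syn_names[[k]]), texts,
                    perl = TRUE, ignore.case = TRUE)
      starts <- lapply(m, function(x) if (x[[1]] == -1L) integer(0) else as.integer(x))
      lens <- lapply(m, function(x) {
        if (x[[1]] == -1L) integer(0) else as.integer(attr(x, "match.length"))
      })
      nhit <- lengths(starts)
      if (!sum(nhit)) next
      hits[[length(hits) + 1L]] <- data.frame(
        doc = rep.int(seq_along(texts), nhit),
        start = unlist(starts), len = unlist(lens), syn = k)
    }
    if (!length(hits)) {
      return(empty_index(doc_ids, names(thesaurus$concepts), categories))
    }
    h <- do.call(rbind, hits)
    h$end <- h$start + h$len - 1L
    h <- resolve_overlaps(h)
    # accepted synonym hits -> concepts (ambiguous synonyms link all matches)
    pairs <- unique(h[, c("doc", "syn")])
  }
  if (!nrow(pairs)) {
    return(empty_index(doc_ids, names(thesaurus$concepts), categories))
  }
  con_per_syn <- thesaurus$name_index[pairs$syn]
  doc_rep <- rep.int(pairs$doc, lengths(con_per_syn))
  concept <- unlist(con_per_syn, use.names = FALSE)
  dc <- unique(data.frame(doc = doc_rep, concept = concept))
  by_doc_raw <- split(dc$concept, dc$doc)
  by_doc <- stats::setNames(vector("list", n_docs), doc_ids)
  for (i in seq_len(n_docs)) by_doc[[i]] <- character(0)
  for (dn in names(by_doc_raw)) {
    by_doc[[as.integer(dn)]] <- sort(unique(by_doc_raw[[dn]]))
  }
  by_concept_raw <- split(doc_ids[dc$doc], dc$concept)
  by_concept <- stats::setNames(
    rep(list(character(0)), length(thesaurus$concepts)),
    names(thesaurus$concepts))
  for (cn in names(by_concept_raw)) {
    by_concept[[cn]] <- sort(unique(by_concept_raw[[cn]]))
  }
  structure(list(by_concept = by_concept, by_doc = by_doc, n_docs = n_docs,
                 doc_ids = doc_ids, categories = categories),
            class = "lit_index")
}

empty_index <- function(doc_ids, concept_ids, categories) {
  structure(list(
    by_concept = stats::setNames(rep(list(character(0)), length(concept_ids)),
                                 concept_ids),
    by_doc = stats::setNames(rep(list(character(0)), length(doc_ids)), doc_ids),
    n_docs = length(doc_ids), doc_ids = doc_ids, categories = categories),
    class = "lit_index")
}

# Greedy longest-match-first interval selection within each document.
# Only documents whose candidate spans actually overlap pay the loop cost.
resolve_overlaps <- function(h) {
  h <- h[order(h$doc, h$start, -h$len), , drop = FALSE]
  n <- nrow(h)
  if (n < 2L) return(h)
  same_doc <- h$doc[-1L] == h$doc[-n]
  overlaps <- same_doc & (h$start[-1L] <= h$end[-n])
  bad_docs <- unique(h$doc[c(FALSE, overlaps)])
  if (!length(bad_docs)) return(h)
  clean <- h[!h$doc %in% bad_docs, , drop = FALSE]
  fixed <- lapply(bad_docs, function(d) {
    g <- h[h$doc == d, , drop = FALSE]
    g <- g[order(-g$len, g$start, g$syn), , drop = FALSE]
    keep <- logical(nrow(g))
    occ_s <- integer(0); occ_e <- integer(0)
    for (i in seq_len(nrow(g))) {
      if (!any(g$start[i] <= occ_e & g$end[i] >= occ_s)) {
        keep[i] <- TRUE
        occ_s <- c(occ_s, g$start[i]); occ_e <- c(occ_e, g$end[i])
      }
    }
    g[keep, , drop = FALSE]
  })
  rbind(clean, do.call(rbind, fixed))
}

#' Retrieve the documents mentioning each queried concept
#'
#' @param index A `lit_index`.
#' @param concept_ids Character vector of concept ids.
#' @return Named list concept_id -> sorted doc_ids (empty for unknown or
#'   untagged concepts).
#' @export
get_references <- function(index, concept_ids) {
  stopifnot(inherits(index, "lit_index"))
  out <- lapply(concept_ids, function(id) index$by_concept[[id]] %||% character(0))
  stats::setNames(out, concept_ids)
}

#' Serialize a mention index to two TSV files
#'
#' Writes `<prefix>.concept_doc.tsv` (concept -> comma-joined doc ids) and
#' `<prefix>.doc_concept.tsv` (doc -> comma-joined concept ids), each with
#' a `#n_docs=` header carrying the corpus size and a category column.
#' [read_mention_index()] restores a bit-identical index.
#'
#' @param index A `lit_index`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_mention_index <- function(index, prefix) {
  stopifnot(inherits(index, "lit_index"))
  p1 <- paste0(prefix, ".concept_doc.tsv")
  p2 <- paste0(prefix, ".doc_concept.tsv")
  cids <- names(index$by_concept)
  writeLines(c(sprintf("#n_docs=%d", index$n_docs),
               "concept_id\tcategory\tdoc_ids",
               vapply(cids, function(cc) {
                 paste(cc, index$categories[[cc]],
                       paste(index$by_concept[[cc]], collapse = ","), sep = "\t")
               }, "")), p1)
  writeLines(c(sprintf("#n_docs=%d", index$n_docs),
               "doc_id\tconcept_ids",
               vapply(names(index$by_doc), function(d) {
                 paste(d, paste(index$by_doc[[d]], collapse = ","), sep = "\t")
               }, "")), p2)
  invisible(c(p1, p2))
}

#' Reload a mention index written by [write_mention_index()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `lit_index`.
#' @export
read_mention_index <- function(prefix) {
  p1 <- paste0(prefix, ".concept_doc.tsv")
  p2 <- paste0(prefix, ".doc_concept.tsv")
  if (!file.exists(p1) || !file.exists(p2)) {
    stop_litnet("mention index files not found at prefix %s", prefix)
  }
  l1 <- readLines(p1); l2 <- readLines(p2)
  n_docs <- as.integer(sub("#n_docs=", "", l1[[1]], fixed = TRUE))
  parse_multi <- function(x) if (!nzchar(x)) character(0) else
    strsplit(x, ",", fixed = TRUE)[[1]]
  rows1 <- strsplit(l1[-(1:2)], "\t", fixed = TRUE)
  by_concept <- stats::setNames(
    lapply(rows1, function(f) parse_multi(if (length(f) >= 3) f[[3]] else "")),
    vapply(rows1, `[[`, "", 1L))
  categories <- stats::setNames(vapply(rows1, `[[`, "", 2L),
                                vapply(rows1, `[[`, "", 1L))
  rows2 <- strsplit(l2[-(1:2)], "\t", fixed = TRUE)
  by_doc <- stats::setNames(
    lapply(rows2, function(f) parse_multi(if (length(f) >= 2) f[[2]] else "")),
    vapply(rows2, `[[`, "", 1L))
  structure(list(by_concept = by_concept, by_doc = by_doc, n_docs = n_docs,
                 doc_ids = names(by_doc), categories = categories),
            class = "lit_index")
}

#' @export
print.lit_index <- function(x, ...) {
  tagged <- sum(lengths(x$by_concept) > 0)
  cat(sprintf("<lit_index> %d docs, %d/%d concepts tagged, %d mention links\n",
              x$n_docs, tagged, length(x$by_concept),
              sum(lengths(x$by_concept))))
  invisible(x)
}
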