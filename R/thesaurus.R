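# Thesaurus: controlled vocabulary of genes, diseases, drugs and pathways.
#
# A thesaurus maps opaque concept identifiers to named concepts with synonym
# lists, plus an inverted index from normalized synonyms to concept ids. All
# tagging and counting downstream operates on concept ids, mirroring the
# "biological identifier" indirection of thesaurus-based literature mining
# systems: free-text names are resolved to identifiers once, up front.

new_concept <- function(concept_id, category, preferred_name, synonyms,
                        categories = concept_categories()) {
  concept_id <- as.character(concept_id)
  category <- as.character(category)
  preferred_name <- as.character(preferred_name)
  synonyms <- as.character(synonyms)
  if (!nzchar(concept_id)) stop_litnet("concept_id must be a non-empty string")
  if (!category %in% categories) {
    stop_litnet("unknown category '%s' for concept '%s' (allowed: %s)",
                category, concept_id, paste(categories, collapse = ", "))
  }
  synonyms <- unique(c(preferred_name, synonyms))
  if (any(!nzchar(synonyms))) {
    stop_litnet("concept '%s' has an empty synonym", concept_id)
  }
  list(concept_id = concept_id, category = category,
       preferred_name = preferred_name, synonyms = synonyms)
}

build_name_index <- function(concepts) {
  syn <- lapply(concepts, function(cc) {
    data.frame(name = normalize_term(cc$synonyms), id = cc$concept_id,
               stringsAsFactors = FALSE)
  })
  syn <- do.call(rbind, syn)
  idx <- split(syn$id, syn$name)
  lapply(idx, function(ids) sort(unique(ids)))
}

#' Construct a thesaurus from a list of concepts
#'
#' @param concepts List of concept entries, each a list with fields
#'   `concept_id`, `category`, `preferred_name`, `synonyms`.
#' @param categories Allowed category set; defaults to the closed set of
#'   [concept_categories()].
#' @return A `lit_thesaurus`: list with `concepts` (named list, keyed and
#'   ordered by input order) and `name_index` (normalized synonym ->
#'   sorted concept ids).
#' @export
lit_thesaurus <- function(concepts, categories = concept_categories()) {
  concepts <- lapply(concepts, function(cc) {
    new_concept(cc$concept_id, cc$category, cc$preferred_name, cc$synonyms,
                categories = categories)
  })
  ids <- vapply(concepts, `[[`, "", "concept_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_litnet("duplicate concept_id(s): %s", paste(unique(dup), collapse = ", "))
  }
  names(concepts) <- ids
  structure(list(concepts = concepts, name_index = build_name_index(concepts)),
            class = "lit_thesaurus")
}

#' Load a thesaurus from TSV
#'
#' Expected header: `concept_id  category  preferred_name  synonyms`, with
#' synonyms pipe-separated. UTF-8. The preferred name is always included in
#' the synonym set whether or not it is repeated in the synonyms column.
#'
#' @param path Path to a TSV file.
#' @param categories Allowed category set.
#' @return A `lit_thesaurus`.
#' @export
load_thesaurus <- function(path, categories = concept_categories()) {
  if (!file.exists(path)) stop_litnet("thesaurus file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop_litnet("empty thesaurus file: %s", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  want <- c("concept_id", "category", "preferred_name", "synonyms")
  if (!identical(header, want)) {
    stop_litnet("bad thesaurus header (line 1): expected '%s'",
                paste(want, collapse = "\\t"))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  concepts <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) {
      stop_litnet("malformed thesaurus row at line %d: expected 4 fields, got %d",
                  i + 1L, length(f))
    }
    syns <- strsplit(f[[4]], "|", fixed = TRUE)[[1]]
    concepts[[i]] <- tryCatch(
      new_concept(f[[1]], f[[2]], f[[3]], syns, categories = categories),
      error = function(e) stop_litnet("line %d: %s", i + 1L, conditionMessage(e)))
  }
  lit_thesaurus(concepts, categories = categories)
}

#' Write a thesaurus to TSV
#'
#' Inverse of [load_thesaurus()]: writing and reloading yields an identical
#' object (same concept order, same synonym order).
#'
#' @param thesaurus A `lit_thesaurus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(thesaurus, path) {
  stopifnot(inherits(thesaurus, "lit_thesaurus"))
  rows <- vapply(thesaurus$concepts, function(cc) {
    paste(cc$concept_id, cc$category, cc$preferred_name,
          paste(cc$synonyms, collapse = "|"), sep = "\t")
  }, "")
  writeLines(c("concept_id\tcategory\tpreferred_name\tsynonyms", rows),
             path, useBytes = FALSE)
  invisible(path)
}

#' Resolve free-text terms to concept ids
#'
#' Lookup is case-insensitive on normalized synonyms (lowercase, trimmed,
#' internal whitespace collapsed). Ambiguity is preserved: a synonym shared
#' by several concepts returns all of them. Unknown terms map to an empty
#' set rather than an error, signalling "not in thesaurus".
#'
#' @param thesaurus A `lit_thesaurus`.
#' @param queries Character vector of free-text terms.
#' @return Named list, one element per query, each a (possibly empty)
#'   character vector of concept ids.
#' @export
resolve_terms <- function(thesaurus, queries) {
  stopifnot(inherits(thesaurus, "lit_thesaurus"))
  keys <- normalize_term(queries)
  out <- lapply(keys, function(k) {
    hit <- thesaurus$name_index[[k]]
    if (is.null(hit)) character(0) else hit
  })
  names(out) <- queries
  out
}

#' Concept ids belonging to a category
#'
#' @param thesaurus A `lit_thesaurus`.
#' @param category Category name.
#' @return Character vector of concept ids, in thesaurus order.
#' @export
concepts_of_category <- function(thesaurus, category) {
  stopifnot(inherits(thesaurus, "lit_thesaurus"))
  cats <- vapply(thesaurus$concepts, `[[`, "", "category")
  names(cats)[cats == category]
}

#' @export
print.lit_thesaurus <- function(x, ...) {
  cats <- table(vapply(x$concepts, `[[`, "", "category"))
  cat(sprintf("<lit_thesaurus> %d concepts (%s); %d distinct synonyms\n",
              length(x$concepts),
              paste(sprintf("%s: %d", names(cats), cats), collapse = ", "),
              length(x$name_index)))
  invisible(x)
}
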