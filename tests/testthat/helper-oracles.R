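# Independent oracles used by unit and acceptance tests. Each reimplements
# the quantity under test with different primitives than the package path
# (loops and exhaustive enumeration instead of sparse algebra, closed
# distributions or igraph routines).

# pair counts by naive double loop over by_doc (the inverse map of the
# representation the package counts from)
naive_pair_counts <- function(index, ids_a, ids_b) {
  docs_of <- lapply(stats::setNames(union(ids_a, ids_b), union(ids_a, ids_b)),
                    function(cc) {
    hits <- character(0)
    for (d in names(index$by_doc)) {
      if (cc %in% index$by_doc[[d]]) hits <- c(hits, d)
    }
    hits
  })
  out <- list()
  for (a in ids_a) for (b in ids_b) {
    if (a >= b && identical(sort(ids_a), sort(ids_b))) next
    if (a == b) next
    lc <- sum(docs_of[[a]] %in% docs_of[[b]])
    out[[paste(a, b)]] <- c(c_a = length(docs_of[[a]]),
                            c_b = length(docs_of[[b]]), lc = lc)
  }
  out
}

# exact hypergeometric upper tail by combinatorial summation
hyper_tail_exact <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force betweenness by matrix-power path counting: sigma_st equals
# the number of walks of shortest length, so (A^d)[s,t] at d = d(s,t)
brute_betweenness <- function(A) {
  n <- nrow(A)
  P <- vector("list", n)
  P[[1]] <- A
  for (d in 2:n) P[[d]] <- P[[d - 1]] %*% A
  D <- matrix(Inf, n, n)
  for (d in 1:n) D[P[[d]] > 0 & is.infinite(D)] <- d
  diag(D) <- 0
  sigma <- function(s, t) if (s == t) 1 else P[[D[s, t]]][s, t]
  btw <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + sigma(s, v) * sigma(v, t) / sigma(s, t)
      }
    }
    btw[v] <- tot
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# independent evaluation of the neighbor-weighted literature score by
# scalar accumulation loops
brute_literature_score <- function(g1, g, rg) {
  if (!length(g)) return(g1)
  num <- 0
  den <- 0
  for (i in seq_along(g)) {
    num <- num + rg[i] * g[i]
    den <- den + rg[i]
  }
  (g1 + num / den) / 2
}

# naive per-document regex tagger (token boundaries, longest-match-first)
naive_tag <- function(corpus, thesaurus) {
  texts <- paste(corpus$documents$title, corpus$documents$abstract,
                 sep = " \r ")
  syns <- names(thesaurus$name_index)
  by_doc <- stats::setNames(vector("list", corpus$n_docs),
                            corpus$documents$doc_id)
  for (i in seq_along(texts)) {
    cand <- list()
    for (k in seq_along(syns)) {
      pat <- litnet:::syn_to_pattern(syns[[k]])
      m <- gregexpr(pat, texts[[i]], perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[[1]] == -1L) next
      for (j in seq_along(m)) {
        cand[[length(cand) + 1L]] <- list(
          start = m[[j]], end = m[[j]] + attr(m, "match.length")[[j]] - 1L,
          syn = k)
      }
    }
    if (!length(cand)) { by_doc[[i]] <- character(0); next }
    lens <- vapply(cand, function(x) x$end - x$start + 1L, 0L)
    starts <- vapply(cand, function(x) x$start, 0L)
    cand <- cand[order(-lens, starts)]
    taken <- logical(nchar(texts[[i]]))
    hits <- integer(0)
    for (x in cand) {
      if (!any(taken[x$start:x$end])) {
        taken[x$start:x$end] <- TRUE
        hits <- c(hits, x$syn)
      }
    }
    by_doc[[i]] <- sort(unique(unlist(thesaurus$name_index[unique(hits)])))
  }
  by_doc
}
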