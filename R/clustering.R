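# Disease-profile clustering with bootstrap support.
#
# Disease columns of the gene x disease profile matrix are compared by
# correlation distance (1 - Pearson r over genes) and clustered by
# complete-linkage agglomeration. Cluster support comes from multiscale
# bootstrap resampling of the genes (the observations underlying each
# profile): at each scale r the genes are resampled with replacement to
# round(r * n) rows, the tree is rebuilt, and the per-cluster bootstrap
# proportion BP_r (exact leaf-set recurrence) is recorded. The
# approximately unbiased (AU) support extrapolates these proportions to
# scale 0 through the probit fit
#
#     qnorm(1 - BP_r) ~ v * sqrt(r) + c / sqrt(r)   (weighted LS)
#     AU = (1 - pnorm(v - c)) * 100,   BP reported at r = 1.
#
# Scales where BP_r is exactly 0 or 1 carry no gradient information and
# are excluded from the fit; a cluster degenerate at (almost) every scale
# is reported directly as AU = 100 (seen in every replicate) or AU = 0
# (never seen, flagged).

#' Correlation distance between disease profiles
#'
#' d(i, j) = 1 - Pearson correlation of columns i and j; in [0, 2].
#' Constant columns have no defined correlation and are rejected.
#'
#' @param profile Numeric matrix, genes x diseases (>= 2 columns).
#' @return A `dist` object over the columns.
#' @export
profile_distance <- function(profile) {
  if (ncol(profile) < 2) stop_litnet("need at least 2 disease columns")
  sds <- apply(profile, 2, stats::sd)
  if (any(sds == 0)) {
    stop_litnet("constant column(s), correlation undefined: %s",
                paste(colnames(profile)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(profile))
}

# distance for bootstrap replicates: undefined correlations (constant
# resampled columns) are treated as correlation 0, i.e. distance 1
profile_distance_safe <- function(profile) {
  suppressWarnings(cc <- stats::cor(profile))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 1
  stats::as.dist(1 - cc)
}

#' Complete-linkage hierarchical clustering
#'
#' Standard agglomerative clustering. For determinism under input
#' reordering, items are put in lexicographic label order before linkage,
#' so ties resolve by smallest member id.
#'
#' @param distances A `dist` object (or symmetric matrix with dimnames).
#' @param linkage Linkage method; `"complete"` (the default) is the
#'   supported surface, other stats::hclust methods pass through untested.
#' @return An `hclust` object.
#' @export
hcluster <- function(distances, linkage = "complete") {
  if (is.matrix(distances)) {
    if (nrow(distances) != ncol(distances) ||
        any(abs(distances - t(distances)) > 1e-12)) {
      stop_litnet("distance matrix must be square and symmetric")
    }
    distances <- stats::as.dist(distances)
  }
  labs <- attr(distances, "Labels")
  if (!is.null(labs)) {
    m <- as.matrix(distances)
    ord <- order(labs)
    distances <- stats::as.dist(m[ord, ord])
  }
  stats::hclust(distances, method = linkage)
}

# leaf-id sets of all internal nodes of an hclust tree, as canonical keys
cluster_keys <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- tree$merge[i, ]
    members[[i]] <- c(
      if (m[1] < 0) tree$labels[-m[1]] else members[[m[1]]],
      if (m[2] < 0) tree$labels[-m[2]] else members[[m[2]]])
  }
  vapply(members, function(x) paste(sort(x), collapse = "|"), "")
}

#' Multiscale bootstrap support for profile clusters
#'
#' Builds the reference complete-linkage tree of the disease profiles,
#' then resamples genes with replacement at each scale in `scales`,
#' rebuilds the tree B times per scale, and records per reference cluster
#' the proportion of replicates containing it (exact leaf-set equality).
#' AU values extrapolate across scales as described above; BP is the
#' proportion at scale 1 (the scale closest to 1 if 1 is not in the grid).
#'
#' @param profile Numeric matrix, genes x diseases.
#' @param B Bootstrap replicates per scale (>= 1; 100 is the conventional
#'   default).
#' @param scales Resampling ratios r (resample size round(r * n_genes));
#'   default 0.5..1.4 in steps of 0.1.
#' @param seed Optional integer seed for reproducible resampling.
#' @return A `lit_cluster_support` list: `tree` (reference hclust),
#'   `table` (data.frame: node, size, members, bp, au, v, c, flag),
#'   `bp_by_scale` (clusters x scales matrix), `scales`, `B`.
#' @export
bootstrap_support <- function(profile, B = 100,
                              scales = seq(0.5, 1.4, by = 0.1),
                              seed = NULL) {
  stopifnot(B >= 1, all(scales > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profile)
  tree <- hcluster(profile_distance(profile))
  keys <- cluster_keys(tree)
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, 0L)
  bp_mat <- matrix(0, length(keys), length(scales),
                   dimnames = list(NULL, sprintf("r=%g", scales)))
  for (s in seq_along(scales)) {
    m <- max(2L, as.integer(round(scales[[s]] * n)))
    count <- numeric(length(keys))
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = TRUE)
      rep_tree <- hcluster(profile_distance_safe(profile[idx, , drop = FALSE]))
      count <- count + (keys %in% cluster_keys(rep_tree))
    }
    bp_mat[, s] <- count / B
  }
  fits <- lapply(seq_along(keys), function(i) au_fit(bp_mat[i, ], scales, B))
  r1 <- which.min(abs(scales - 1))
  tab <- data.frame(
    node = seq_along(keys), size = sizes, members = keys,
    bp = bp_mat[, r1] * 100,
    au = vapply(fits, `[[`, 0, "au"),
    v = vapply(fits, `[[`, 0, "v"),
    c = vapply(fits, `[[`, 0, "c"),
    flag = vapply(fits, `[[`, "", "flag"),
    stringsAsFactors = FALSE)
  structure(list(tree = tree, table = tab, bp_by_scale = bp_mat,
                 scales = scales, B = B),
            class = "lit_cluster_support")
}

# multiscale probit fit for one cluster; returns AU in [0,100]
au_fit <- function(bp, scales, B) {
  use <- bp > 0 & bp < 1
  if (sum(use) < 2) {
    if (mean(bp) >= 0.5) {
      return(list(au = 100, v = NA_real_, c = NA_real_, flag = "saturated"))
    }
    return(list(au = 0, v = NA_real_, c = NA_real_, flag = "never_observed"))
  }
  r <- scales[use]
  z <- stats::qnorm(1 - bp[use])
  w <- B * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[[1]]
  cc <- fit$coefficients[[2]]
  list(au = (1 - stats::pnorm(v - cc)) * 100, v = v, c = cc, flag = "ok")
}

#' @export
print.lit_cluster_support <- function(x, ...) {
  cat(sprintf("<lit_cluster_support> %d leaves, %d clusters, B=%d, %d scales\n",
              length(x$tree$labels), nrow(x$table), x$B, length(x$scales)))
  print(x$table[, c("node", "size", "bp", "au", "flag")], row.names = FALSE)
  invisible(x)
}

#' Export a supported dendrogram as Newick
#'
#' Branch lengths are merge-height differences; internal node labels carry
#' the support as `AU/BP` (rounded to integer percent).
#'
#' @param support A `lit_cluster_support` from [bootstrap_support()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(support, path) {
  stopifnot(inherits(support, "lit_cluster_support"))
  phy <- ape::as.phylo(support$tree)
  part <- ape::prop.part(phy)
  labs <- attr(part, "labels")
  part_keys <- vapply(part, function(ix) paste(sort(labs[ix]), collapse = "|"), "")
  node_lab <- character(length(part_keys))
  m <- match(part_keys, support$table$members)
  ok <- !is.na(m)
  node_lab[ok] <- sprintf("%.0f/%.0f", support$table$au[m[ok]],
                          support$table$bp[m[ok]])
  phy$node.label <- node_lab
  ape::write.tree(phy, file = path)
  invisible(path)
}
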