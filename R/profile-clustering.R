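#' Spearman-correlation distance between kinase affinity profiles
#'
#' Computes, for every pair of kinases, 1 minus the Spearman correlation
#' of their log10 Kd values across the compounds measured for both.
#' Kinases with no finite (uncensored) Kd at all are excluded with a
#' reason. Pairs sharing fewer than `min_overlap` compounds are
#' missing-with-reason (`NA` in the matrix). By default, censored-above
#' cells enter the ranking as a shared largest value (ties at the top), so
#' two kinases that both fail to bind a compound count as agreeing; set
#' `censored = "missing"` to drop those cells from the overlap instead.
#'
#' @param x An [affinity_matrix()].
#' @param min_overlap Minimum number of shared compounds (default 10).
#' @param censored `"max_tie"` (default) or `"missing"`.
#' @return A symmetric kinase x kinase matrix of distances in \[0, 2\]
#'   with zero diagonal, attributes `excluded` (kinase ids) and
#'   `min_overlap`.
#' @export
spearman_distance <- function(x, min_overlap = 10,
                              censored = c("max_tie", "missing")) {
  stopifnot(inherits(x, "affinity_matrix"))
  censored <- match.arg(censored)
  vals <- log10(x$kd)
  cens <- x$censor == "above_range"
  if (censored == "max_tie") {
    top <- max(vals[is.finite(vals)], 0, na.rm = TRUE) + 1
    vals[cens] <- top
  } # "missing": censored cells stay NA
  vals[x$censor == "not_estimated"] <- NA

  has_finite <- colSums(is.finite(log10(x$kd))) > 0
  excluded <- x$kinases[!has_finite]
  vals <- vals[, has_finite, drop = FALSE]
  kin <- x$kinases[has_finite]
  nk <- ncol(vals)

  obs <- !is.na(vals)
  overlap <- crossprod(obs)
  d <- matrix(NA_real_, nk, nk, dimnames = list(kin, kin))
  if (nk > 0 && !anyNA(vals)) {
    # complete matrix: Spearman = Pearson on column ranks
    rk <- apply(vals, 2, rank)
    rho <- suppressWarnings(stats::cor(rk))
    d <- 1 - rho
  } else if (nk > 0) {
    for (i in seq_len(nk)) {
      for (jj in i:nk) {
        ok <- obs[, i] & obs[, jj]
        if (sum(ok) >= 2) {
          rho <- suppressWarnings(
            stats::cor(vals[ok, i], vals[ok, jj], method = "spearman"))
          d[i, jj] <- d[jj, i] <- 1 - rho
        }
      }
    }
  }
  d[overlap < min_overlap] <- NA
  diag(d) <- 0
  d[is.nan(d)] <- NA # zero-variance profiles have no defined correlation
  attr(d, "excluded") <- excluded
  attr(d, "min_overlap") <- min_overlap
  d
}

#' Agglomerative clustering of kinases by affinity-profile distance
#'
#' Hierarchical (average-linkage by default) clustering of the Spearman
#' distance matrix, cut into `k` flat clusters. Kinases with any missing
#' distance after the overlap rule are excluded with a reason, since their
#' placement would be arbitrary. The result is deterministic given the
#' input.
#'
#' @param distance Matrix from [spearman_distance()].
#' @param k Number of clusters (must not exceed the number of clusterable
#'   kinases).
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A list of class `cluster_result`: `labels` (named integer
#'   vector), `tree` (the `hclust` object), `k`, `linkage`, `excluded`.
#' @export
cluster_profiles <- function(distance, k, linkage = "average") {
  stopifnot(is.matrix(distance), nrow(distance) == ncol(distance))
  complete <- rowSums(is.na(distance)) == 0
  excluded <- rownames(distance)[!complete]
  d <- distance[complete, complete, drop = FALSE]
  if (k > nrow(d)) {
    stop(sprintf("k = %d exceeds the %d clusterable kinases", k, nrow(d)),
         call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  labels <- stats::cutree(tree, k = k)
  structure(list(labels = labels, tree = tree, k = k, linkage = linkage,
                 excluded = c(attr(distance, "excluded"), excluded)),
            class = "cluster_result")
}

#' Compare an affinity-based partition with sequence-based kinome groups
#'
#' Cross-tabulates the two labelings over their shared kinases and
#' computes the adjusted Rand index (1 = identical partitions, ~0 =
#' chance-level agreement).
#'
#' @param labels Named vector of cluster labels (e.g.
#'   `cluster_result$labels`).
#' @param kinome_groups Named vector of sequence-group labels.
#' @return A list of class `partition_comparison`: `contingency` (table),
#'   `ari`, `n`.
#' @export
cluster_vs_group <- function(labels, kinome_groups) {
  common <- intersect(names(labels), names(kinome_groups))
  if (length(common) == 0) stop("no shared kinases", call. = FALSE)
  a <- labels[common]
  b <- kinome_groups[common]
  structure(list(contingency = table(cluster = a, group = b),
                 ari = mclust::adjustedRandIndex(a, b),
                 n = length(common)),
            class = "partition_comparison")
}
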