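# Internal cluster validity metrics. All Euclidean, all hand-checkable:
# tests verify each against closed forms and independent oracles.

#' Mean silhouette coefficient
#'
#' For each case, `s(i) = (b_i - a_i) / max(a_i, b_i)` where `a_i` is the
#' mean distance to its own cluster and `b_i` the smallest mean distance to
#' another cluster; cases in singleton clusters score 0. Higher is better.
#'
#' @param x numeric matrix.
#' @param labels cluster labels with `2 <= k <= n - 1`.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  ids <- unique(labels)
  if (length(ids) < 2L) stopf("silhouette requires k >= 2")
  d <- as.matrix(dist(x))
  sizes <- table(factor(labels, levels = ids))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
    a <- sum(d[i, labels == own]) / (sizes[[as.character(own)]] - 1L)
    b <- min(vapply(setdiff(ids, own), function(c)
      mean(d[i, labels == c]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) sum_i max_{j != i} (S_i + S_j) / M_ij` with `S` the mean
#' distance of a cluster's members to its centroid and `M` the distance
#' between centroids. Lower is better. Identical centroids are an error.
#'
#' @inheritParams silhouette_mean
#' @return non-negative scalar.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  ids <- sort(unique(labels))
  k <- length(ids)
  if (k < 2L) stopf("Davies-Bouldin requires k >= 2")
  cen <- do.call(rbind, lapply(ids, function(c)
    colMeans(x[labels == c, , drop = FALSE])))
  S <- vapply(seq_len(k), function(c)
    mean(sqrt(rowSums(sweep(x[labels == ids[c], , drop = FALSE], 2L, cen[c, ])^2))),
    0)
  M <- as.matrix(dist(cen))
  db <- 0
  for (i in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      if (M[i, j] == 0)
        stopf("identical centroids for clusters %s and %s", ids[i], ids[j])
      (S[i] + S[j]) / M[i, j]
    }, 0)
    db <- db + max(ratios)
  }
  db / k
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `[B / (k - 1)] / [W / (n - k)]`. Higher is better. If `W = 0` (each
#' cluster a single repeated point) the value is `+Inf` with a warning.
#'
#' @inheritParams silhouette_mean
#' @return positive scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  ids <- unique(labels)
  k <- length(ids)
  if (k < 2L || k > n - 1L) stopf("Calinski-Harabasz requires 2 <= k <= n - 1")
  grand <- colMeans(x)
  B <- sum(vapply(ids, function(c) {
    rows <- which(labels == c)
    length(rows) * sum((colMeans(x[rows, , drop = FALSE]) - grand)^2)
  }, 0))
  W <- wcss(x, labels)
  if (W == 0) {
    warnf("zero within-cluster dispersion; returning Inf")
    return(Inf)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Shannon diversity of cluster sizes
#'
#' `H = -sum p_c log p_c` (natural log) over cluster-size proportions;
#' maximal (`log k`) for equal sizes. Higher means a more balanced
#' partition.
#'
#' @param cluster_sizes positive integer sizes.
#' @return value in `[0, log k]`.
#' @export
shannon_diversity <- function(cluster_sizes) {
  if (any(cluster_sizes <= 0)) stopf("cluster sizes must be positive")
  p <- cluster_sizes / sum(cluster_sizes)
  -sum(p * log(p))
}

#' Gini index of cluster-size inequality
#'
#' `G = sum_i sum_j |n_i - n_j| / (2 k^2 mean(n))`; 0 for equal sizes,
#' approaching `(k - 1) / k` when one cluster dominates. Lower is better.
#'
#' @param cluster_sizes positive integer sizes.
#' @return value in `[0, 1)`.
#' @export
gini_index <- function(cluster_sizes) {
  if (any(cluster_sizes <= 0)) stopf("cluster sizes must be positive")
  k <- length(cluster_sizes)
  sum(abs(outer(cluster_sizes, cluster_sizes, "-"))) /
    (2 * k^2 * mean(cluster_sizes))
}

#' Compute the five internal validity metrics for one partition
#'
#' @param x numeric matrix.
#' @param labels cluster labels.
#' @return named list: `silhouette`, `davies_bouldin`, `calinski_harabasz`,
#'   `shannon`, `gini`.
#' @export
internal_metrics <- function(x, labels) {
  sizes <- as.numeric(table(labels))
  list(silhouette = silhouette_mean(x, labels),
       davies_bouldin = davies_bouldin(x, labels),
       calinski_harabasz = calinski_harabasz(x, labels),
       shannon = shannon_diversity(sizes),
       gini = gini_index(sizes))
}

#' Rank algorithms across the five internal metrics
#'
#' Each metric ranks the algorithms direction-aware (higher-better for
#' silhouette, Calinski-Harabasz and Shannon; lower-better for
#' Davies-Bouldin and Gini), ties receiving average ranks. The overall
#' ranking is the sum of the five ranks; the final rank orders algorithms by
#' ascending rank sum, breaking exact ties alphabetically and flagging them.
#'
#' @param metrics data frame with one row per algorithm (row names =
#'   algorithm) and columns `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`, `shannon`, `gini`.
#' @return data frame of class `metric_report` with per-metric ranks,
#'   `rank_sum`, `final_rank` and a `tied` flag, ordered by final rank.
#' @export
rank_algorithms <- function(metrics) {
  needed <- c("silhouette", "davies_bouldin", "calinski_harabasz",
              "shannon", "gini")
  missing <- setdiff(needed, colnames(metrics))
  if (length(missing))
    stopf("missing metric(s): %s", paste(missing, collapse = ", "))
  higher_better <- c(silhouette = TRUE, davies_bouldin = FALSE,
                     calinski_harabasz = TRUE, shannon = TRUE, gini = FALSE)
  out <- as.data.frame(metrics[, needed, drop = FALSE])
  for (mname in needed) {
    v <- metrics[[mname]]
    out[[paste0("rank_", mname)]] <-
      rank(if (higher_better[[mname]]) -v else v, ties.method = "average")
  }
  out$rank_sum <- rowSums(out[, paste0("rank_", needed)])
  ord <- order(out$rank_sum, rownames(out))
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$rank_sum) | duplicated(out$rank_sum, fromLast = TRUE)
  class(out) <- c("metric_report", "data.frame")
  out
}
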