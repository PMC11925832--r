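#' Robust and Sparse K-means clustering
#'
#' K-means hardened in two ways: case trimming for robustness to outliers,
#' and an L1-constrained nonnegative feature-weight vector for sparsity in
#' high dimension. The fit alternates three steps until the weights converge:
#'
#' 1. *Trimmed weighted K-means*: Lloyd iterations under the weighted squared
#'    distance `d_w(x, c) = sum_j w_j (x_j - c_j)^2`, excluding at each
#'    assignment the `ceil(alpha * n)` cases farthest (weighted) from their
#'    nearest center — the weighted trimmed set `O_W`.
#' 2. *Unweighted trimming*: centers are recomputed on cases outside `O_W`
#'    and the `ceil(alpha * n)` cases with the largest unweighted distance to
#'    their nearest center form `O_E`.
#' 3. *Weight update*: on cases outside `O_W U O_E` the per-feature
#'    between-cluster sum of squares `b_j` is computed, and
#'    `w = S(b, delta) / ||S(b, delta)||_2` with `S` coordinatewise
#'    soft-thresholding and `delta >= 0` the smallest value (binary search;
#'    0 when already feasible) that makes `||w||_1 <= s`.
#'
#' Final labels assign every case — including trimmed ones — to its nearest
#' weighted center. The best of `n_init` k-means++ restarts by the weighted
#' between-cluster objective is returned.
#'
#' When `s >= sqrt(p)` the L1 constraint is vacuous and the fit runs in the
#' no-sparsity regime with fixed uniform weights `1/sqrt(p)`; with
#' `alpha = 0` this reduces exactly to Lloyd K-means.
#'
#' @param x numeric matrix (rows = cases).
#' @param k number of clusters (>= 2).
#' @param alpha trim fraction in `[0, 0.5)`.
#' @param s L1 bound in `[1, sqrt(p)]`; `sqrt(p)` disables sparsity.
#' @param n_init number of k-means++ restarts.
#' @param max_iter maximum outer (weight) iterations.
#' @param tol convergence tolerance on the weight vector (max abs change).
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param centers optional initial centers (k x p); forces a single start.
#' @return an object of class `rskc`: `labels`, `k`, `centers`, `weights`,
#'   `trimmed_weighted` (`O_W`), `trimmed_unweighted` (`O_E`), `objective`,
#'   `objective_trace`, `wcss`, `iterations`, `seed`.
#' @references Kondo, Salibian-Barrera & Zamar's robust sparse K-means and
#'   Witten & Tibshirani's sparse clustering give the two ingredients
#'   combined here.
#' @examples
#' x <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 4), 30, 2))
#' fit <- rskc(x, k = 2, alpha = 0.05, seed = 1)
#' table(fit$labels)
#' @export
rskc <- function(x, k, alpha = 0.1, s = sqrt(ncol(x)), n_init = 10L,
                 max_iter = 20L, tol = 1e-4, seed = NULL, centers = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (k < 2L) stopf("k must be >= 2")
  if (alpha < 0 || alpha >= 0.5) stopf("alpha must lie in [0, 0.5)")
  if (s < 1) stopf("s must be >= 1")
  n_trim <- ceiling(alpha * n)
  if (k >= n - n_trim) stopf("k (%d) must be < n - ceil(alpha n) = %d", k, n - n_trim)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (!is.null(centers)) n_init <- 1L
  sparse <- s < sqrt(p) - 1e-8

  best <- NULL
  for (init in seq_len(n_init)) {
    w <- rep(1 / sqrt(p), p)
    cen <- if (!is.null(centers)) as.matrix(centers)
           else x[kmeanspp_seed(x, k, w, n_trim), , drop = FALSE]
    trace <- numeric(0)
    ow <- oe <- integer(0)
    labels <- rep(1L, n)
    for (iter in seq_len(max_iter)) {
      w_old <- w
      # (1) trimmed weighted Lloyd
      res <- trimmed_lloyd(x, cen, w, n_trim)
      labels <- res$labels; cen <- res$centers; ow <- res$trimmed
      # (2) unweighted trimming
      keep_w <- setdiff(seq_len(n), ow)
      cen_u <- cluster_means(x, ifelse(seq_len(n) %in% keep_w, labels, NA), k)
      cen_u[is.na(cen_u[, 1]), ] <- cen[is.na(cen_u[, 1]), , drop = FALSE]
      d2u <- row_center_dist2(x, cen_u)
      du_min <- apply(d2u, 1L, min)
      oe <- if (n_trim > 0) order(du_min, decreasing = TRUE)[seq_len(n_trim)]
            else integer(0)
      # (3) weight update on untrimmed cases
      keep <- setdiff(seq_len(n), union(ow, oe))
      b <- between_ss_per_feature(x[keep, , drop = FALSE], labels[keep])
      if (sparse) {
        w <- l1_constrained_weights(b, s)
      }
      trace <- c(trace, sum(w * b))
      if (max(abs(w - w_old)) < tol) break
    }
    # final assignment of every case to the nearest weighted center
    d2 <- row_center_dist2(x, cen, w)
    labels <- max.col(-d2, ties.method = "first")
    keep <- setdiff(seq_len(n), union(ow, oe))
    obj <- sum(w * between_ss_per_feature(x[keep, , drop = FALSE], labels[keep]))
    # restarts compete on the robust criterion: weighted within-cluster SS
    # over untrimmed cases (the between-SS objective would reward centers
    # parked on untrimmed outliers)
    sel <- sum(d2[cbind(keep, labels[keep])])
    if (is.null(best) || sel < best$sel_crit) {
      best <- list(labels = labels, k = k, centers = cen, weights = w,
                   trimmed_weighted = sort(ow), trimmed_unweighted = sort(oe),
                   objective = obj, sel_crit = sel, objective_trace = trace,
                   wcss = wcss(x, labels), iterations = iter,
                   alpha = alpha, s = s, seed = seed)
    }
  }
  best$sel_crit <- NULL
  structure(best, class = "rskc")
}

# k-means++ seeding under feature weights; returns row indices. The n_trim
# rows farthest from the chosen seeds are excluded from the sampling pool so
# presumed outliers cannot become initial centers.
kmeanspp_seed <- function(x, k, w, n_trim = 0L) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- row_center_dist2(x, x[idx[1], , drop = FALSE], w)[, 1]
  for (j in seq_len(k - 1L)) {
    prob <- d2
    if (n_trim > 0 && n - n_trim > j)
      prob[order(d2, decreasing = TRUE)[seq_len(n_trim)]] <- 0
    if (!all(is.finite(prob)) || sum(prob) == 0) prob <- rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = prob)
    d2 <- pmin(d2, row_center_dist2(x, x[idx[j + 1L], , drop = FALSE], w)[, 1])
  }
  idx
}

# Lloyd iterations with per-assignment trimming of the n_trim worst cases
# under weighted distance. Centers are means of untrimmed assigned cases.
trimmed_lloyd <- function(x, centers, w, n_trim, max_iter = 50L) {
  n <- nrow(x); k <- nrow(centers)
  labels_old <- rep(0L, n)
  trimmed <- integer(0)
  for (it in seq_len(max_iter)) {
    d2 <- row_center_dist2(x, centers, w)
    labels <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(n), labels)]
    trimmed <- if (n_trim > 0) order(dmin, decreasing = TRUE)[seq_len(n_trim)]
               else integer(0)
    lab_eff <- labels
    lab_eff[trimmed] <- NA
    newc <- cluster_means(x, lab_eff, k)
    # re-seed empty clusters with the farthest untrimmed case
    empty <- which(is.na(newc[, 1]))
    if (length(empty)) {
      cand <- setdiff(order(dmin, decreasing = TRUE), trimmed)
      for (m in seq_along(empty)) {
        newc[empty[m], ] <- x[cand[m], ]
        labels[cand[m]] <- empty[m]
      }
    }
    centers <- newc
    if (all(labels == labels_old)) break
    labels_old <- labels
  }
  list(labels = labels, centers = centers, trimmed = trimmed)
}

# Per-feature between-cluster sum of squares: total SS minus within SS.
between_ss_per_feature <- function(x, labels) {
  tot <- colSums(sweep(x, 2L, colMeans(x))^2)
  within <- numeric(ncol(x))
  for (c in unique(labels)) {
    rows <- which(labels == c)
    if (length(rows) > 1L) {
      xc <- x[rows, , drop = FALSE]
      within <- within + colSums(sweep(xc, 2L, colMeans(xc))^2)
    }
  }
  b <- tot - within
  b[b < 0] <- 0
  b
}

# w = S(b, delta) / ||S(b, delta)||_2 with the smallest delta >= 0 giving
# ||w||_1 <= s (binary search on delta).
l1_constrained_weights <- function(b, s) {
  soft <- function(b, d) pmax(b - d, 0)
  wvec <- function(d) {
    sb <- soft(b, d)
    nb <- sqrt(sum(sb^2))
    if (nb == 0) return(rep(0, length(b)))
    sb / nb
  }
  if (sum(wvec(0)) <= s + 1e-8) return(wvec(0))
  lo <- 0; hi <- max(b)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(wvec(mid)) > s) lo <- mid else hi <- mid
  }
  wvec(hi)
}

#' @export
print.rskc <- function(x, ...) {
  cat(sprintf("Robust & Sparse K-means: k = %d, alpha = %.3g, s = %.3g\n",
              x$k, x$alpha, x$s))
  cat(sprintf("  cluster sizes: %s\n", paste(tabulate(x$labels, x$k), collapse = " ")))
  cat(sprintf("  %d/%d features with non-zero weight; objective %.4g; wcss %.4g\n",
              sum(x$weights > 1e-10), length(x$weights), x$objective, x$wcss))
  if (length(x$trimmed_weighted))
    cat(sprintf("  trimmed cases: O_W = %d, O_E = %d\n",
                length(x$trimmed_weighted), length(x$trimmed_unweighted)))
  invisible(x)
}

#' Assign new cases to the nearest weighted RSKC center
#' @param object an `rskc` fit.
#' @param newdata matrix with the same columns as the training data.
#' @param ... unused.
#' @return integer cluster labels.
#' @export
predict.rskc <- function(object, newdata, ...) {
  d2 <- row_center_dist2(as.matrix(newdata), object$centers, object$weights)
  max.col(-d2, ties.method = "first")
}

#' Plot an RSKC fit on its two heaviest-weighted features
#' @param x an `rskc` fit.
#' @param data the matrix the model was fitted to.
#' @param ... passed to [plot()].
#' @export
plot.rskc <- function(x, data, ...) {
  j <- order(x$weights, decreasing = TRUE)[1:2]
  plot(data[, j[1]], data[, j[2]], col = x$labels, pch = 19,
       xlab = colnames(data)[j[1]] %||% "feature 1",
       ylab = colnames(data)[j[2]] %||% "feature 2", ...)
  pts <- union(x$trimmed_weighted, x$trimmed_unweighted)
  if (length(pts)) points(data[pts, j[1]], data[pts, j[2]], pch = 4, cex = 1.5)
  invisible(x)
}
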