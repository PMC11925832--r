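#' Within-cluster sum of squares
#'
#' `sum_c sum_{i in c} ||x_i - centroid_c||^2`, the elbow criterion.
#'
#' @param x numeric matrix.
#' @param labels cluster labels (>= 1 row per cluster).
#' @return non-negative scalar.
#' @export
wcss <- function(x, labels) {
  x <- as.matrix(x)
  total <- 0
  for (c in unique(labels)) {
    rows <- which(labels == c)
    xc <- x[rows, , drop = FALSE]
    ctr <- colMeans(xc)
    total <- total + sum(sweep(xc, 2L, ctr)^2)
  }
  total
}

#' Names of the algorithms in the default registry
#'
#' The deep-clustering auto-encoder used elsewhere in this literature needs
#' a deep-learning stack and is supported only as a user-registered plug-in
#' via the `registry` argument of [run_algorithm()].
#' @return character vector of algorithm names.
#' @export
cluster_algorithms <- function() names(default_registry)

# Plug-in registry: each entry is function(x, k, params, seed) -> list with
# at least `labels`; optional `weights`, `trimmed_weighted`,
# `trimmed_unweighted`, `objective`.
default_registry <- list(
  kmeans = function(x, k, params, seed) {
    set.seed(seed)
    km <- kmeans(x, centers = k, nstart = params$nstart %||% 5L,
                 iter.max = params$iter_max %||% 50L)
    list(labels = km$cluster)
  },
  minibatch_kmeans = function(x, k, params, seed) {
    set.seed(seed)
    minibatch_kmeans_fit(x, k,
                         batch_size = params$batch_size %||% 100L,
                         n_iter = params$n_iter %||% 100L)
  },
  weighted_kmeans = function(x, k, params, seed) {
    set.seed(seed)
    w <- params$weights %||% rep(1 / ncol(x), ncol(x))
    xs <- sweep(x, 2L, sqrt(w), "*")
    km <- kmeans(xs, centers = k, nstart = params$nstart %||% 5L,
                 iter.max = params$iter_max %||% 50L)
    list(labels = km$cluster, weights = w)
  },
  rskc = function(x, k, params, seed) {
    fit <- rskc(x, k, alpha = params$alpha %||% 0.05,
                s = params$s %||% sqrt(ncol(x)),
                n_init = params$n_init %||% 5L, seed = seed)
    fit[c("labels", "weights", "trimmed_weighted", "trimmed_unweighted",
          "objective")]
  },
  gmm = function(x, k, params, seed) {
    set.seed(seed)
    mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
    fit <- mclust::Mclust(x, G = k,
                          modelNames = params$model %||% "EII",
                          verbose = FALSE)
    if (is.null(fit)) stopf("GMM fit failed for k = %d", k)
    list(labels = as.integer(fit$classification))
  },
  clara = function(x, k, params, seed) {
    set.seed(seed)
    sampsize <- min(nrow(x), params$sampsize %||% (40L + 2L * k))
    cl <- cluster::clara(x, k, samples = params$samples %||% 5L,
                         sampsize = sampsize, rngR = TRUE, pamLike = TRUE)
    list(labels = cl$clustering)
  },
  som = function(x, k, params, seed) {
    set.seed(seed)
    som_cluster_fit(x, k, grid_units = params$grid_units,
                    n_iter = params$n_iter %||% 500L)
  }
)

#' Run a clustering algorithm through the uniform adapter contract
#'
#' Every registered algorithm returns the same shape of result with exactly
#' `k` non-empty clusters when feasible (an empty cluster is repaired by
#' re-seeding the farthest case as a new center). Available algorithms:
#' `kmeans`, `minibatch_kmeans`, `weighted_kmeans`, `rskc`, `gmm` (maximum
#' posterior), `clara` (PAM on random subsamples), `som` (best-matching units
#' grouped into k by K-means on the codebook). Additional algorithms — e.g.
#' a deep-clustering auto-encoder — can be supplied via `registry`.
#'
#' @param name algorithm name.
#' @param x numeric matrix.
#' @param k number of clusters.
#' @param params list of algorithm-specific parameters.
#' @param seed integer seed (controls all randomness in the run).
#' @param registry optional named list of plug-in fit functions overriding or
#'   extending the default registry.
#' @return object of class `cluster_fit`: `labels` (1..k), `k`, `algorithm`,
#'   `weights`, `trimmed_weighted`, `trimmed_unweighted`, `objective`,
#'   `wcss`, `seed`.
#' @export
run_algorithm <- function(name, x, k, params = list(), seed = 1L,
                          registry = NULL) {
  reg <- default_registry
  if (!is.null(registry)) reg[names(registry)] <- registry
  if (!name %in% names(reg))
    stopf("unknown algorithm '%s'; registry: %s", name,
          paste(names(reg), collapse = ", "))
  x <- as.matrix(x)
  raw <- reg[[name]](x, k, params, as.integer(seed))
  labels <- ensure_k_clusters(x, as.integer(raw$labels), k)
  p <- ncol(x)
  structure(list(labels = labels, k = k, algorithm = name,
                 weights = raw$weights %||% rep(1 / p, p),
                 trimmed_weighted = raw$trimmed_weighted %||% integer(0),
                 trimmed_unweighted = raw$trimmed_unweighted %||% integer(0),
                 objective = raw$objective %||% NA_real_,
                 wcss = wcss(x, labels), seed = as.integer(seed)),
            class = "cluster_fit")
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("%s fit: k = %d, wcss = %.4g, sizes: %s\n", x$algorithm, x$k,
              x$wcss, paste(tabulate(x$labels, x$k), collapse = " ")))
  invisible(x)
}

# Guarantee exactly k non-empty clusters by re-seeding each empty id with the
# case farthest from its current centroid.
ensure_k_clusters <- function(x, labels, k) {
  labels <- relabel_consecutive(labels)
  sizes <- tabulate(labels, k)
  while (any(sizes == 0L)) {
    cen <- cluster_means(x, labels, k)
    cen[is.na(cen[, 1]), ] <- colMeans(x)
    d <- row_center_dist2(x, cen)
    dmin <- d[cbind(seq_len(nrow(x)), labels)]
    # only steal from clusters of size > 1
    movable <- which(tabulate(labels, k)[labels] > 1L)
    far <- movable[which.max(dmin[movable])]
    labels[far] <- which(sizes == 0L)[1]
    sizes <- tabulate(labels, k)
  }
  labels
}

# Mini-batch K-means (per-center learning-rate counts).
minibatch_kmeans_fit <- function(x, k, batch_size = 100L, n_iter = 100L) {
  n <- nrow(x)
  batch_size <- min(batch_size, n)
  centers <- x[kmeanspp_seed(x, k, rep(1, ncol(x))), , drop = FALSE]
  counts <- rep(0, k)
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, batch_size)
    d2 <- row_center_dist2(x[idx, , drop = FALSE], centers)
    a <- max.col(-d2, ties.method = "first")
    for (m in seq_along(idx)) {
      c <- a[m]
      counts[c] <- counts[c] + 1
      eta <- 1 / counts[c]
      centers[c, ] <- (1 - eta) * centers[c, ] + eta * x[idx[m], ]
    }
  }
  d2 <- row_center_dist2(x, centers)
  list(labels = max.col(-d2, ties.method = "first"))
}

# Small online self-organizing map: square grid of >= 4k units, trained with
# a shrinking Gaussian neighborhood, units then grouped into k clusters by
# K-means on the codebook vectors.
som_cluster_fit <- function(x, k, grid_units = NULL, n_iter = 500L) {
  n <- nrow(x); p <- ncol(x)
  g <- ceiling(sqrt(grid_units %||% (4L * k)))
  units <- g * g
  grid_xy <- cbind(rep(seq_len(g), each = g), rep(seq_len(g), times = g))
  codebook <- x[sample.int(n, units, replace = units > n), , drop = FALSE]
  sigma0 <- g / 2; eta0 <- 0.5
  for (t in seq_len(n_iter)) {
    i <- sample.int(n, 1L)
    d2 <- rowSums(sweep(codebook, 2L, x[i, ])^2)
    bmu <- which.min(d2)
    frac <- t / n_iter
    sigma <- sigma0 * (1 - frac) + 0.5 * frac
    eta <- eta0 * (1 - frac) + 0.01 * frac
    gd2 <- rowSums(sweep(grid_xy, 2L, grid_xy[bmu, ])^2)
    h <- eta * exp(-gd2 / (2 * sigma^2))
    codebook <- codebook + h * (matrix(x[i, ], units, p, byrow = TRUE) - codebook)
  }
  km <- kmeans(codebook, centers = min(k, units), nstart = 5L, iter.max = 50L)
  bmu <- max.col(-row_center_dist2(x, codebook), ties.method = "first")
  list(labels = km$cluster[bmu])
}

#' Automated elbow selection of the number of clusters
#'
#' Runs an algorithm over a range of cluster counts, records the
#' within-cluster sum of squares for each, and selects the count at which the
#' rate of decrease sharply falls: after min-max normalizing both axes to
#' `[0, 1]`, the elbow is the point with maximum perpendicular distance to
#' the chord joining the first and last curve points. Ties (including an
#' exactly linear curve, which is warned about) resolve to the smallest k.
#'
#' @param x numeric matrix.
#' @param algorithm registered algorithm name (see [run_algorithm()]).
#' @param k_range increasing integer vector of candidate counts (>= 3 values).
#' @param params,registry passed to [run_algorithm()].
#' @param seed master seed; each (algorithm, k) run gets a derived seed.
#' @return object of class `elbow_curve`: `k_values`, `criterion`, `k_opt`.
#' @export
find_elbow <- function(x, algorithm = "kmeans", k_range = 2:10,
                       params = list(), seed = 1L, registry = NULL) {
  k_range <- as.integer(k_range)
  if (length(k_range) < 3L) stopf("k_range must contain at least 3 values")
  if (is.unsorted(k_range, strictly = TRUE)) stopf("k_range must be strictly increasing")
  if (max(k_range) >= nrow(x)) stopf("max(k_range) must be < n")
  crit <- vapply(seq_along(k_range), function(i)
    run_algorithm(algorithm, x, k_range[i], params,
                  seed = derive_seed(seed, i), registry = registry)$wcss,
    0)
  if (is.unsorted(rev(crit)))
    message("elbow criterion is not monotone non-increasing in k")
  k_opt <- elbow_point(k_range, crit)
  structure(list(k_values = k_range, criterion = crit, k_opt = k_opt,
                 algorithm = algorithm),
            class = "elbow_curve")
}

# Max perpendicular distance to the first-last chord on normalized axes.
elbow_point <- function(k_values, criterion) {
  kx <- (k_values - min(k_values)) / diff(range(k_values))
  rngc <- diff(range(criterion))
  cy <- if (rngc == 0) rep(0, length(criterion))
        else (criterion - min(criterion)) / rngc
  x1 <- kx[1]; y1 <- cy[1]
  x2 <- kx[length(kx)]; y2 <- cy[length(cy)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- abs((y2 - y1) * kx - (x2 - x1) * cy + x2 * y1 - y2 * x1) / len
  if (max(dist) < 1e-12)
    warnf("elbow curve is linear; selecting the smallest k")
  k_values[which.max(dist)]  # which.max takes the first (smallest k) on ties
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("Elbow curve (%s): k in [%d, %d], k_opt = %d\n", x$algorithm,
              min(x$k_values), max(x$k_values), x$k_opt))
  invisible(x)
}

#' @export
plot.elbow_curve <- function(x, ...) {
  plot(x$k_values, x$criterion, type = "b", xlab = "k", ylab = "WCSS", ...)
  graphics::abline(v = x$k_opt, lty = 2)
  invisible(x)
}
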