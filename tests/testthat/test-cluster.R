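# RSKC, the algorithm bench, wcss and elbow selection.

test_that("wcss matches hand computations", {
  x <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  expect_equal(wcss(x, c(1, 1, 2, 2)), 0.01, tolerance = 1e-12)
  expect_equal(wcss(x, 1:4), 0)
  expect_equal(wcss(x, rep(1, 4)), sum((x - mean(x))^2))
})

test_that("rskc with alpha = 0 and s = sqrt(p) reproduces Lloyd K-means", {
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(60 * 3), 60, 3)
    init <- x[sample(60, 3), , drop = FALSE]
    ref <- lloyd_oracle(x, init)
    fit <- rskc(x, k = 3, alpha = 0, s = sqrt(3), centers = init)
    expect_equal(fit$labels, ref$labels)
    expect_equal(unname(fit$weights), rep(1 / sqrt(3), 3))
  }
})

test_that("rskc trims gross outliers and recovers the planted partition", {
  blobs <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(10, 0), c(0, 10)),
                      seed = 5)
  set.seed(6)
  outliers <- matrix(runif(10, 40, 60) * sample(c(-1, 1), 10, TRUE), 5, 2)
  x <- rbind(blobs$x, outliers)
  n <- nrow(x)
  fit <- rskc(x, k = 3, alpha = 5 / n, n_init = 5, seed = 8)
  out_idx <- 121:125
  expect_true(all(out_idx %in% union(fit$trimmed_weighted, fit$trimmed_unweighted)))
  ari <- adjusted_rand_index(fit$labels[1:120], blobs$labels)
  expect_gt(ari, 0.95)
})

test_that("sparse weighting concentrates on informative features", {
  set.seed(9)
  n <- 90
  informative <- make_blobs(n_per = 30,
                            centers = matrix(rnorm(30, sd = 4), 3, 10),
                            seed = 10)$x
  noise <- matrix(rnorm(n * 40), n, 40)
  x <- cbind(informative, noise)
  fit <- rskc(x, k = 3, alpha = 0, s = 2, n_init = 5, seed = 11)
  expect_lte(sum(fit$weights), 2 + 1e-6)
  expect_equal(sqrt(sum(fit$weights^2)), 1, tolerance = 1e-8)
  expect_gt(mean(fit$weights[1:10]), mean(fit$weights[11:50]))
})

test_that("rskc objective trace is non-decreasing for fixed trimmed sets", {
  # alpha = 0 keeps the trimmed sets empty (hence fixed), the regime in
  # which each alternating step provably cannot decrease the objective;
  # noise features make the weight iteration take several rounds
  set.seed(12)
  blobs <- make_blobs(n_per = 50, seed = 12)$x
  x <- cbind(blobs, matrix(rnorm(150 * 6), 150, 6))
  fit <- rskc(x, k = 3, alpha = 0, s = 1.8, n_init = 1, seed = 13)
  tr <- fit$objective_trace
  expect_gte(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-6))
  expect_gt(fit$objective, 0)
})

test_that("rskc centers resist outlier inflation better than kmeans", {
  blobs <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(10, 0), c(0, 10)),
                      seed = 14)
  base_out <- matrix(c(30, 30, -30, 30, 30, -30, -25, -25), 4, 2, byrow = TRUE)
  shift <- function(mult) {
    x <- rbind(blobs$x, base_out * mult)
    fit <- rskc(x, k = 3, alpha = 4 / nrow(x), n_init = 5, seed = 15)
    fit$centers[order(fit$centers[, 1], fit$centers[, 2]), ]
  }
  km_shift <- function(mult) {
    x <- rbind(blobs$x, base_out * mult)
    set.seed(15)
    km <- kmeans(x, 3, nstart = 5)
    km$centers[order(km$centers[, 1], km$centers[, 2]), ]
  }
  d_rskc <- max(abs(shift(1) - shift(10)))
  d_km <- max(abs(km_shift(1) - km_shift(10)))
  expect_lt(d_rskc, 0.1 * 10)   # < 10% of the blob separation
  expect_gt(d_km, d_rskc)
})

test_that("rskc validates its arguments", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(rskc(x, k = 1), "k must be")
  expect_error(rskc(x, k = 2, s = 0.5), "s must be")
  expect_error(rskc(x, k = 2, alpha = 0.6), "alpha")
  expect_error(rskc(x, k = 19, alpha = 0.3), "must be <")
})

test_that("every registered algorithm recovers the blob fixture deterministically", {
  blobs <- make_blobs(n_per = 40, centers = rbind(c(0, 0), c(9, 0), c(0, 9)),
                      seed = 20)
  for (alg in cluster_algorithms()) {
    fit1 <- run_algorithm(alg, blobs$x, 3, seed = 21)
    fit2 <- run_algorithm(alg, blobs$x, 3, seed = 21)
    expect_identical(fit1$labels, fit2$labels)
    expect_equal(length(unique(fit1$labels)), 3)
    expect_true(all(tabulate(fit1$labels, 3) > 0))
    expect_gt(adjusted_rand_index(fit1$labels, blobs$labels), 0.9)
  }
  expect_error(run_algorithm("nope", blobs$x, 3), "registry")
})

test_that("a degenerate partition is repaired to k non-empty clusters", {
  x <- matrix(rnorm(40), 20, 2)
  labels <- rep(1L, 20)
  fixed <- sepclust:::ensure_k_clusters(x, labels, 3)
  expect_true(all(tabulate(fixed, 3) > 0))
})

test_that("a plug-in algorithm can be registered", {
  x <- make_blobs(n_per = 10, seed = 22)$x
  stub <- function(x, k, params, seed) list(labels = rep(seq_len(k), length.out = nrow(x)))
  fit <- run_algorithm("dcae", x, 3, seed = 1, registry = list(dcae = stub))
  expect_equal(fit$algorithm, "dcae")
  expect_equal(sort(unique(fit$labels)), 1:3)
})

test_that("elbow detection maximizes chord distance and handles degeneracy", {
  expect_equal(sepclust:::elbow_point(2:6, c(100, 40, 35, 33, 32)), 3)
  # oracle: explicit distances over all points
  kx <- (2:6 - 2) / 4
  cy <- (c(100, 40, 35, 33, 32) - 32) / 68
  d <- abs(kx + cy - 1) / sqrt(2)
  expect_equal(which.max(d), 2L)
  expect_warning(k <- sepclust:::elbow_point(2:5, c(40, 30, 20, 10)), "linear")
  expect_equal(k, 2)
})

test_that("find_elbow selects the planted cluster count on blobs", {
  blobs <- make_blobs(n_per = 50, centers = rbind(c(0, 0), c(8, 0), c(0, 8)),
                      seed = 23)
  el <- find_elbow(blobs$x, "kmeans", 2:10, seed = 24)
  expect_equal(el$k_opt, 3)
  expect_error(find_elbow(blobs$x, "kmeans", 2:3, seed = 1), "3 values")
  # wcss non-increasing on average over seeds
  curves <- sapply(1:5, function(s)
    find_elbow(blobs$x, "kmeans", 2:8, seed = s)$criterion)
  expect_true(all(diff(rowMeans(curves)) <= 1e-8))
})
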