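# Internal validity metrics, agreement indices, rank aggregation, stability.

fixture_1d <- function() list(x = matrix(c(0, 0.1, 10, 10.1), 4, 1),
                              labels = c(1, 1, 2, 2))

test_that("silhouette matches the per-point formula and the library oracle", {
  f <- fixture_1d()
  expect_equal(silhouette_mean(f$x, f$labels), 0.9900, tolerance = 1e-4)
  # independent oracle on random data
  set.seed(1)
  x <- matrix(rnorm(90), 30, 3)
  lab <- sample(1:3, 30, replace = TRUE)
  sil <- cluster::silhouette(lab, dist(x))
  expect_equal(silhouette_mean(x, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-10)
  # tight duplicate cluster far from another: near 1
  y <- rbind(matrix(0, 5, 2), matrix(100, 5, 2)) + rnorm(20, sd = 1e-3)
  expect_gt(silhouette_mean(y, rep(1:2, each = 5)), 0.99)
  expect_error(silhouette_mean(f$x, rep(1, 4)), "k >= 2")
})

test_that("random labels on one blob give silhouette near zero", {
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(200), 100, 2)
    silhouette_mean(x, sample(1:3, 100, replace = TRUE))
  }, 0)
  expect_lt(max(abs(vals)), 0.1)
})

test_that("Davies-Bouldin matches hand value, monotonicity, and an oracle", {
  f <- fixture_1d()
  expect_equal(davies_bouldin(f$x, f$labels), 0.01, tolerance = 1e-12)
  # moving identical-shape clusters apart strictly decreases DB
  mk <- function(gap) rbind(matrix(c(0, 0.1), 2, 1), matrix(c(gap, gap + 0.1), 2, 1))
  expect_lt(davies_bouldin(mk(20), f$labels), davies_bouldin(mk(10), f$labels))
  # direct-formula oracle on random data
  set.seed(2)
  x <- matrix(rnorm(90), 30, 3)
  lab <- rep(1:3, each = 10)
  cen <- sapply(1:3, function(c) colMeans(x[lab == c, ]))
  S <- sapply(1:3, function(c)
    mean(sqrt(colSums((t(x[lab == c, ]) - cen[, c])^2))))
  db_oracle <- mean(sapply(1:3, function(i)
    max(sapply(setdiff(1:3, i), function(j)
      (S[i] + S[j]) / sqrt(sum((cen[, i] - cen[, j])^2))))))
  expect_equal(davies_bouldin(x, lab), db_oracle, tolerance = 1e-10)
  expect_error(davies_bouldin(rbind(c(0, 0), c(0, 0)), c(1, 2)), "identical centroids")
})

test_that("Calinski-Harabasz matches hand value and an oracle", {
  f <- fixture_1d()
  expect_equal(calinski_harabasz(f$x, f$labels), 20000, tolerance = 1e-9)
  expect_warning(ch <- calinski_harabasz(matrix(c(0, 0, 5, 5), 4, 1),
                                         c(1, 1, 2, 2)), "Inf")
  expect_equal(ch, Inf)
  set.seed(3)
  x <- matrix(rnorm(120), 40, 3)
  lab <- rep(1:4, each = 10)
  grand <- colMeans(x)
  B <- sum(sapply(1:4, function(c) 10 * sum((colMeans(x[lab == c, ]) - grand)^2)))
  W <- sum(sapply(1:4, function(c)
    sum(sweep(x[lab == c, ], 2, colMeans(x[lab == c, ]))^2)))
  expect_equal(calinski_harabasz(x, lab), (B / 3) / (W / 36), tolerance = 1e-10)
})

test_that("Shannon and Gini follow their closed forms and limits", {
  expect_equal(shannon_diversity(rep(25, 4)), log(4))
  expect_equal(shannon_diversity(10), 0)
  expect_equal(shannon_diversity(c(1, 1, 2)), 1.0397, tolerance = 1e-4)
  expect_error(shannon_diversity(c(1, 0)), "positive")
  expect_equal(gini_index(rep(7, 5)), 0)
  expect_equal(gini_index(c(3, 1)), 0.25)
  # dominance limit: (k-1)/k
  expect_equal(gini_index(c(1e6 - 3, 1, 1, 1)), 0.75, tolerance = 1e-3)
})

test_that("ARI matches the hand contingency and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(4)
  for (rep in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("NMI matches the entropy oracle and its conventions", {
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(normalized_mutual_information(rep(1, 5), rep(2, 5)), 1)
  set.seed(5)
  for (rep in 1:20) {
    a <- sample(1:3, 15, replace = TRUE)
    b <- sample(1:3, 15, replace = TRUE)
    expect_equal(normalized_mutual_information(a, b), nmi_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI and NMI are invariant to label permutation", {
  set.seed(6)
  for (rep in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    perm <- sample(4)
    expect_equal(adjusted_rand_index(perm[a], b), adjusted_rand_index(a, b))
    expect_equal(normalized_mutual_information(perm[a], b),
                 normalized_mutual_information(a, b))
  }
})

test_that("metric ranges hold on randomized inputs", {
  set.seed(7)
  for (rep in 1:10) {
    x <- matrix(rnorm(150), 50, 3)
    k <- sample(2:5, 1)
    lab <- sample(seq_len(k), 50, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sizes <- as.numeric(table(lab))
    expect_true(abs(silhouette_mean(x, lab)) <= 1)
    expect_true(shannon_diversity(sizes) <= log(length(sizes)) + 1e-12)
    g <- gini_index(sizes)
    expect_true(g >= 0 && g < 1)
  }
})

test_that("rank aggregation is direction-aware with average ranks on ties", {
  report <- rank_algorithms(printed_metric_table())
  expect_equal(report["kmeans", "rank_sum"], 13)
  expect_equal(report["rskc", "rank_sum"], 15)
  expect_equal(rownames(report)[1:2], c("kmeans", "rskc"))
  # all-identical metrics: every rank_sum equal, all flagged tied
  same <- printed_metric_table()[rep(1, 3), ]
  rownames(same) <- c("a1", "a2", "a3")
  rs <- rank_algorithms(same)
  expect_equal(length(unique(rs$rank_sum)), 1)
  expect_true(all(rs$tied))
  # strict dominance gives final ranks 1, 2
  dom <- data.frame(silhouette = c(0.9, 0.1), davies_bouldin = c(0.5, 2),
                    calinski_harabasz = c(100, 10), shannon = c(1.3, 0.5),
                    gini = c(0.1, 0.6), row.names = c("good", "bad"))
  rd <- rank_algorithms(dom)
  expect_equal(rownames(rd), c("good", "bad"))
  expect_equal(rd$final_rank, c(1, 2))
  expect_error(rank_algorithms(dom[, -1]), "missing metric")
})

test_that("blob-fixture clustering beats random labels on all three geometry metrics", {
  blobs <- make_blobs(n_per = 40, seed = 8)
  km <- run_algorithm("kmeans", blobs$x, 3, seed = 9)$labels
  rs <- run_algorithm("rskc", blobs$x, 3, params = list(alpha = 0.05), seed = 9)$labels
  set.seed(10)
  rand <- sample(1:3, nrow(blobs$x), replace = TRUE)
  for (lab in list(km, rs)) {
    expect_gt(silhouette_mean(blobs$x, lab), silhouette_mean(blobs$x, rand))
    expect_lt(davies_bouldin(blobs$x, lab), davies_bouldin(blobs$x, rand))
    expect_gt(calinski_harabasz(blobs$x, lab), calinski_harabasz(blobs$x, rand))
  }
})

test_that("stability protocol is deterministic and behaves at the extremes", {
  blobs <- make_blobs(n_per = 30, seed = 11)
  stub <- list(fixed = function(x, k, params, seed)
    list(labels = rep(seq_len(k), length.out = nrow(x))))
  rep1 <- stability_assess(blobs$x, "fixed", 3, B = 5, R = 3, seed = 12,
                           registry = stub)
  expect_equal(rep1$ari_mean, 1)
  expect_equal(rep1$ari_sd, 0)
  expect_equal(rep1$ari_cv, 0)
  s1 <- stability_assess(blobs$x, "kmeans", 3, B = 4, R = 3, seed = 13)
  s2 <- stability_assess(blobs$x, "kmeans", 3, B = 4, R = 3, seed = 13)
  expect_identical(s1, s2)
  expect_error(stability_assess(blobs$x, "kmeans", 3, B = 2, R = 1, seed = 1),
               "R must be")
})
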