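#' Subsampling stability of a clustering algorithm
#'
#' Draws `B` subsamples, each a random `frac` of the cases without
#' replacement; on each subsample the algorithm runs `R` times under
#' distinct derived seeds, and the subsample's agreement score is the mean
#' pairwise ARI (and NMI) over up to `pair_budget` randomly chosen run
#' pairs. The report aggregates the `B` agreement scores as mean, SD, and
#' coefficient of variation (SD/mean) — lower CV means a more stable
#' algorithm. Fully deterministic given `seed`.
#'
#' @param x numeric matrix.
#' @param algorithm registered algorithm name (see [run_algorithm()]).
#' @param k number of clusters.
#' @param B number of subsamples.
#' @param frac subsample fraction.
#' @param R runs per subsample (>= 2).
#' @param pair_budget maximum run pairs scored per subsample.
#' @param params,registry passed to [run_algorithm()].
#' @param seed master seed.
#' @return list of class `stability_report`: `ari_mean`, `ari_sd`, `ari_cv`,
#'   `nmi_mean`, `nmi_sd`, `nmi_cv`, plus the protocol parameters.
#' @export
stability_assess <- function(x, algorithm, k, B = 50L, frac = 0.8, R = 20L,
                             pair_budget = 200L, params = list(), seed = 1L,
                             registry = NULL) {
  if (R < 2L) stopf("R must be >= 2")
  n <- nrow(x)
  m <- ceiling(frac * n)
  if (m <= k) stopf("subsample size %d must exceed k = %d", m, k)
  ari_b <- nmi_b <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, b))
    idx <- sample.int(n, m)
    xs <- x[idx, , drop = FALSE]
    runs <- lapply(seq_len(R), function(r)
      run_algorithm(algorithm, xs, k, params,
                    seed = derive_seed(seed, b * 1000L + r),
                    registry = registry)$labels)
    pairs <- utils::combn(R, 2L)
    npair <- ncol(pairs)
    if (npair > pair_budget) {
      set.seed(derive_seed(seed, b + 500000L))
      pairs <- pairs[, sample.int(npair, pair_budget), drop = FALSE]
    }
    ari_b[b] <- mean(apply(pairs, 2L, function(pr)
      adjusted_rand_index(runs[[pr[1]]], runs[[pr[2]]])))
    nmi_b[b] <- mean(apply(pairs, 2L, function(pr)
      normalized_mutual_information(runs[[pr[1]]], runs[[pr[2]]])))
  }
  cv <- function(v) if (mean(v) > 0) sd(v) / mean(v) else NA_real_
  structure(list(algorithm = algorithm, k = k, B = B, frac = frac, R = R,
                 ari_mean = mean(ari_b), ari_sd = sd(ari_b), ari_cv = cv(ari_b),
                 nmi_mean = mean(nmi_b), nmi_sd = sd(nmi_b), nmi_cv = cv(nmi_b)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability (%s, k = %d; B = %d x R = %d at %.0f%%):\n",
              x$algorithm, x$k, x$B, x$R, 100 * x$frac))
  cat(sprintf("  ARI %.3f +/- %.3f (CV %.3f); NMI %.3f +/- %.3f (CV %.3f)\n",
              x$ari_mean, x$ari_sd, x$ari_cv, x$nmi_mean, x$nmi_sd, x$nmi_cv))
  invisible(x)
}
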