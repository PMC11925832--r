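#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Computes the overall KMO statistic and the per-variable measures of
#' sampling adequacy (MSA). With `R` the correlation matrix and `P` the
#' partial-correlation matrix obtained from the (pseudo-)inverse of `R`
#' (`p_ij = -r^ij / sqrt(r^ii r^jj)`), the overall statistic is
#' `sum R_ij^2 / (sum R_ij^2 + sum P_ij^2)` over off-diagonal pairs;
#' `MSA_j` restricts both sums to row `j`. Values near 1 indicate variables
#' largely explained by the common structure (PCA-suitable); low values
#' indicate variables whose correlations are mostly partial (idiosyncratic).
#'
#' A singular correlation matrix is inverted by SVD pseudo-inverse with a
#' warning. If `R` is exactly the identity both sums vanish; the convention
#' here returns 0 with a warning.
#'
#' @param m a [feature_matrix()] or a numeric matrix with >= 2 columns.
#' @return a list with `overall` and named `per_variable` MSA values.
#' @export
kmo <- function(m) {
  x <- if (inherits(m, "feature_matrix")) m$x else m
  if (ncol(x) < 2L) stopf("kmo() needs at least 2 columns")
  R <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv)) {
    warnf("singular correlation matrix; using pseudo-inverse")
    s <- svd(R)
    pos <- s$d > max(s$d) * 1e-12
    Rinv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  d <- sqrt(abs(diag(Rinv)))
  P <- -Rinv / outer(d, d)
  diag(P) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; p2 <- P^2
  denom <- sum(r2) + sum(p2)
  if (denom == 0) {
    warnf("identity correlation matrix; KMO undefined, returning 0")
    return(list(overall = 0,
                per_variable = setNames(rep(0, ncol(x)), colnames(x))))
  }
  per <- rowSums(r2) / (rowSums(r2) + rowSums(p2))
  per[!is.finite(per)] <- 0
  list(overall = sum(r2) / denom,
       per_variable = setNames(per, colnames(x)))
}

#' Filter variables by sampling adequacy
#'
#' Removes variables whose MSA falls below `kmo_min`. In `single_pass` mode
#' all sub-threshold columns are dropped at once; in `iterative` mode
#' (default, standard MSA practice) the single lowest-MSA column is dropped
#' and the statistic recomputed until every remaining MSA meets the floor.
#'
#' @param m a [feature_matrix()].
#' @param kmo_min per-variable adequacy floor (default 0.6).
#' @param mode `"iterative"` or `"single_pass"`.
#' @return the filtered matrix, removals recorded as reason `"kmo"`.
#' @export
kmo_filter <- function(m, kmo_min = 0.6, mode = c("iterative", "single_pass")) {
  mode <- match.arg(mode)
  stopifnot(kmo_min >= 0, kmo_min < 1)
  if (kmo_min == 0) return(m)
  if (mode == "single_pass") {
    msa <- kmo(m)$per_variable
    bad <- names(msa)[msa < kmo_min]
    if (length(bad) == ncol(m$x)) stopf("KMO filter would drop every column")
    return(fm_drop(m, bad, "kmo"))
  }
  first <- TRUE
  repeat {
    if (ncol(m$x) < 2L) stopf("KMO filter would drop every column")
    # recomputations repeat any singularity warning; report it once
    msa <- if (first) kmo(m)$per_variable
           else suppressWarnings(kmo(m)$per_variable)
    first <- FALSE
    if (all(msa >= kmo_min)) return(m)
    worst <- names(msa)[which.min(msa)]
    m <- fm_drop(m, worst, "kmo")
  }
}

#' Principal component reduction retaining a variance target
#'
#' Eigendecomposition of the covariance of the (already standardized) input;
#' the number of retained components is the smallest `m` whose cumulative
#' explained-variance ratio reaches `var_target` (>= comparison, so hitting
#' the target exactly qualifies). Scores are the centered data projected on
#' the loadings. Eigenvector sign is fixed by forcing the largest-magnitude
#' loading of each component to be positive, making output reproducible
#' across linear-algebra backends.
#'
#' @param m a [feature_matrix()] or numeric matrix without missing values.
#' @param var_target cumulative variance target in (0, 1] (default 0.95).
#' @return list of class `component_matrix`: `scores` (n x m), `loadings`
#'   (p x m, orthonormal), `explained_ratio` (all p ratios, descending),
#'   `n_components`, `kept_features`.
#' @export
pca_reduce <- function(m, var_target = 0.95) {
  stopifnot(var_target > 0, var_target <= 1)
  x <- if (inherits(m, "feature_matrix")) m$x else m
  if (anyNA(x)) stopf("pca_reduce() requires an imputed matrix")
  if (nrow(x) < 2L) stopf("pca_reduce() needs at least 2 rows")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  ncomp <- which(cumsum(ratio) >= var_target - 1e-12)[1]
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(x, 2L, pc$center) %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(ncomp))
  structure(list(scores = scores, loadings = rot,
                 explained_ratio = ratio, n_components = ncomp,
                 kept_features = colnames(x)),
            class = "component_matrix")
}

#' @export
print.component_matrix <- function(x, ...) {
  cat(sprintf("Component matrix: %d x %d scores (%.1f%% variance retained from %d features)\n",
              nrow(x$scores), x$n_components,
              100 * sum(x$explained_ratio[seq_len(x$n_components)]),
              length(x$kept_features)))
  invisible(x)
}

#' Run the KMO + PCA reduction stage and optionally write artifacts
#'
#' @param m a standardized [feature_matrix()].
#' @param kmo_min,kmo_mode,var_target see [kmo_filter()] and [pca_reduce()].
#' @param dir if non-NULL, writes `components.csv`, `loadings.csv` and
#'   `reduction_report.json` there.
#' @return list with the filtered `features` and the `components`.
#' @export
reduce_features <- function(m, kmo_min = 0.6, kmo_mode = "iterative",
                            var_target = 0.95, dir = NULL) {
  msa0 <- kmo(m)$per_variable
  mf <- kmo_filter(m, kmo_min, kmo_mode)
  comp <- pca_reduce(mf, var_target)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(patient_id = rownames(comp$scores), comp$scores,
                         check.names = FALSE),
              file.path(dir, "components.csv"), row.names = FALSE)
    write.csv(data.frame(feature = rownames(comp$loadings), comp$loadings,
                         check.names = FALSE),
              file.path(dir, "loadings.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(msa = as.list(msa0), kept = comp$kept_features,
           dropped = mf$dropped,
           explained_ratio = comp$explained_ratio,
           n_components = comp$n_components),
      file.path(dir, "reduction_report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(features = mf, components = comp)
}
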