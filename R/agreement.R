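# Chance-adjusted and information-theoretic agreement between partitions.

#' Adjusted Rand Index
#'
#' Standard permutation-model ARI from the contingency table:
#' `(Index - Expected) / (Max - Expected)` over pair counts. 1 for identical
#' partitions (up to relabeling), around 0 for independent ones; can be
#' negative.
#'
#' @param labels_a,labels_b equal-length label vectors (length >= 2).
#' @return scalar `<= 1`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stopf("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2L) stopf("need at least 2 cases")
  tab <- table(labels_a, labels_b)
  choose2 <- function(m) m * (m - 1) / 2
  idx <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  exp_idx <- a * b / choose2(n)
  max_idx <- (a + b) / 2
  if (max_idx == exp_idx) return(1)  # both partitions trivial
  (idx - exp_idx) / (max_idx - exp_idx)
}

#' Normalized Mutual Information
#'
#' `NMI = I(U, V) / sqrt(H(U) H(V))` with natural logarithms (geometric-mean
#' normalization; `"arithmetic"` uses `(H(U) + H(V)) / 2`). When both
#' partitions are trivial (zero entropy) the convention is 1.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @param normalization `"geometric"` (default) or `"arithmetic"`.
#' @return value in `[0, 1]`.
#' @export
normalized_mutual_information <- function(labels_a, labels_b,
                                          normalization = c("geometric", "arithmetic")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b)) stopf("label vectors differ in length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b) / n
  pu <- rowSums(tab); pv <- colSums(tab)
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu == 0 && hv == 0) return(1)
  mi <- 0
  for (i in seq_along(pu)) for (j in seq_along(pv)) {
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pu[i] * pv[j]))
  }
  denom <- if (normalization == "geometric") sqrt(hu * hv) else (hu + hv) / 2
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}
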