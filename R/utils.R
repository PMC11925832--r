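# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream index, staying well
# inside 32-bit integer range. Arithmetic in doubles (exact below 2^53) so
# chained derivations cannot overflow.
derive_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483) * 10007 +
                as.numeric(stream) * 101) %% 2147483)
}

# Squared Euclidean distances from every row of x to every row of centers,
# optionally under per-feature weights (n x k matrix result).
row_center_dist2 <- function(x, centers, w = NULL) {
  if (!is.null(w)) {
    sw <- sqrt(w)
    x <- sweep(x, 2L, sw, "*")
    centers <- sweep(centers, 2L, sw, "*")
  }
  xn <- rowSums(x^2)
  cn <- rowSums(centers^2)
  d2 <- outer(xn, cn, "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# Per-cluster means; clusters indexed 1..k. Empty clusters yield NA rows.
cluster_means <- function(x, labels, k) {
  p <- ncol(x)
  out <- matrix(NA_real_, k, p)
  for (c in seq_len(k)) {
    rows <- which(labels == c)
    if (length(rows) == 1L) out[c, ] <- x[rows, ]
    else if (length(rows) > 1L) out[c, ] <- colMeans(x[rows, , drop = FALSE])
  }
  out
}

# Relabel an arbitrary label vector to consecutive integers 1..k preserving
# first-appearance order.
relabel_consecutive <- function(labels) {
  match(labels, unique(labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
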