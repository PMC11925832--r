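# Shared fixtures and independent oracles, built in code at test time.

# Gaussian blob fixture with known labels.
make_blobs <- function(n_per = 30, centers = rbind(c(0, 0), c(8, 0), c(0, 8)),
                       sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(c)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2L,
          centers[c, ], "+")))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Reference Lloyd K-means from fixed initial centers (assignment ties go to
# the lowest-index center, centers updated as plain means).
lloyd_oracle <- function(x, centers, max_iter = 100) {
  labels_old <- rep(0L, nrow(x))
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(nrow(centers)), function(c)
      rowSums(sweep(x, 2L, centers[c, ])^2))
    labels <- apply(d2, 1L, which.min)
    for (c in seq_len(nrow(centers)))
      if (any(labels == c))
        centers[c, ] <- colMeans(x[labels == c, , drop = FALSE])
    if (all(labels == labels_old)) break
    labels_old <- labels
  }
  list(labels = labels, centers = centers)
}

# Brute-force O(n^2) pair-counting ARI.
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / total
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Direct entropy-formula NMI (geometric-mean normalization).
nmi_oracle <- function(a, b) {
  n <- length(a)
  pa <- table(a) / n; pb <- table(b) / n
  ha <- -sum(pa * log(pa)); hb <- -sum(pb * log(pb))
  mi <- 0
  for (u in names(pa)) for (v in names(pb)) {
    puv <- sum(a == u & b == v) / n
    if (puv > 0) mi <- mi + puv * log(puv / (pa[[u]] * pb[[v]]))
  }
  if (ha == 0 && hb == 0) return(1)
  mi / sqrt(ha * hb)
}

# One random toy patient for ASE property tests: random culture day,
# antimicrobial run, lab trajectories spanning the threshold ranges.
random_toy_patient <- function(id) {
  los <- sample(6:12, 1)
  pid <- sprintf("T%04d", id)
  enc <- data.frame(patient_id = pid, hosp_los = los,
                    died = rbinom(1, 1, 0.3), stringsAsFactors = FALSE)
  enc$discharged_alive_day <- if (enc$died == 1) NA_integer_ else los
  ev <- list()
  add <- function(day, type, name, value = NA_real_)
    data.frame(patient_id = pid, day = as.integer(day), event_type = type,
               name = name, value = value, stringsAsFactors = FALSE)
  if (runif(1) < 0.8) {
    cd <- sample(seq_len(los - 2), 1)
    ev <- c(ev, list(add(cd, "blood_culture", "blood_culture")))
    run_len <- sample(0:6, 1)
    if (run_len > 0) {
      start <- min(max(1, cd + sample(-3:3, 1)), los)
      ev <- c(ev, list(add(start:min(start + run_len - 1, los),
                           "antimicrobial", "antimicrobial")))
    }
  }
  days <- sort(sample(seq_len(los), min(4, los)))
  ev <- c(ev, list(
    add(days, "lab", "lactate", round(runif(length(days), 0.5, 4), 2)),
    add(days, "lab", "creatinine", round(runif(length(days), 50, 300), 1)),
    add(days, "lab", "bilirubin", round(runif(length(days), 5, 80), 1)),
    add(days, "lab", "platelets", round(runif(length(days), 40, 350))),
    add(days, "lab", "egfr", round(runif(length(days), 15, 120)))))
  if (runif(1) < 0.3) ev <- c(ev, list(add(sample(seq_len(los), 1), "vent", "vent")))
  if (runif(1) < 0.2) ev <- c(ev, list(add(sample(seq_len(los), 1),
                                           "vasopressor", "vasopressor")))
  list(encounter = enc, events = do.call(rbind, ev))
}

# Table-2-style printed metric values used by the rank-aggregation checks.
printed_metric_table <- function() {
  data.frame(
    silhouette = c(-0.133, -0.153, -0.123, -0.174, -0.142, -0.189, -0.230, -0.614),
    davies_bouldin = c(8.330, 7.874, 6.319, 10.963, 9.538, 8.638, 4.214, 17.693),
    calinski_harabasz = c(73.175, 56.49, 55.568, 110.067, 58.503, 54.859, 53.357, 1.473),
    shannon = c(3.568, 3.701, 2.900, 3.353, 3.712, 3.646, 2.595, 3.229),
    gini = c(0.481, 0.487, 0.523, 0.492, 0.529, 0.510, 0.528, 0.491),
    row.names = c("kmeans", "rskc", "clara", "som", "dcae", "gmm",
                  "minibatch_kmeans", "weighted_kmeans"))
}
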