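# Boosted-tree multi-class cluster membership model used to carry
# development-cohort cluster labels onto an external validation cohort.

hyper_space <- function() list(
  eta = c(0.02, 0.3),          # log-uniform
  max_depth = c(2L, 8L),
  subsample = c(0.5, 1),
  colsample_bytree = c(0.5, 1),
  nrounds = c(30L, 200L)
)

sample_config <- function() {
  sp <- hyper_space()
  list(eta = exp(runif(1, log(sp$eta[1]), log(sp$eta[2]))),
       max_depth = sample(sp$max_depth[1]:sp$max_depth[2], 1L),
       subsample = runif(1, sp$subsample[1], sp$subsample[2]),
       colsample_bytree = runif(1, sp$colsample_bytree[1], sp$colsample_bytree[2]),
       nrounds = sample(sp$nrounds[1]:sp$nrounds[2], 1L))
}

cv_accuracy <- function(x, y, n_class, cfg, folds, seed) {
  params <- list(objective = "multi:softprob", num_class = n_class,
                 eta = cfg$eta, max_depth = cfg$max_depth,
                 subsample = cfg$subsample,
                 colsample_bytree = cfg$colsample_bytree,
                 eval_metric = "merror", nthread = 1L, seed = seed)
  d <- xgboost::xgb.DMatrix(x, label = y)
  cvres <- xgboost::xgb.cv(params = params, data = d, nrounds = cfg$nrounds,
                           nfold = folds, verbose = 0, stratified = TRUE)
  log <- cvres$evaluation_log
  1 - min(log$test_merror_mean)
}

#' Fit a boosted-tree cluster-membership model
#'
#' Gradient-boosted trees with softmax multi-class output, trained to predict
#' development-cohort cluster labels from the post-KMO variables.
#' Hyperparameters (learning rate, tree depth, subsample ratio, column
#' subsample, boosting rounds) are chosen to maximize mean k-fold
#' cross-validated accuracy within `budget` evaluations by a sequential
#' model-based optimizer: a random initial design followed by proposals
#' scored with a random-forest surrogate over a random candidate pool.
#' `tuner = "random"` falls back to pure random search; `budget = 1` skips
#' tuning and fits sensible defaults. Deterministic given `seed`.
#'
#' @param x numeric feature matrix (post-KMO variables, not PCA scores).
#' @param labels integer cluster labels; every class needs >= 2 rows.
#' @param budget number of hyperparameter evaluations.
#' @param folds CV folds.
#' @param tuner `"smbo"` (default) or `"random"`.
#' @param seed integer seed.
#' @return object of class `membership_model`: the fitted booster plus
#'   `feature_names`, `classes`, `tuned_params`, `cv_score`, `seed`.
#' @export
fit_membership_model <- function(x, labels, budget = 30L, folds = 5L,
                                 tuner = c("smbo", "random"), seed = 1L) {
  tuner <- match.arg(tuner)
  x <- as.matrix(x)
  classes <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes < 2L))
    stopf("class(es) with a single training row: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  y <- match(labels, classes) - 1L
  n_class <- length(classes)
  folds <- min(folds, min(sizes))
  set.seed(as.integer(seed))

  default_cfg <- list(eta = 0.1, max_depth = 4L, subsample = 0.9,
                      colsample_bytree = 0.9, nrounds = 100L)
  evals <- list(); scores <- numeric(0)
  if (budget <= 1L) {
    best_cfg <- default_cfg
    best_score <- NA_real_
  } else {
    n_init <- min(budget, max(3L, ceiling(budget / 3)))
    for (i in seq_len(n_init)) {
      cfg <- if (i == 1L) default_cfg else sample_config()
      evals[[i]] <- cfg
      scores[i] <- cv_accuracy(x, y, n_class, cfg, folds,
                               derive_seed(seed, i))
    }
    while (length(evals) < budget) {
      i <- length(evals) + 1L
      cfg <- if (tuner == "random") sample_config()
             else propose_smbo(evals, scores)
      evals[[i]] <- cfg
      scores[i] <- cv_accuracy(x, y, n_class, cfg, folds,
                               derive_seed(seed, i))
    }
    best_cfg <- evals[[which.max(scores)]]
    best_score <- max(scores)
  }

  params <- list(objective = "multi:softprob", num_class = n_class,
                 eta = best_cfg$eta, max_depth = best_cfg$max_depth,
                 subsample = best_cfg$subsample,
                 colsample_bytree = best_cfg$colsample_bytree,
                 nthread = 1L, seed = seed)
  booster <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(x, label = y),
                                nrounds = best_cfg$nrounds)
  structure(list(booster = booster, feature_names = colnames(x),
                 classes = classes, tuned_params = best_cfg,
                 cv_score = best_score, seed = as.integer(seed)),
            class = "membership_model")
}

# Surrogate proposal: fit a random forest to (config, score) pairs and pick
# the candidate with the best predicted score from a random pool.
propose_smbo <- function(evals, scores, pool_size = 50L) {
  df <- do.call(rbind, lapply(evals, function(cfg)
    data.frame(eta = cfg$eta, max_depth = cfg$max_depth,
               subsample = cfg$subsample,
               colsample_bytree = cfg$colsample_bytree,
               nrounds = cfg$nrounds)))
  df$score <- scores
  rf <- ranger::ranger(score ~ ., data = df, num.trees = 200L,
                       seed = nrow(df))
  pool <- replicate(pool_size, sample_config(), simplify = FALSE)
  pdf <- do.call(rbind, lapply(pool, as.data.frame))
  pred <- predict(rf, pdf)$predictions
  pool[[which.max(pred)]]
}

#' @export
print.membership_model <- function(x, ...) {
  cat(sprintf("Cluster membership model: %d classes, %d features\n",
              length(x$classes), length(x$feature_names)))
  if (!is.na(x$cv_score))
    cat(sprintf("  tuned CV accuracy %.3f (eta %.3g, depth %d, %d rounds)\n",
                x$cv_score, x$tuned_params$eta, x$tuned_params$max_depth,
                x$tuned_params$nrounds))
  invisible(x)
}

#' Predicted class probabilities
#' @param object a `membership_model`.
#' @param newdata matrix with the model's feature columns.
#' @param ... unused.
#' @return n x k matrix of class probabilities (columns named by cluster id).
#' @export
predict.membership_model <- function(object, newdata, ...) {
  newdata <- check_model_features(object, newdata)
  pr <- predict(object$booster, newdata)
  colnames(pr) <- as.character(object$classes)
  pr
}

check_model_features <- function(model, x) {
  x <- as.matrix(x)
  missing <- setdiff(model$feature_names, colnames(x))
  if (length(missing))
    stopf("missing feature column(s): %s", paste(missing, collapse = ", "))
  x[, model$feature_names, drop = FALSE]
}

#' Assign cases to clusters by maximum predicted probability
#'
#' Ties resolve to the smallest cluster id and are reported via a message.
#'
#' @param model a `membership_model`.
#' @param x_new matrix with the model's feature columns.
#' @return integer vector of cluster ids.
#' @export
assign_clusters <- function(model, x_new) {
  pr <- predict(model, x_new)
  top <- apply(pr, 1L, max)
  n_tied <- sum(rowSums(pr == top) > 1L)
  if (n_tied > 0) message(sprintf("%d tied assignment(s) resolved to the smallest cluster id", n_tied))
  model$classes[apply(pr, 1L, which.max)]
}

#' Per-feature additive attributions (SHAP values)
#'
#' Exact tree-path attributions from the boosted ensemble: for every case
#' and class, `baseline + sum_features attribution` equals the model margin
#' for that class (additivity contract, tolerance 1e-4).
#'
#' @param model a `membership_model`.
#' @param x matrix with the model's feature columns.
#' @param top_q how many top features to report per class in `$top_features`.
#' @return list of class `attribution_matrix`: `values` (n x class x feature
#'   array), `baseline` (per case and class), `top_features` (per class,
#'   ranked by mean absolute attribution).
#' @export
feature_attribution <- function(model, x, top_q = 10L) {
  x <- check_model_features(model, x)
  contrib <- predict(model$booster, x, predcontrib = TRUE)
  p <- length(model$feature_names)
  values <- contrib[, , seq_len(p), drop = FALSE]
  dimnames(values) <- list(NULL, as.character(model$classes),
                           model$feature_names)
  baseline <- contrib[, , p + 1L]
  top <- lapply(seq_along(model$classes), function(c) {
    imp <- apply(abs(values[, c, , drop = FALSE]), 3L, mean)
    head(sort(imp, decreasing = TRUE), top_q)
  })
  names(top) <- as.character(model$classes)
  structure(list(values = values, baseline = baseline, top_features = top),
            class = "attribution_matrix")
}

#' Compare development and validation cohorts
#'
#' Pearson correlation between the per-cluster ASE-positive fractions of the
#' two cohorts (clusters matched by id), optionally with variable-wise
#' standardized differences when feature matrices are supplied.
#'
#' @param dev_comp,val_comp cluster composition tables from
#'   [subdivide_clusters()] sharing a cluster id set.
#' @param dev_x,val_x optional feature matrices (same columns) for the
#'   standardized-difference report.
#' @param kinds optional per-column kind (`"continuous"`/`"binary"`) for the
#'   report; inferred from values when omitted.
#' @return list with `pearson_r` and (possibly NULL) `std_diff` data frame.
#' @export
compare_cohorts <- function(dev_comp, val_comp, dev_x = NULL, val_x = NULL,
                            kinds = NULL) {
  ids <- sort(dev_comp$cluster)
  if (!setequal(ids, val_comp$cluster))
    stopf("cohorts have different cluster id sets")
  fd <- dev_comp$frac_ase_pos[match(ids, dev_comp$cluster)]
  fv <- val_comp$frac_ase_pos[match(ids, val_comp$cluster)]
  if (sd(fd) == 0 || sd(fv) == 0)
    stopf("correlation undefined: constant ASE-fraction vector")
  r <- cor(fd, fv)
  sdiff <- NULL
  if (!is.null(dev_x) && !is.null(val_x)) {
    dev_x <- as.matrix(dev_x); val_x <- as.matrix(val_x)
    common <- intersect(colnames(dev_x), colnames(val_x))
    if (is.null(kinds))
      kinds <- ifelse(vapply(common, function(cn)
        all(c(dev_x[, cn], val_x[, cn]) %in% c(0, 1)), TRUE),
        "binary", "continuous")
    rows <- lapply(common, function(cn) {
      g1 <- dev_x[, cn]; g2 <- val_x[, cn]
      res <- tryCatch({
        if (kinds[[cn]] == "binary")
          standardized_difference(list(p = mean(g1), n = length(g1)),
                                  list(p = mean(g2), n = length(g2)),
                                  kind = "binary")
        else
          standardized_difference(list(mean = mean(g1), sd = sd(g1)),
                                  list(mean = mean(g2), sd = sd(g2)),
                                  kind = "continuous")
      }, error = function(e) list(d = NA_real_, class = NA_character_))
      data.frame(variable = cn, kind = kinds[[cn]], d = res$d,
                 effect = res$class, stringsAsFactors = FALSE)
    })
    sdiff <- do.call(rbind, rows)
  }
  list(pearson_r = r, std_diff = sdiff)
}
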