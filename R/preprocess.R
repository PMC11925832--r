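#' Feature matrix container
#'
#' A light container pairing an `n x p` numeric matrix with per-column
#' metadata: the feature name, its kind (`binary` or `continuous`), the
#' summary it came from (`min`, `max`, `sd` or `static`), and its observed
#' missing fraction. Columns removed by the filters are recorded in
#' `$dropped` with the reason.
#'
#' @param x numeric matrix (may contain `NA` before imputation).
#' @param kind character vector, one of `"binary"`, `"continuous"` per column.
#' @param summary per-column source summary; defaults to `"static"`.
#' @return object of class `feature_matrix` with elements `x`, `meta`,
#'   `dropped`.
#' @export
feature_matrix <- function(x, kind, summary = rep("static", ncol(x))) {
  stopifnot(is.matrix(x), !is.null(colnames(x)),
            length(kind) == ncol(x), length(summary) == ncol(x))
  if (anyDuplicated(colnames(x))) stopf("duplicate feature names")
  meta <- data.frame(name = colnames(x), kind = kind, summary = summary,
                     missing_fraction = colMeans(is.na(x)),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(x = x, meta = meta,
                 dropped = data.frame(name = character(), reason = character(),
                                      stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d patients x %d features (%d binary, %d continuous)\n",
              nrow(x$x), ncol(x$x), sum(x$meta$kind == "binary"),
              sum(x$meta$kind == "continuous")))
  if (nrow(x$dropped))
    cat(sprintf("  dropped: %d (%s)\n", nrow(x$dropped),
                paste(sprintf("%s=%d", names(table(x$dropped$reason)),
                              table(x$dropped$reason)), collapse = ", ")))
  invisible(x)
}

fm_drop <- function(m, cols, reason) {
  if (!length(cols)) return(m)
  m$dropped <- rbind(m$dropped,
                     data.frame(name = cols, reason = reason,
                                stringsAsFactors = FALSE))
  keep <- setdiff(colnames(m$x), cols)
  m$x <- m$x[, keep, drop = FALSE]
  m$meta <- m$meta[m$meta$name %in% keep, , drop = FALSE]
  rownames(m$meta) <- NULL
  m
}

fm_cbind <- function(a, b) {
  stopifnot(nrow(a$x) == nrow(b$x))
  out <- feature_matrix(cbind(a$x, b$x), c(a$meta$kind, b$meta$kind),
                        c(a$meta$summary, b$meta$summary))
  # recompute from parts so pre-recorded missing fractions survive cbind
  out$meta$missing_fraction <- c(a$meta$missing_fraction, b$meta$missing_fraction)
  out$dropped <- rbind(a$dropped, b$dropped)
  out
}

#' Summarize day-stamped events into patient-level features
#'
#' Every lab with at least one observation for a patient contributes its
#' minimum, maximum and sample standard deviation over time (n-1 denominator;
#' a single observation gets SD = `sd_convention`, default 0), reflecting
#' extremes and fluctuation of the physiological state. Patients with no
#' observation of a lab get missing markers. Non-lab event streams become
#' count/indicator features: `any_vent`, `any_vasopressor`,
#' `antimicrobial_days` (distinct calendar days), `blood_culture_count`.
#'
#' Rows with a non-finite lab value are rejected with a warning.
#'
#' @param events long-format event table.
#' @param encounters encounter table (defines the patient universe and order).
#' @param sd_convention SD assigned to single-observation series.
#' @return a [feature_matrix()].
#' @export
summarize_timeseries <- function(events, encounters, sd_convention = 0) {
  pid <- encounters$patient_id
  n <- length(pid)
  labs <- events[events$event_type == "lab", , drop = FALSE]
  bad <- !is.finite(labs$value)
  if (any(bad)) {
    warnf("rejecting %d lab rows with non-finite values", sum(bad))
    labs <- labs[!bad, , drop = FALSE]
  }
  lab_names <- sort(unique(labs$name))
  cols <- list()
  for (nm in lab_names) {
    sub <- labs[labs$name == nm, , drop = FALSE]
    sp <- split(sub$value, factor(sub$patient_id, levels = pid))
    mn <- vapply(sp, function(v) if (length(v)) min(v) else NA_real_, 0)
    mx <- vapply(sp, function(v) if (length(v)) max(v) else NA_real_, 0)
    sdv <- vapply(sp, function(v) {
      if (!length(v)) NA_real_
      else if (length(v) == 1L) sd_convention
      else sd(v)
    }, 0)
    cols[[paste0(nm, "_min")]] <- mn
    cols[[paste0(nm, "_max")]] <- mx
    cols[[paste0(nm, "_sd")]] <- sdv
  }
  count_days <- function(type) {
    sub <- events[events$event_type == type, c("patient_id", "day")]
    sub <- unique(sub)
    tab <- table(factor(sub$patient_id, levels = pid))
    as.numeric(tab)
  }
  vent_days <- count_days("vent")
  vaso_days <- count_days("vasopressor")
  cols[["any_vent"]] <- as.numeric(vent_days > 0)
  cols[["any_vasopressor"]] <- as.numeric(vaso_days > 0)
  cols[["antimicrobial_days"]] <- count_days("antimicrobial")
  bc <- events[events$event_type == "blood_culture", , drop = FALSE]
  cols[["blood_culture_count"]] <-
    as.numeric(table(factor(bc$patient_id, levels = pid)))
  x <- do.call(cbind, cols)
  rownames(x) <- pid
  kind <- ifelse(colnames(x) %in% c("any_vent", "any_vasopressor"),
                 "binary", "continuous")
  summ <- rep("static", ncol(x))
  summ[grepl("_min$", colnames(x))] <- "min"
  summ[grepl("_max$", colnames(x))] <- "max"
  summ[grepl("_sd$", colnames(x))] <- "sd"
  feature_matrix(x, kind, summ)
}

#' Encode encounter-level variables as feature columns
#'
#' Categorical fields become one 0/1 indicator column per level (full dummy
#' encoding); existing flags and numeric fields pass through unchanged.
#' Outcome variables (`died`) and raw timing variables
#' (`discharged_alive_day`) are excluded; derived lengths of stay are kept.
#'
#' @param encounters encounter table.
#' @return a [feature_matrix()] of the encounter-derived columns.
#' @export
encode_categoricals <- function(encounters) {
  drop_cols <- c("patient_id", "died", "discharged_alive_day")
  enc <- encounters[, setdiff(names(encounters), drop_cols), drop = FALSE]
  cols <- list(); kind <- character()
  for (nm in names(enc)) {
    v <- enc[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      for (lev in sort(unique(v))) {
        cn <- paste0(nm, "_", lev)
        cols[[cn]] <- as.numeric(v == lev)
        kind[cn] <- "binary"
      }
    } else {
      cols[[nm]] <- as.numeric(v)
      kind[nm] <- if (all(v %in% c(0, 1, NA))) "binary" else "continuous"
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- encounters$patient_id
  feature_matrix(x, unname(kind[colnames(x)]))
}

#' Build the full raw feature matrix for a cohort
#'
#' Column-binds the encounter-derived block ([encode_categoricals()]) and the
#' event-summary block ([summarize_timeseries()]).
#'
#' @param encounters,events cohort tables.
#' @return a [feature_matrix()].
#' @export
build_features <- function(encounters, events) {
  fm_cbind(encode_categoricals(encounters),
           summarize_timeseries(events, encounters))
}

#' Remove rare binary indicators
#'
#' Binary columns whose prevalence (mean over non-missing rows) is strictly
#' below `prevalence_min` are removed; continuous columns are untouched.
#'
#' @param m a [feature_matrix()].
#' @param prevalence_min prevalence floor (default 0.01).
#' @return the filtered matrix with removals recorded in `$dropped`.
#' @export
filter_prevalence <- function(m, prevalence_min = 0.01) {
  stopifnot(prevalence_min > 0, prevalence_min < 1)
  bin <- m$meta$name[m$meta$kind == "binary"]
  prev <- colMeans(m$x[, bin, drop = FALSE], na.rm = TRUE)
  fm_drop(m, bin[prev < prevalence_min], "prevalence")
}

#' Remove highly collinear features
#'
#' For each pair of columns with `|Pearson r| > collinearity_r_max`
#' (pairwise-complete observations), the later column in matrix order is
#' dropped. The scan is a greedy single pass over pairs in column order, so
#' the result is deterministic. Correlations involving a constant column are
#' treated as 0.
#'
#' @param m a [feature_matrix()].
#' @param collinearity_r_max absolute correlation cap (default 0.9).
#' @return the filtered matrix.
#' @export
filter_collinear <- function(m, collinearity_r_max = 0.9) {
  stopifnot(collinearity_r_max > 0, collinearity_r_max <= 1)
  x <- m$x
  p <- ncol(x)
  if (p < 2L) return(m)
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  dropped <- logical(p)
  for (i in seq_len(p - 1L)) {
    if (dropped[i]) next
    for (j in seq((i + 1L), p)) {
      if (!dropped[j] && abs(r[i, j]) > collinearity_r_max) dropped[j] <- TRUE
    }
  }
  fm_drop(m, colnames(x)[dropped], "collinearity")
}

#' Mean-impute missing values
#'
#' Every missing marker is replaced by the mean of the available values in
#' its column. A fully-missing column is an error.
#'
#' @param m a [feature_matrix()].
#' @return the imputed matrix; `missing_fraction` metadata is preserved.
#' @export
impute_mean <- function(m) {
  x <- m$x
  miss <- colSums(is.na(x))
  full <- colnames(x)[miss == nrow(x)]
  if (length(full))
    stopf("cannot impute fully-missing column(s): %s",
          paste(full, collapse = ", "))
  for (j in which(miss > 0)) {
    mu <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- mu
  }
  m$x <- x
  m
}

#' Standardize continuous features
#'
#' Continuous columns are z-scored with the population SD (n denominator) so
#' no variable dominates through its value range; binary indicator columns
#' are left on the 0/1 scale. A constant continuous column is set to all
#' zeros with a warning.
#'
#' @param m an imputed [feature_matrix()].
#' @return the standardized matrix.
#' @export
standardize <- function(m) {
  if (anyNA(m$x)) stopf("standardize() requires an imputed matrix")
  x <- m$x
  n <- nrow(x)
  for (j in which(m$meta$kind == "continuous")) {
    mu <- mean(x[, j])
    s <- sqrt(sum((x[, j] - mu)^2) / n)
    if (s == 0) {
      warnf("constant continuous column '%s' set to zeros", colnames(x)[j])
      x[, j] <- 0
    } else {
      x[, j] <- (x[, j] - mu) / s
    }
  }
  m$x <- x
  m
}

#' Run the fixed preprocessing pipeline
#'
#' Composition, in order: event summarization + categorical encoding,
#' prevalence filter, collinearity filter, mean imputation, standardization.
#' The composition is deterministic; rerunning on the same tables reproduces
#' the same matrix.
#'
#' @param encounters,events cohort tables.
#' @param prevalence_min,collinearity_r_max filter settings.
#' @return a standardized [feature_matrix()] with no missing values.
#' @export
preprocess_cohort <- function(encounters, events,
                              prevalence_min = 0.01,
                              collinearity_r_max = 0.9) {
  m <- build_features(encounters, events)
  m <- filter_prevalence(m, prevalence_min)
  m <- filter_collinear(m, collinearity_r_max)
  m <- impute_mean(m)
  standardize(m)
}

#' Write a feature matrix and its metadata
#'
#' Writes `features.csv` (with patient ids) and `features_meta.json` (name,
#' kind, summary, missing fraction, and the dropped-column log).
#'
#' @param m a [feature_matrix()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_features <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(patient_id = rownames(m$x), m$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, file.path(dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(list(features = m$meta, dropped = m$dropped),
                       file.path(dir, "features_meta.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
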