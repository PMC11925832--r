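# Adult Sepsis Event (ASE) rules engine. Day-granular implementation of the
# CDC surveillance definition: presumed infection (blood culture plus a
# qualifying run of antimicrobial days) with concurrent acute organ
# dysfunction inside a day window around the culture, with every threshold
# parameterized so liberalized variants can be expressed as criteria
# objects.

#' ASE criteria set
#'
#' All thresholds of the Adult Sepsis Event definition as a single
#' parameter object. Defaults are the standard criteria: organ dysfunction
#' within +/- 2 days of a blood culture, at least 4 qualifying antimicrobial
#' days (QAD), creatinine rise >= 2-fold over the encounter-minimum baseline
#' or eGFR decline >= 50% from the encounter-maximum baseline, total
#' bilirubin >= 34.2 umol/L with >= 2-fold rise, lactate > 2 mmol/L,
#' platelets < 100 x 10^9/L with >= 50% decline from an encounter-maximum
#' baseline that itself must be >= `platelet_baseline_min`.
#'
#' `platelet_baseline_min` is kept fixed (100) across liberalized variants so
#' that relaxing `platelet_abs_max` can only add positives.
#'
#' @param variant_id label for the criteria set.
#' @param window_days max `|dysfunction day - culture day|` (default 2).
#' @param min_qad minimum qualifying antimicrobial days (default 4).
#' @param creat_ratio_min fold-rise of creatinine over baseline (default 2).
#' @param egfr_decline_min fractional eGFR decline (default 0.5).
#' @param bili_abs_min absolute bilirubin threshold, umol/L (default 34.2).
#' @param bili_ratio_min fold-rise of bilirubin (default 2).
#' @param lactate_min lactate threshold, mmol/L, strict `>` (default 2).
#' @param platelet_abs_max platelet threshold, 10^9/L, strict `<` (default 100).
#' @param platelet_decline_min fractional platelet decline (default 0.5).
#' @param platelet_baseline_min minimum qualifying baseline (default 100).
#' @param discharge_alive_qad_rule if TRUE, an antimicrobial run extending to
#'   the day of leaving hospital alive qualifies regardless of `min_qad`.
#' @return object of class `ase_criteria`.
#' @export
ase_criteria <- function(variant_id = "default", window_days = 2L,
                         min_qad = 4L, creat_ratio_min = 2.0,
                         egfr_decline_min = 0.50, bili_abs_min = 34.2,
                         bili_ratio_min = 2.0, lactate_min = 2.0,
                         platelet_abs_max = 100, platelet_decline_min = 0.50,
                         platelet_baseline_min = 100,
                         discharge_alive_qad_rule = FALSE) {
  cr <- list(variant_id = variant_id, window_days = as.integer(window_days),
             min_qad = as.integer(min_qad), creat_ratio_min = creat_ratio_min,
             egfr_decline_min = egfr_decline_min, bili_abs_min = bili_abs_min,
             bili_ratio_min = bili_ratio_min, lactate_min = lactate_min,
             platelet_abs_max = platelet_abs_max,
             platelet_decline_min = platelet_decline_min,
             platelet_baseline_min = platelet_baseline_min,
             discharge_alive_qad_rule = isTRUE(discharge_alive_qad_rule))
  if (cr$window_days < 0) stopf("window_days must be >= 0")
  pos <- c("min_qad", "creat_ratio_min", "bili_abs_min", "bili_ratio_min",
           "lactate_min", "platelet_abs_max", "platelet_baseline_min")
  for (f in pos) if (cr[[f]] <= 0) stopf("%s must be positive", f)
  for (f in c("egfr_decline_min", "platelet_decline_min"))
    if (cr[[f]] <= 0 || cr[[f]] >= 1) stopf("%s must lie in (0, 1)", f)
  class(cr) <- "ase_criteria"
  cr
}

#' @export
print.ase_criteria <- function(x, ...) {
  cat(sprintf("ASE criteria '%s': window +/-%d d, QAD >= %d%s\n", x$variant_id,
              x$window_days, x$min_qad,
              if (x$discharge_alive_qad_rule) " (or run to discharge alive)" else ""))
  cat(sprintf("  creat x%.2g | eGFR -%.0f%% | bili >= %.3g & x%.2g | lactate > %.2g | plt < %.3g & -%.0f%%\n",
              x$creat_ratio_min, 100 * x$egfr_decline_min, x$bili_abs_min,
              x$bili_ratio_min, x$lactate_min, x$platelet_abs_max,
              100 * x$platelet_decline_min))
  invisible(x)
}

#' The ten liberalized ASE criteria variants
#'
#' Variants `a`-`j`: (a) creatinine rise >= 1.5-fold or eGFR decline >= 25%;
#' (b) bilirubin >= 25.7 umol/L with >= 1.5-fold rise; (c) lactate > 1.5
#' mmol/L; (d) platelets < 150 with >= 25% decline; (e) a-d combined;
#' (f) window 3 days; (g) window 4 days; (h) minimum 3 QAD; (i) antimicrobial
#' run extending to the day of leaving hospital alive qualifies;
#' (j) a, b, c, d, f, h and i combined. The default criteria set is the
#' reference and is not part of the list.
#'
#' @return named list of ten [ase_criteria()] objects.
#' @export
liberalized_variants <- function() {
  v <- list(
    a = ase_criteria("a", creat_ratio_min = 1.5, egfr_decline_min = 0.25),
    b = ase_criteria("b", bili_abs_min = 25.7, bili_ratio_min = 1.5),
    c = ase_criteria("c", lactate_min = 1.5),
    d = ase_criteria("d", platelet_abs_max = 150, platelet_decline_min = 0.25),
    e = ase_criteria("e", creat_ratio_min = 1.5, egfr_decline_min = 0.25,
                     bili_abs_min = 25.7, bili_ratio_min = 1.5,
                     lactate_min = 1.5, platelet_abs_max = 150,
                     platelet_decline_min = 0.25),
    f = ase_criteria("f", window_days = 3L),
    g = ase_criteria("g", window_days = 4L),
    h = ase_criteria("h", min_qad = 3L),
    i = ase_criteria("i", discharge_alive_qad_rule = TRUE),
    j = ase_criteria("j", creat_ratio_min = 1.5, egfr_decline_min = 0.25,
                     bili_abs_min = 25.7, bili_ratio_min = 1.5,
                     lactate_min = 1.5, platelet_abs_max = 150,
                     platelet_decline_min = 0.25, window_days = 3L,
                     min_qad = 3L, discharge_alive_qad_rule = TRUE))
  v
}

# Reporting convention: percentages rounded to one decimal.
pct1 <- function(num, den) round(100 * num / den, 1)

# Maximal runs of consecutive integer days; returns list of c(first, last).
day_runs <- function(days) {
  days <- sort(unique(days))
  if (!length(days)) return(list())
  breaks <- which(diff(days) > 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(days))
  Map(function(s, e) c(days[s], days[e]), starts, ends)
}

#' Qualifying antimicrobial days around a blood culture
#'
#' QAD is the length of the longest run of consecutive calendar days with at
#' least one antimicrobial event whose first day lies within
#' `+/- window_days` of the culture day. If `discharge_alive_qad_rule` is
#' set and such a run extends to the day the patient left hospital alive,
#' the run qualifies regardless of `min_qad`.
#'
#' @param events event table rows for one patient.
#' @param culture_day blood-culture day.
#' @param criteria an [ase_criteria()].
#' @param discharged_alive_day hospital day of leaving alive, or `NA`.
#' @return list with `qad` (count; 0 when no antimicrobials) and
#'   `qualifies` (logical, including the discharge-alive rule).
#' @export
qualifying_antimicrobial_days <- function(events, culture_day, criteria,
                                          discharged_alive_day = NA) {
  days <- events$day[events$event_type == "antimicrobial"]
  runs <- day_runs(days)
  eligible <- Filter(function(r)
    abs(r[1] - culture_day) <= criteria$window_days, runs)
  if (!length(eligible)) return(list(qad = 0L, qualifies = FALSE))
  lens <- vapply(eligible, function(r) r[2] - r[1] + 1L, 0L)
  qad <- max(lens)
  qualifies <- qad >= criteria$min_qad
  if (!qualifies && criteria$discharge_alive_qad_rule &&
      !is.na(discharged_alive_day)) {
    qualifies <- any(vapply(eligible, function(r)
      r[2] >= discharged_alive_day, TRUE))
  }
  list(qad = as.integer(qad), qualifies = qualifies)
}

#' Acute organ dysfunction flags in the culture window
#'
#' Evaluates the six ASE organ-dysfunction categories inside
#' `[culture_day - window, culture_day + window]`:
#' respiratory (any ventilation day), cardiac (any vasopressor day),
#' lactate (any value strictly above the threshold), renal (peak in-window
#' creatinine over the encounter-minimum baseline, or eGFR decline from the
#' encounter-maximum baseline), liver (peak in-window bilirubin above the
#' absolute threshold and fold-rise over the encounter-minimum baseline),
#' hematologic (in-window platelet nadir below the threshold with a
#' sufficient decline from an encounter-maximum baseline that is itself at
#' least `platelet_baseline_min`).
#'
#' Lab events with names outside the known panel are ignored with a warning.
#'
#' @inheritParams qualifying_antimicrobial_days
#' @return named logical vector over the six categories.
#' @export
organ_dysfunction_flags <- function(events, culture_day, criteria) {
  lo <- culture_day - criteria$window_days
  hi <- culture_day + criteria$window_days
  in_win <- events$day >= lo & events$day <= hi
  labs <- events[events$event_type == "lab", , drop = FALSE]
  known <- c("lactate", "creatinine", "bilirubin", "platelets", "egfr",
             "sodium", "wbc")
  unknown <- setdiff(unique(labs$name), known)
  if (length(unknown))
    warnf("ignoring unknown lab name(s): %s", paste(unknown, collapse = ", "))
  wlab <- function(nm) labs$value[labs$name == nm & labs$day >= lo & labs$day <= hi]
  alab <- function(nm) labs$value[labs$name == nm]

  respiratory <- any(events$event_type == "vent" & in_win)
  cardiac <- any(events$event_type == "vasopressor" & in_win)
  lactate <- length(wlab("lactate")) > 0 && max(wlab("lactate")) > criteria$lactate_min

  renal <- FALSE
  cr_all <- alab("creatinine"); cr_win <- wlab("creatinine")
  if (length(cr_all) && length(cr_win) && min(cr_all) > 0)
    renal <- max(cr_win) / min(cr_all) >= criteria$creat_ratio_min
  eg_all <- alab("egfr"); eg_win <- wlab("egfr")
  if (!renal && length(eg_all) && length(eg_win) && max(eg_all) > 0)
    renal <- (max(eg_all) - min(eg_win)) / max(eg_all) >= criteria$egfr_decline_min

  liver <- FALSE
  bi_all <- alab("bilirubin"); bi_win <- wlab("bilirubin")
  if (length(bi_all) && length(bi_win) && min(bi_all) > 0)
    liver <- max(bi_win) >= criteria$bili_abs_min &&
      max(bi_win) / min(bi_all) >= criteria$bili_ratio_min

  hematologic <- FALSE
  pl_all <- alab("platelets"); pl_win <- wlab("platelets")
  if (length(pl_all) && length(pl_win) && max(pl_all) > 0) {
    baseline <- max(pl_all)
    hematologic <- baseline >= criteria$platelet_baseline_min &&
      min(pl_win) < criteria$platelet_abs_max &&
      (baseline - min(pl_win)) / baseline >= criteria$platelet_decline_min
  }

  c(respiratory = respiratory, renal = renal, liver = liver,
    hematologic = hematologic, cardiac = cardiac, lactate = lactate)
}

#' ASE status of one encounter
#'
#' Positive iff some blood-culture day has a qualifying antimicrobial run
#' (per [qualifying_antimicrobial_days()]) and at least one organ-dysfunction
#' flag inside the window. With multiple cultures, the first qualifying day
#' is recorded.
#'
#' @param encounter single row of an encounter table.
#' @param events event rows for that patient.
#' @param criteria an [ase_criteria()].
#' @return list of class `ase_assessment`: `patient_id`, `variant_id`,
#'   `ase_positive`, `culture_day`, `qad`, `flags`.
#' @export
ase_status <- function(encounter, events, criteria = ase_criteria()) {
  culture_days <- sort(unique(events$day[events$event_type == "blood_culture"]))
  dad <- encounter$discharged_alive_day
  out <- list(patient_id = encounter$patient_id,
              variant_id = criteria$variant_id, ase_positive = FALSE,
              culture_day = NA_integer_, qad = 0L,
              flags = setNames(rep(FALSE, 6),
                               c("respiratory", "renal", "liver",
                                 "hematologic", "cardiac", "lactate")))
  class(out) <- "ase_assessment"
  for (cd in culture_days) {
    q <- qualifying_antimicrobial_days(events, cd, criteria, dad)
    if (!q$qualifies) next
    flags <- organ_dysfunction_flags(events, cd, criteria)
    if (any(flags)) {
      out$ase_positive <- TRUE
      out$culture_day <- as.integer(cd)
      out$qad <- q$qad
      out$flags <- flags
      return(out)
    }
  }
  if (length(culture_days)) {
    q <- qualifying_antimicrobial_days(events, culture_days[1], criteria, dad)
    out$qad <- q$qad
    out$culture_day <- as.integer(culture_days[1])
  }
  out
}

#' Assess every encounter in a cohort against one criteria set
#'
#' @param encounters encounter table.
#' @param events event table.
#' @param criteria an [ase_criteria()].
#' @return data frame with one row per patient: `patient_id`, `variant_id`,
#'   `ase_positive`, `culture_day`, `qad`, and the six flag columns.
#' @export
ase_assess <- function(encounters, events, criteria = ase_criteria()) {
  ev_split <- split(events, factor(events$patient_id,
                                   levels = encounters$patient_id))
  rows <- lapply(seq_len(nrow(encounters)), function(i) {
    st <- ase_status(encounters[i, ], ev_split[[i]], criteria)
    data.frame(patient_id = st$patient_id, variant_id = st$variant_id,
               ase_positive = st$ase_positive, culture_day = st$culture_day,
               qad = st$qad, t(as.data.frame(st$flags)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Subdivide clusters by ASE fraction
#'
#' Per-cluster size, ASE-positive count and fraction, and the majority flag
#' (fraction >= 0.5, boundary inclusive).
#'
#' @param labels cluster labels (factor levels define the cluster domain).
#' @param ase_flags logical vector aligned with `labels`.
#' @return data frame of class `cluster_composition`: `cluster`, `size`,
#'   `n_ase_pos`, `frac_ase_pos`, `majority`.
#' @export
subdivide_clusters <- function(labels, ase_flags) {
  if (length(labels) != length(ase_flags)) stopf("labels and flags differ in length")
  ids <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  sizes <- table(factor(labels, levels = ids))
  if (any(sizes == 0L))
    stopf("empty cluster id(s) in labels domain: %s",
          paste(names(sizes)[sizes == 0L], collapse = ", "))
  npos <- vapply(ids, function(c) sum(ase_flags[labels == c]), 0)
  out <- data.frame(cluster = ids, size = as.numeric(sizes),
                    n_ase_pos = npos, frac_ase_pos = npos / as.numeric(sizes),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$majority <- out$frac_ase_pos >= 0.5
  class(out) <- c("cluster_composition", "data.frame")
  out
}

#' Majority/minority block composition summary
#'
#' For the ASE-majority and ASE-minority blocks: share of the cohort,
#' within-block ASE-positive fraction, and share of all ASE-positive
#' patients. Percentages are rounded to one decimal.
#'
#' @param comp a [subdivide_clusters()] result.
#' @param total_ase_pos total ASE-positive count in the cohort (must be at
#'   least the majority-block ASE count).
#' @return data frame with rows `majority` and `minority` and columns
#'   `n_clusters`, `n_patients`, `n_ase_pos`, `cohort_share_pct`,
#'   `within_block_ase_pct`, `ase_share_pct`.
#' @export
composition_summary <- function(comp, total_ase_pos) {
  n <- sum(comp$size)
  blocks <- split(comp, ifelse(comp$majority, "majority", "minority"))
  if (total_ase_pos < sum(comp$n_ase_pos[comp$majority]))
    stopf("total_ase_pos below the majority-block ASE count")
  if (total_ase_pos == 0) warnf("total_ase_pos is 0; shares reported as 0")
  row <- function(block) {
    if (is.null(block))
      return(data.frame(n_clusters = 0, n_patients = 0, n_ase_pos = 0,
                        cohort_share_pct = 0, within_block_ase_pct = 0,
                        ase_share_pct = 0))
    np <- sum(block$size); na <- sum(block$n_ase_pos)
    data.frame(n_clusters = nrow(block), n_patients = np, n_ase_pos = na,
               cohort_share_pct = pct1(np, n),
               within_block_ase_pct = if (np > 0) pct1(na, np) else 0,
               ase_share_pct = if (total_ase_pos > 0)
                 pct1(na, total_ase_pos) else 0)
  }
  out <- rbind(majority = row(blocks$majority), minority = row(blocks$minority))
  out
}

#' Reclassification of ASE-negative patients under liberalized variants
#'
#' For each criteria variant, the count and percentage (one decimal,
#' denominator = number of input patients) of default-ASE-negative patients
#' who are positive under that variant.
#'
#' @param encounters encounter rows of the ASE-negative patients of interest
#'   (typically the ASE-negative members of the ASE-majority clusters).
#' @param events event table (all patients; filtered internally).
#' @param variants named list of [ase_criteria()] (default
#'   [liberalized_variants()]).
#' @return data frame: `variant`, `n_positive`, `pct_positive`.
#' @export
reclassify_liberalized <- function(encounters, events,
                                   variants = liberalized_variants()) {
  if (!length(variants))
    return(data.frame(variant = character(), n_positive = integer(),
                      pct_positive = numeric(), stringsAsFactors = FALSE))
  denom <- nrow(encounters)
  events <- events[events$patient_id %in% encounters$patient_id, , drop = FALSE]
  rows <- lapply(names(variants), function(vn) {
    res <- ase_assess(encounters, events, variants[[vn]])
    np <- sum(res$ase_positive)
    data.frame(variant = vn, n_positive = np,
               pct_positive = if (denom > 0) pct1(np, denom) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standardized difference between two groups
#'
#' Continuous: `d = (m2 - m1) / sqrt((s1^2 + s2^2) / 2)`. Binary:
#' `d = (p2 - p1) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`. The effect class
#' follows the conventional cuts on `|d|`: negligible (<= 0.2), small
#' (<= 0.4), medium (<= 0.8), large (> 0.8).
#'
#' @param group1,group2 for `kind = "continuous"`: lists with `mean` and
#'   `sd`; for `kind = "binary"`: lists with `p` (or `x` and `n`).
#' @param kind `"continuous"` or `"binary"`.
#' @return list with `d` and `class`.
#' @export
standardized_difference <- function(group1, group2,
                                    kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  prop <- function(g) if (!is.null(g$p)) g$p else g$x / g$n
  if (kind == "binary") {
    p1 <- prop(group1); p2 <- prop(group2)
    pooled <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    if (pooled == 0) stopf("zero pooled SD")
    d <- (p2 - p1) / pooled
  } else {
    pooled <- sqrt((group1$sd^2 + group2$sd^2) / 2)
    if (pooled == 0) stopf("zero pooled SD")
    d <- (group2$mean - group1$mean) / pooled
  }
  cls <- if (abs(d) <= 0.2) "negligible" else if (abs(d) <= 0.4) "small"
         else if (abs(d) <= 0.8) "medium" else "large"
  list(d = d, class = cls)
}
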