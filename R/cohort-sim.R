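#' Configuration for a synthetic ICU cohort
#'
#' Defines the generative model for a synthetic cohort of ICU
#' hospitalizations: a latent Gaussian/Bernoulli mixture over patient-level
#' features with planted cluster structure, an outlier contamination
#' component, and sepsis-relevant event patterns (blood cultures,
#' antimicrobial runs, organ-dysfunction lab excursions) wired to a subset of
#' "septic" clusters so that downstream Adult Sepsis Event (ASE) analysis has
#' known ground truth.
#'
#' Septic-cluster patients fall into one of three severity strata:
#' with probability `p_sev` they receive an event pattern crossing the
#' default ASE thresholds ("severe"); otherwise, with conditional probability
#' `p_mild`, they receive a "near-miss" pattern landing strictly between the
#' liberalized and default thresholds (sub-threshold lactate and creatinine
#' excursions, a 3-day antimicrobial run); the remainder receive a culture
#' and a 2-day antimicrobial run that fails even the liberalized criteria.
#'
#' @param n_patients number of hospitalizations to simulate.
#' @param k_true number of latent clusters.
#' @param mix mixing proportions over clusters; must sum to 1.
#' @param n_cont,n_bin number of latent continuous / binary features.
#' @param separation cluster-mean spread in SD units: per-feature cluster
#'   means are drawn `Normal(0, separation^2)` while within-cluster SD is 1.
#' @param contamination fraction of patients drawn from an inflated-variance
#'   outlier component (`Normal(mu_c, 25 I)`).
#' @param septic_clusters integer ids of clusters whose members carry
#'   sepsis-like event patterns.
#' @param p_sev probability a septic-cluster patient crosses default ASE
#'   thresholds.
#' @param p_mild conditional probability (given not severe) of a sub-threshold
#'   "near-miss" pattern.
#' @param missing_rates named numeric vector of per-lab missingness
#'   fractions applied to lab events (rows deleted at random).
#' @param seed integer seed for patient-level sampling; the generator is
#'   fully deterministic given the config.
#' @param population_seed integer seed for the population-level parameters
#'   (cluster means, Bernoulli probabilities, diagnosis mixtures). Two
#'   cohorts generated with different `seed` but the same `population_seed`
#'   are independent samples of the same population — the
#'   development/validation design.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_patients = 600L,
                          k_true = 4L,
                          mix = NULL,
                          n_cont = 12L,
                          n_bin = 6L,
                          separation = 5,
                          contamination = 0.02,
                          septic_clusters = 1L,
                          p_sev = 0.9,
                          p_mild = 0.7,
                          missing_rates = c(lactate = 0.403, egfr = 0.10,
                                            bilirubin = 0.08, creatinine = 0.05,
                                            platelets = 0.03),
                          seed = 1L,
                          population_seed = 2015L) {
  if (is.null(mix)) {
    # Default: septic cluster holds 21.5% of patients (development-cohort
    # ASE-prevalence scale), remainder split evenly.
    mix <- c(0.215, rep((1 - 0.215) / (k_true - 1), k_true - 1))
    if (k_true == 1L) mix <- 1
  }
  cfg <- list(n_patients = as.integer(n_patients), k_true = as.integer(k_true),
              mix = as.numeric(mix), n_cont = as.integer(n_cont),
              n_bin = as.integer(n_bin), separation = separation,
              contamination = contamination,
              septic_clusters = as.integer(septic_clusters),
              p_sev = p_sev, p_mild = p_mild,
              missing_rates = missing_rates, seed = as.integer(seed),
              population_seed = as.integer(population_seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (abs(sum(cfg$mix) - 1) > 1e-9) stopf("mix must sum to 1")
  if (length(cfg$mix) != cfg$k_true) stopf("mix must have k_true entries")
  for (f in c("contamination", "p_sev", "p_mild")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stopf("%s must lie in [0, 1]", f)
  }
  if (length(cfg$missing_rates) &&
      (any(cfg$missing_rates < 0) || any(cfg$missing_rates > 1)))
    stopf("missing_rates must lie in [0, 1]")
  if (!all(cfg$septic_clusters %in% seq_len(cfg$k_true)))
    stopf("septic_clusters must be a subset of 1..k_true")
  if (cfg$n_patients > 0 && cfg$n_patients < cfg$k_true)
    stopf("invalid config: n_patients (%d) < k_true (%d)",
          cfg$n_patients, cfg$k_true)
  invisible(cfg)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a [cohort_config()] object.
#' @export
cohort_config_from_file <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(lst$missing_rates)) lst$missing_rates <- unlist(lst$missing_rates)
  do.call(cohort_config, lst)
}

# Baseline reference values for the simulated lab panel (units in comments).
lab_reference <- function() {
  c(lactate = 1.0,      # mmol/L
    creatinine = 70,    # umol/L
    bilirubin = 10,     # umol/L
    platelets = 250,    # 10^9/L
    egfr = 90,          # mL/min/1.73m2
    sodium = 140,       # mmol/L
    wbc = 8)            # 10^9/L
}

#' Generate a synthetic ICU cohort
#'
#' Draws a cohort of hospitalizations from the generative model described in
#' [cohort_config()]: an encounter table (one row per hospitalization), a
#' long-format day-stamped event table (labs, antimicrobial days, blood
#' cultures, ventilation and vasopressor days), and a ground-truth table with
#' the latent cluster, septic flag, and outlier flag of every patient.
#'
#' All events are stamped with 1-based integer hospital days. Lab
#' trajectories are piecewise-constant baselines (sampled near normal
#' reference ranges with < 7% day-to-day jitter, so incidental
#' ratio-to-baseline changes never cross even the liberalized criteria) plus
#' a single scripted excursion window for septic-cluster patients.
#'
#' @param config a [cohort_config()].
#' @return a list of class `sepsis_cohort` with elements `encounters`,
#'   `events`, `truth` (data frames) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 1))
#' head(coh$encounters)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  if (n == 0L) return(empty_cohort(config))
  k <- config$k_true

  # Population-level structure is drawn under its own seed so that cohorts
  # sampled with different `seed` share the same latent clusters.
  set.seed(config$population_seed %||% 2015L)
  mu <- matrix(rnorm(k * config$n_cont, 0, config$separation), k, config$n_cont)
  pb <- if (config$n_bin > 0L)
    matrix(runif(k * config$n_bin, 0.1, 0.9), k, config$n_bin) else NULL
  cmb_names <- c("cmb_chf", "cmb_copd", "cmb_diabetes", "cmb_renal", "cmb_cancer")
  pcmb <- matrix(runif(k * length(cmb_names), 0.05, 0.4), k, length(cmb_names))
  chapters <- c("circulatory", "respiratory", "infectious", "digestive", "injury")
  dxp <- matrix(runif(k * 5, 0.2, 1), k, 5)
  dxp[config$septic_clusters, 3] <- dxp[config$septic_clusters, 3] + 2  # infectious-heavy
  dxp <- dxp / rowSums(dxp)

  set.seed(config$seed)
  pid <- sprintf("P%05d", seq_len(n))
  cl <- sample.int(k, n, replace = TRUE, prob = config$mix)
  outlier <- runif(n) < config$contamination
  septic <- cl %in% config$septic_clusters

  # Latent continuous block: per-cluster means ~ N(0, delta^2), unit noise;
  # outliers use an inflated-variance component with the same means.
  xc <- mu[cl, , drop = FALSE] +
    matrix(rnorm(n * config$n_cont), n, config$n_cont) *
    ifelse(outlier, 5, 1)
  colnames(xc) <- sprintf("feat_c%02d", seq_len(config$n_cont))

  # Latent binary block: per-cluster Bernoulli probabilities.
  xb <- NULL
  if (config$n_bin > 0L) {
    xb <- matrix(rbinom(n * config$n_bin, 1L, pb[cl, , drop = FALSE]),
                 n, config$n_bin)
    colnames(xb) <- sprintf("feat_b%02d", seq_len(config$n_bin))
  }

  # Encounter-level demographics and outcomes (Table-1-like marginals).
  age <- pmin(pmax(round(rnorm(n, 62, 15)), 18), 100)
  sex <- ifelse(runif(n) < 0.36, "F", "M")
  admit_via_ed <- as.integer(runif(n) < 0.66)
  icu_los <- 1L + rpois(n, 2)
  hosp_los <- icu_los + rpois(n, 5)
  hosp_los[septic] <- pmax(hosp_los[septic], 8L)
  icu_los <- pmin(icu_los, hosp_los)
  died <- runif(n) < ifelse(septic, 0.30, 0.08)
  discharged_alive_day <- ifelse(died, NA_integer_, hosp_los)

  cmb <- matrix(rbinom(n * length(cmb_names), 1L, pcmb[cl, , drop = FALSE]),
                n, length(cmb_names), dimnames = list(NULL, cmb_names))

  dx_chapter <- vapply(seq_len(n), function(i)
    sample(chapters, 1L, prob = dxp[cl[i], ]), character(1))

  encounters <- data.frame(patient_id = pid, age = age, sex = sex,
                           admit_via_ed = admit_via_ed, icu_los = icu_los,
                           hosp_los = hosp_los, died = as.integer(died),
                           discharged_alive_day = discharged_alive_day,
                           dx_chapter = dx_chapter,
                           stringsAsFactors = FALSE)
  encounters <- cbind(encounters, as.data.frame(cmb), as.data.frame(xc))
  if (!is.null(xb)) encounters <- cbind(encounters, as.data.frame(xb))

  # Severity stratum for septic-cluster patients.
  u <- runif(n)
  stratum <- rep("none", n)
  stratum[septic & u < config$p_sev] <- "severe"
  mild_draw <- runif(n)
  stratum[septic & stratum == "none" & mild_draw < config$p_mild] <- "mild"
  stratum[septic & stratum == "none"] <- "plain"
  stratum[!septic] <- "none"

  events <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_patient_events(pid[i], hosp_los[i], stratum[i])))
  rownames(events) <- NULL

  truth <- data.frame(patient_id = pid, true_cluster = cl,
                      true_septic = septic, is_outlier = outlier,
                      stringsAsFactors = FALSE)

  if (length(config$missing_rates))
    events <- inject_missingness(events, config$missing_rates,
                                 seed = derive_seed(config$seed, 99L))

  structure(list(encounters = encounters, events = events, truth = truth,
                 config = config), class = "sepsis_cohort")
}

empty_cohort <- function(config) {
  enc <- data.frame(patient_id = character(), age = numeric(),
                    sex = character(), admit_via_ed = integer(),
                    icu_los = integer(), hosp_los = integer(),
                    died = integer(), discharged_alive_day = integer(),
                    dx_chapter = character(), stringsAsFactors = FALSE)
  ev <- data.frame(patient_id = character(), day = integer(),
                   event_type = character(), name = character(),
                   value = numeric(), stringsAsFactors = FALSE)
  tr <- data.frame(patient_id = character(), true_cluster = integer(),
                   true_septic = logical(), is_outlier = logical(),
                   stringsAsFactors = FALSE)
  structure(list(encounters = enc, events = ev, truth = tr, config = config),
            class = "sepsis_cohort")
}

# One patient's event stream. Baseline labs on days 1..min(los, 5); septic
# strata add a culture day, an antimicrobial run and a scripted excursion.
simulate_patient_events <- function(pid, los, stratum) {
  ref <- lab_reference()
  lab_days <- seq_len(min(los, 5L))
  base <- ref * runif(length(ref), 0.9, 1.1)
  ev <- do.call(rbind, lapply(names(ref), function(nm)
    data.frame(patient_id = pid, day = lab_days, event_type = "lab", name = nm,
               value = round(base[nm] * runif(length(lab_days), 0.97, 1.03), 2),
               stringsAsFactors = FALSE)))

  add <- function(day, type, name, value = NA_real_)
    data.frame(patient_id = pid, day = as.integer(day), event_type = type,
               name = name, value = value, stringsAsFactors = FALSE)

  if (stratum %in% c("severe", "mild", "plain")) {
    cd <- 3L
    ev <- rbind(ev, add(cd, "blood_culture", "blood_culture"))
    if (stratum == "severe") {
      ev <- rbind(ev,
        add(cd:(cd + 4L), "antimicrobial", "antimicrobial"),
        add(cd + 1L, "vasopressor", "vasopressor"),
        add(cd + 1L, "lab", "lactate", round(3.5 * runif(1, 1.0, 1.3), 2)),
        add(cd + 1L, "lab", "creatinine",
            round(base["creatinine"] * runif(1, 2.2, 3.0), 1)))
      if (runif(1) < 0.6)
        ev <- rbind(ev, add(cd:(cd + 2L), "vent", "vent"))
    } else if (stratum == "mild") {
      # Near-miss: lands strictly between liberalized and default thresholds.
      ev <- rbind(ev,
        add(cd:(cd + 2L), "antimicrobial", "antimicrobial"),
        add(cd + 1L, "lab", "lactate", round(runif(1, 1.60, 1.95), 2)),
        add(cd + 1L, "lab", "creatinine",
            round(base["creatinine"] * runif(1, 1.55, 1.90), 1)))
    } else {
      ev <- rbind(ev, add(cd:(cd + 1L), "antimicrobial", "antimicrobial"))
    }
  } else {
    if (runif(1) < 0.3) {
      st <- sample.int(max(los - 1L, 1L), 1L)
      ev <- rbind(ev, add(st:min(st + sample.int(2L, 1L), los),
                          "antimicrobial", "antimicrobial"))
    }
    if (runif(1) < 0.15) ev <- rbind(ev, add(1:2, "vent", "vent"))
    if (runif(1) < 0.05) ev <- rbind(ev, add(1L, "vasopressor", "vasopressor"))
  }
  ev$day <- pmin(ev$day, los)
  # scripted excursions are appended after the baseline series and must win
  # same-day collisions, so keep the last occurrence
  ev <- ev[!duplicated(ev[c("day", "event_type", "name")], fromLast = TRUE), ]
  rownames(ev) <- NULL
  ev
}

#' Randomly delete lab values to emulate missingness
#'
#' Each lab event row whose `name` appears in `rates` is deleted
#' independently with the given probability. Non-lab events are untouched.
#'
#' @param events an event table.
#' @param rates named numeric vector of per-lab deletion probabilities.
#' @param seed integer seed; output is reproducible given the seed.
#' @return the thinned event table.
#' @export
inject_missingness <- function(events, rates, seed = 1L) {
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  known <- unique(events$name[events$event_type == "lab"])
  unknown <- setdiff(names(rates), known)
  if (length(unknown))
    warnf("ignoring missingness rates for unknown lab names: %s",
          paste(unknown, collapse = ", "))
  rates <- rates[names(rates) %in% known]
  if (!length(rates)) return(events)
  set.seed(as.integer(seed))
  drop <- rep(FALSE, nrow(events))
  for (nm in names(rates)) {
    idx <- which(events$event_type == "lab" & events$name == nm)
    drop[idx] <- runif(length(idx)) < rates[[nm]]
  }
  out <- events[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort: %d patients, %d events, k_true = %d\n",
              nrow(x$encounters), nrow(x$events), x$config$k_true))
  cat(sprintf("  septic clusters: %s; outliers: %d\n",
              paste(x$config$septic_clusters, collapse = ","),
              sum(x$truth$is_outlier)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `encounters.csv`, `events.csv` and `truth.csv` (RFC-4180, UTF-8,
#' header row) into `dir`.
#'
#' @param cohort a `sepsis_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$encounters, file.path(dir, "encounters.csv"), row.names = FALSE)
  write.csv(cohort$events, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing the three CSV files.
#' @return a `sepsis_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  structure(list(
    encounters = read.csv(file.path(dir, "encounters.csv"), stringsAsFactors = FALSE),
    events = read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE),
    truth = read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE),
    config = NULL), class = "sepsis_cohort")
}
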