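# Adult Sepsis Event engine: QAD, organ dysfunction, variants, composition,
# standardized differences.

ev_row <- function(pid, day, type, name = type, value = NA_real_)
  data.frame(patient_id = pid, day = as.integer(day), event_type = type,
             name = name, value = value, stringsAsFactors = FALSE)

lab_row <- function(pid, day, name, value) ev_row(pid, day, "lab", name, value)

test_that("QAD counts the longest eligible consecutive run", {
  abx <- ev_row("A", 3:7, "antimicrobial")
  crit <- ase_criteria()
  expect_equal(qualifying_antimicrobial_days(abx, 3, crit)$qad, 5)
  expect_true(qualifying_antimicrobial_days(abx, 3, crit)$qualifies)
  # 3-day run fails the default but passes the liberalized min_qad = 3
  abx3 <- ev_row("A", 3:5, "antimicrobial")
  expect_false(qualifying_antimicrobial_days(abx3, 3, crit)$qualifies)
  expect_equal(qualifying_antimicrobial_days(abx3, 3, crit)$qad, 3)
  expect_true(qualifying_antimicrobial_days(abx3, 3, liberalized_variants()$h)$qualifies)
  # gap breaks the run
  gap <- ev_row("A", c(3, 4, 6, 7), "antimicrobial")
  expect_equal(qualifying_antimicrobial_days(gap, 3, crit)$qad, 2)
  # run starting outside the window is ineligible
  late <- ev_row("A", 7:12, "antimicrobial")
  expect_equal(qualifying_antimicrobial_days(late, 3, crit)$qad, 0)
  # no antimicrobials at all
  none <- ev_row("A", 1, "lab", "lactate", 1)
  expect_equal(qualifying_antimicrobial_days(none, 3, crit)$qad, 0)
})

test_that("a short run extending to discharge alive qualifies under the rule", {
  abx <- ev_row("A", 3:4, "antimicrobial")
  crit_i <- liberalized_variants()$i
  expect_true(qualifying_antimicrobial_days(abx, 3, crit_i,
                                            discharged_alive_day = 4)$qualifies)
  expect_false(qualifying_antimicrobial_days(abx, 3, crit_i,
                                             discharged_alive_day = 9)$qualifies)
  expect_false(qualifying_antimicrobial_days(abx, 3, ase_criteria(),
                                             discharged_alive_day = 4)$qualifies)
})

test_that("organ dysfunction thresholds follow default vs liberalized cuts", {
  crit <- ase_criteria()
  lib <- liberalized_variants()
  # creatinine ratio 1.8: renal false at 2.0, true at 1.5
  ev <- rbind(lab_row("A", 1, "creatinine", 70), lab_row("A", 4, "creatinine", 126))
  expect_false(organ_dysfunction_flags(ev, 3, crit)[["renal"]])
  expect_true(organ_dysfunction_flags(ev, 3, lib$a)[["renal"]])
  # bilirubin peak 30 with 3x rise: liver false at 34.2, true at 25.7
  ev <- rbind(lab_row("A", 1, "bilirubin", 10), lab_row("A", 4, "bilirubin", 30))
  expect_false(organ_dysfunction_flags(ev, 3, crit)[["liver"]])
  expect_true(organ_dysfunction_flags(ev, 3, lib$b)[["liver"]])
  # lactate 1.8: false at 2.0, true at 1.5 (strict >)
  ev <- lab_row("A", 4, "lactate", 1.8)
  expect_false(organ_dysfunction_flags(ev, 3, crit)[["lactate"]])
  expect_true(organ_dysfunction_flags(ev, 3, lib$c)[["lactate"]])
  expect_false(organ_dysfunction_flags(lab_row("A", 4, "lactate", 1.5), 3,
                                       lib$c)[["lactate"]])
  # platelets 120 -> 60: hematologic true at default; 200 -> 130 only under d
  ev <- rbind(lab_row("A", 1, "platelets", 150), lab_row("A", 4, "platelets", 60))
  expect_true(organ_dysfunction_flags(ev, 3, crit)[["hematologic"]])
  ev2 <- rbind(lab_row("A", 1, "platelets", 200), lab_row("A", 4, "platelets", 130))
  expect_false(organ_dysfunction_flags(ev2, 3, crit)[["hematologic"]])
  expect_true(organ_dysfunction_flags(ev2, 3, lib$d)[["hematologic"]])
  # vent and vasopressor days inside/outside the window
  expect_true(organ_dysfunction_flags(ev_row("A", 5, "vent"), 3, crit)[["respiratory"]])
  expect_false(organ_dysfunction_flags(ev_row("A", 6, "vent"), 3, crit)[["respiratory"]])
  expect_true(organ_dysfunction_flags(ev_row("A", 2, "vasopressor"), 3, crit)[["cardiac"]])
  expect_warning(organ_dysfunction_flags(lab_row("A", 3, "troponin", 5), 3, crit),
                 "unknown lab")
})

test_that("ase_status requires culture + QAD + in-window dysfunction together", {
  enc <- data.frame(patient_id = "A", hosp_los = 10L, died = 0L,
                    discharged_alive_day = 10L, stringsAsFactors = FALSE)
  ev <- rbind(ev_row("A", 3, "blood_culture"),
              ev_row("A", 3:7, "antimicrobial"),
              lab_row("A", 4, "lactate", 3.5))
  st <- ase_status(enc, ev, ase_criteria())
  expect_true(st$ase_positive)
  expect_equal(st$qad, 5)
  expect_equal(st$culture_day, 3)
  expect_true(st$flags[["lactate"]])
  expect_false(any(st$flags[setdiff(names(st$flags), "lactate")]))
  # no culture: negative with empty flags
  st0 <- ase_status(enc, ev[-1, ], ase_criteria())
  expect_false(st0$ase_positive)
  expect_false(any(st0$flags))
  # window boundary: dysfunction on culture day + 3
  ev3 <- rbind(ev_row("A", 3, "blood_culture"), ev_row("A", 3:7, "antimicrobial"),
               lab_row("A", 6, "lactate", 3.5))
  expect_false(ase_status(enc, ev3, ase_criteria())$ase_positive)
  expect_true(ase_status(enc, ev3, liberalized_variants()$f)$ase_positive)
  # day + 4 requires the 4-day window
  ev4 <- rbind(ev_row("A", 3, "blood_culture"), ev_row("A", 3:7, "antimicrobial"),
               lab_row("A", 7, "lactate", 3.5))
  expect_false(ase_status(enc, ev4, liberalized_variants()$f)$ase_positive)
  expect_true(ase_status(enc, ev4, liberalized_variants()$g)$ase_positive)
})

test_that("the variant list matches the ten published liberalizations", {
  v <- liberalized_variants()
  expect_named(v, letters[1:10])
  expect_equal(v$a$creat_ratio_min, 1.5)
  expect_equal(v$a$egfr_decline_min, 0.25)
  expect_equal(v$b$bili_abs_min, 25.7)
  expect_equal(v$c$lactate_min, 1.5)
  expect_equal(v$d$platelet_abs_max, 150)
  expect_equal(v$f$window_days, 3)
  expect_equal(v$g$window_days, 4)
  expect_equal(v$h$min_qad, 3)
  expect_true(v$i$discharge_alive_qad_rule)
  expect_equal(v$j$window_days, 3)
  expect_equal(v$j$min_qad, 3)
  # j has union semantics: positive under c alone implies positive under j
  enc <- data.frame(patient_id = "A", hosp_los = 10L, died = 0L,
                    discharged_alive_day = 10L, stringsAsFactors = FALSE)
  ev <- rbind(ev_row("A", 3, "blood_culture"), ev_row("A", 3:7, "antimicrobial"),
              lab_row("A", 4, "lactate", 1.8))
  expect_false(ase_status(enc, ev, ase_criteria())$ase_positive)
  expect_true(ase_status(enc, ev, v$c)$ase_positive)
  expect_true(ase_status(enc, ev, v$j)$ase_positive)
})

test_that("cluster subdivision and composition conserve counts and boundaries", {
  labels <- factor(rep(c("a", "b"), c(4, 6)))
  flags <- c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6))
  comp <- subdivide_clusters(labels, flags)
  expect_true(comp$majority[comp$cluster == "a"])  # 0.5 boundary is majority
  expect_false(comp$majority[comp$cluster == "b"])
  expect_equal(sum(comp$size), 10)
  expect_equal(sum(comp$n_ase_pos), 2)
  # empty level in the domain is an error
  expect_error(subdivide_clusters(factor(rep("a", 3), levels = c("a", "b")),
                                  rep(TRUE, 3)), "empty cluster")
  # all-negative flags: no majority clusters
  comp0 <- subdivide_clusters(labels, rep(FALSE, 10))
  expect_false(any(comp0$majority))
  expect_warning(summ0 <- composition_summary(comp0, 0), "0")
  expect_equal(summ0["majority", "ase_share_pct"], 0)
  expect_equal(summ0["majority", "n_patients"], 0)
})

test_that("threshold monotonicity and variant nesting hold over random patients", {
  set.seed(77)
  patients <- lapply(1:1000, random_toy_patient)
  variants <- liberalized_variants()
  default <- ase_criteria()
  status <- function(p, crit) ase_status(p$encounter, p$events, crit)$ase_positive
  pos <- sapply(patients, status, crit = default)
  pos_v <- sapply(names(variants), function(vn)
    sapply(patients, status, crit = variants[[vn]]))
  # default positives nest inside every single-threshold liberalization
  for (vn in names(variants)) expect_true(all(pos_v[pos, vn]))
  # every component variant of the combined criteria nests inside it
  for (vn in c("a", "b", "c", "d", "e", "f", "h", "i"))
    expect_true(all(pos_v[pos_v[, vn], "j"]))
  # the liberalizations do add patients on this population
  expect_gt(sum(pos_v[, "j"]), sum(pos))
})

test_that("reclassification reports per-variant counts over the right denominator", {
  set.seed(78)
  patients <- lapply(1:60, random_toy_patient)
  enc <- do.call(rbind, lapply(patients, `[[`, "encounter"))
  ev <- do.call(rbind, lapply(patients, `[[`, "events"))
  base <- ase_assess(enc, ev)
  neg <- enc[!base$ase_positive, , drop = FALSE]
  rep_ <- reclassify_liberalized(neg, ev)
  expect_equal(nrow(rep_), 10)
  expect_true(all(rep_$n_positive <= nrow(neg)))
  expect_equal(rep_$pct_positive, round(100 * rep_$n_positive / nrow(neg), 1))
  # monotone: window 4 captures at least the window-3 reclassifications
  expect_gte(rep_$n_positive[rep_$variant == "g"],
             rep_$n_positive[rep_$variant == "f"])
  empty <- reclassify_liberalized(neg, ev, variants = list())
  expect_equal(nrow(empty), 0)
})

test_that("standardized differences follow the pooled formulas and classes", {
  same <- standardized_difference(list(mean = 5, sd = 2), list(mean = 5, sd = 2))
  expect_equal(same$d, 0)
  expect_equal(same$class, "negligible")
  d_ase <- standardized_difference(list(x = 787, n = 3660),
                                   list(x = 576, n = 3012), kind = "binary")
  expect_equal(round(d_ase$d, 2), -0.06)
  expect_equal(d_ase$class, "negligible")
  d_f <- standardized_difference(list(x = 1315, n = 3660),
                                 list(x = 956, n = 3012), kind = "binary")
  expect_equal(round(abs(d_f$d), 2), 0.09)
  # class boundaries on |d|
  mk <- function(m2) standardized_difference(list(mean = 0, sd = 1),
                                             list(mean = m2, sd = 1))$class
  expect_equal(mk(0.2), "negligible")
  expect_equal(mk(0.3), "small")
  expect_equal(mk(0.7), "medium")
  expect_equal(mk(1.0), "large")
  expect_error(standardized_difference(list(mean = 1, sd = 0),
                                       list(mean = 2, sd = 0)), "zero pooled")
})
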