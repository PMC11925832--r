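---
title: "Methods: unsupervised sepsis phenotyping and the ASE comparator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised sepsis phenotyping and the ASE comparator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sepsis — life-threatening organ dysfunction caused by a dysregulated
response to infection — has no reference-standard case definition.
Surveillance definitions such as the CDC Adult Sepsis Event (ASE) impose
hard thresholds (a 2-fold creatinine rise, lactate above 2 mmol/L, at least
4 qualifying antimicrobial days around a blood culture) on what is really a
continuum, and therefore undercount milder disease. `sepclust` implements
the complementary strategy: cluster ICU hospitalizations on a wide feature
set *without* any sepsis label, then use the ASE definition — at its default
and at liberalized thresholds — purely as a comparator to interpret the
clusters.

This vignette records the modelling choices, their defaults, and what the
package's synthetic experiments do and do not demonstrate.

# The synthetic cohort generator

Real cohorts of this kind cannot be shared, so the package ships a
generative model (`cohort_config()`, `generate_cohort()`) that reproduces
the *statistical structure* the pipeline must cope with:

* **Latent clusters.** Each patient belongs to one of `k_true` clusters
  (default 4). Continuous features are drawn `N(mu_c, I)` with cluster
  means `mu_c ~ N(0, separation^2)`; `separation = 5` SD units makes
  cluster recovery essentially deterministic for a sound algorithm, which
  is the point — failures then indicate implementation defects, not
  statistical bad luck. Binary features are per-cluster Bernoulli draws.
* **Population vs. sample seeds.** Cluster means and probability tables are
  drawn under a `population_seed` (default fixed), patient-level sampling
  under `seed`. Two cohorts with different sampling seeds are therefore
  independent samples of the *same* population — the development/validation
  design of a two-year split of one region. Without this split an external
  membership model would have nothing transferable to learn.
* **Outliers.** A fraction `contamination` (default 2%) of patients draw
  their continuous features with SD 5 instead of 1, leaving cluster means
  untouched: enough for trimmed clustering to detect, without shifting the
  planted geometry.
* **Septic clusters and ASE linkage.** Members of `septic_clusters`
  (default cluster 1, holding 21.5% of patients — the development-cohort
  ASE-prevalence scale) receive a blood-culture day and an antimicrobial
  run. With probability `p_sev` (default 0.9) the pattern crosses the
  default ASE thresholds (5-day antimicrobial run, an in-window vasopressor
  day, lactate ≥ 3.5, a ≥2.2-fold creatinine rise); otherwise, with
  conditional probability `p_mild` (default 0.7), it lands strictly between
  the liberalized and default thresholds (3-day run, lactate in
  (1.6, 1.95), creatinine rise in (1.55, 1.9)) — a "near-miss" patient who
  is ASE-negative by default criteria but positive under the fully
  liberalized variant. The severe pattern includes a vasopressor day
  deliberately: cardiac dysfunction is not a laboratory value, so planted
  severity survives any lab-missingness setting.
* **Lab trajectories.** Piecewise-constant baselines sampled within ±10% of
  normal reference values, with ≤3% day-to-day jitter, plus a single
  scripted excursion window. The jitter bound guarantees that incidental
  ratio-to-baseline changes (max ≈ 1.06-fold) can never cross even the
  liberalized 1.5-fold criteria.
* **Missingness.** Lab rows are deleted independently per lab at the
  configured rates; the default puts 40.3% on the lactate analogue (the
  highest missingness a lab showed in the motivating data) and 3–10% on the
  others.

What the generator does **not** emulate: real covariance between labs and
demographics, pharmacology, time-of-day effects, ICD coding, site effects,
or any clinically realistic cluster shapes. Passing tests on this generator
demonstrates that the pipeline's machinery is correct and that its
statistical contracts hold — not that the pipeline would find clinically
meaningful phenotypes in any particular real cohort.

# Preprocessing

The feature matrix is built in a fixed order: event summaries (per-lab
min/max/SD over time — SD with the n−1 denominator, singletons assigned
SD 0 so the dispersion feature is defined for every observed patient — plus
ventilation/vasopressor indicators and antimicrobial/culture counts),
encounter variables with full dummy encoding of categoricals, then four
filters:

* prevalence: binary columns with mean < 1% are dropped (strict `<`);
* collinearity: for any pair with |Pearson r| > 0.9 on pairwise-complete
  rows, the *later* column in matrix order is dropped, in a single greedy
  pass — the rule is arbitrary but deterministic and order-stable;
  correlations with constant columns are treated as 0;
* mean imputation (a fully missing column is an error);
* standardization of continuous columns with the population (n)
  denominator; binary indicators stay on the 0/1 scale because z-scoring
  them destroys their prevalence interpretation.

Outcome variables (death, any ASE flag) and raw timing variables never
enter the matrix; derived lengths of stay do.

# KMO and PCA

The Kaiser–Meyer–Olkin statistic compares squared correlations to squared
partial correlations computed from the (pseudo-)inverse of the correlation
matrix. Full dummy blocks make that matrix exactly singular, so the SVD
pseudo-inverse path is routine, not exceptional; it is reported once per
filtering run. Filtering is on the **per-variable** MSA (the wording
"variables with KMO < 0.6" implies a per-variable criterion), iteratively:
drop the single worst variable, recompute, repeat until all MSA ≥ 0.6.
Iterative removal is standard MSA practice and protects against one junk
variable dragging its neighbours below the floor. A single-pass mode is
available. The degenerate case R = I returns 0 with a warning (both sums
vanish; 0 is the conservative "PCA unsuitable" answer).

PCA then keeps the smallest number of components whose cumulative explained
variance reaches 95% (`>=`, so exactly 95.0% qualifies). Inputs arrive
standardized, so this is correlation-scale PCA without further scaling.
Eigenvector signs are fixed by forcing each component's largest-magnitude
loading positive, making scores reproducible across linear-algebra
backends.

# Robust and Sparse K-means

`rskc()` alternates (i) trimmed K-means under weighted squared distance,
excluding the `ceil(alpha n)` worst-fitting cases (`O_W`), (ii) unweighted
re-trimming (`O_E`), and (iii) a weight update `w = S(b, Δ)/‖S(b, Δ)‖₂`
where `b` is the per-feature between-cluster sum of squares on untrimmed
cases and `Δ` is the smallest soft-threshold (binary search) satisfying
`‖w‖₁ ≤ s`. Numerical conventions worth recording:

* **No-sparsity regime.** When `s ≥ √p` the L1 constraint cannot bind and
  weights are held uniform at `1/√p`; with `alpha = 0` the procedure is
  then *exactly* Lloyd K-means, which the tests verify against an
  independent Lloyd implementation from shared initializations. (The
  literal update would give weights proportional to `b`, silently changing
  the metric between iterations even when no sparsity was requested.)
* **Restart selection.** Restarts are compared on the robust criterion —
  weighted within-cluster SS over untrimmed cases — rather than on the
  weighted between-cluster objective, which explodes for degenerate
  solutions that park a center on an untrimmed gross outlier. The
  between-cluster objective is still computed, traced per iteration (it is
  non-decreasing for fixed trimmed sets), and reported.
* **Seeding.** k-means++ under the current weights, with the `ceil(alpha n)`
  currently-farthest rows excluded from the seeding pool so presumed
  outliers cannot become initial centers. Default `n_init = 10`; planted
  substructure (e.g. severity strata inside a septic cluster) creates real
  local optima that fewer restarts can fall into.
* **Empty clusters** are repaired by re-seeding the farthest untrimmed case.
* Final labels assign *every* case, trimmed ones included, to the nearest
  weighted center; `O_W`/`O_E` are reported separately.

# Algorithm bench and elbow

`run_algorithm()` gives every algorithm the same contract: exactly `k`
non-empty clusters when feasible, deterministic given the seed. GMM uses
`mclust` (spherical `EII` by default for speed and stability in ~50
dimensions; assignment by maximum posterior), CLARA uses `cluster::clara`
(PAM on ≤5 subsamples of size 40 + 2k), SOM is a small online map on a
square grid of ≥ 4k units whose codebook is then grouped into `k` by
K-means, mini-batch K-means uses per-center learning-rate counts, weighted
K-means takes fixed user weights. A deep-clustering auto-encoder is not in
the default registry — it needs a deep-learning stack and offline training —
but the `registry` argument accepts any plug-in with the same signature.

The elbow detector min-max normalizes both axes of the WCSS-vs-k curve and
takes the point of maximum perpendicular distance to the chord joining the
endpoints; ties, including exactly linear curves (warned), resolve to the
smallest k. The cluster count is always a data outcome — nothing in the
package hard-codes a "right" k.

# Evaluation and stability

The five internal metrics are implemented directly from their definitions
and checked in the tests against closed forms on a 1-D fixture
({0, 0.1, 10, 10.1}: silhouette 0.990, Davies–Bouldin 0.01,
Calinski–Harabasz 20000) and against independent oracles
(`cluster::silhouette`, brute-force pair counting for ARI, direct entropy
formulas for NMI). Conventions: silhouette of a singleton is 0; identical
centroids are an error for Davies–Bouldin; zero within-cluster dispersion
returns +Inf with a warning for Calinski–Harabasz; NMI uses the geometric
mean normalization (arithmetic switchable) and defines 0/0 as 1.

Rank aggregation is direction-aware (higher-better: silhouette, CH,
Shannon; lower-better: DB, Gini), with average ranks on ties and the final
ordering by rank sum, ties broken alphabetically and flagged. Published
rank tables in this literature are not always internally consistent with
their own rank sums; this package follows the rank sum strictly and only
treats the top-two identification as reproducible.

Stability: B subsamples of 80% without replacement; R runs per subsample
under distinct derived seeds; agreement per subsample is the mean pairwise
ARI (and NMI) over at most `pair_budget` (default 200) random run pairs —
R(R−1)/2 pairs at the full protocol (200 subsamples × 100 runs) would be
~5000 comparisons per subsample, and a capped random sample of pairs
estimates the same mean. The coefficient of variation of the per-subsample
agreements is the stability score. Desk-scale defaults are B = 20–50,
R = 10–20; the full protocol is reachable through the same arguments.

# External assignment

The membership model is a softmax XGBoost on the post-KMO *variables* (not
PCA scores — scores are clustering-only, and a variable-space model is
reusable on new data). Hyperparameters (log-uniform learning rate 0.02–0.3,
depth 2–8, row/column subsampling 0.5–1, 30–200 rounds) maximize k-fold CV
accuracy (default 5 folds, capped at the smallest class) within a `budget`
of evaluations using a small sequential model-based optimizer: a random
initial design of about a third of the budget, then proposals chosen by a
random-forest surrogate over a random candidate pool. Pure random search is
available; `budget = 1` fits documented defaults with no tuning. `nthread`
is pinned to 1 for bit-reproducibility.

Attributions use the exact tree-path decomposition (`predcontrib`), whose
additivity (baseline + attributions = class margin, tolerance 1e-4) is
asserted rather than assumed. Cohort comparison reports the Pearson
correlation of per-cluster ASE-positive fractions and variable-wise
standardized differences; the binary formula is
`(p2 − p1)/√((p1(1−p1) + p2(1−p2))/2)` with effect classes at |d| ≤ 0.2 /
0.4 / 0.8. Published tables of such differences do not use a consistent
sign convention, so magnitudes are the comparable quantity.

# The ASE engine

All thresholds live in one `ase_criteria()` object; the ten liberalized
variants a–j are expressed as such objects. Conventions:

* windows are inclusive integer-day intervals (±2 days by default);
* QAD requires consecutive calendar days; gaps break the run; a run is
  eligible if its first day lies within the window of the culture; with the
  discharge rule on, an eligible run extending to the day of leaving
  hospital alive qualifies regardless of length;
* baselines are encounter extrema (minimum creatinine/bilirubin, maximum
  platelets/eGFR), a deliberate simplification of look-back windows to the
  encounter;
* lactate uses strict `>` (its liberalization is printed with `>`); the
  absolute/ratio criteria quoted with `≥` use `≥`;
* the platelet criterion's qualifying-baseline floor is a separate
  parameter (`platelet_baseline_min`, fixed at 100 across variants): tying
  it to the liberalized `< 150` threshold would make the liberalized
  variant *miss* patients the default catches, violating the monotonicity
  that the variant design and its published counts imply;
* the combined variant j relaxes a, b, c, d plus the 3-day window, 3-day
  QAD and the discharge rule — it does not include the 4-day window
  (variant g), so g is the one variant not nested within j.

Monotonicity (relaxing any single threshold never turns a positive into a
negative) and variant nesting are asserted over 1,000 randomized toy
patients in the test suite.

Reported percentages round to one decimal, matching the convention of the
tables they reproduce.

# Problem sizes

The shipped experiments use cohorts of 250–2,000 patients, elbow scans over
k = 2–10, stability at B = 20 × R = 10, and tuning budgets of 1–5
evaluations — sizes chosen so the whole suite and the acceptance script
each run in minutes on a single core while leaving every statistical
conclusion (recovery ARIs, stability CVs, nesting properties) far from
their thresholds. Every scale is a config argument, and the full-scale
protocol (k to 120, B = 200 × R = 100) is reachable without code changes.

# Known limitations

* The generator's clusters are axis-aligned Gaussians/Bernoullis; none of
  the algorithms is stressed by elongated, nested or manifold-shaped
  clusters.
* Mean imputation and pairwise-complete correlations are the only
  missing-data strategies, matching the pipeline being modelled; multiple
  imputation is out of scope.
* eGFR is consumed as a supplied lab series; no creatinine-based equation
  is applied.
* The ASE engine operates at day granularity; clock-time phenomena
  (same-day sequences) are invisible to it.
* Hierarchical methods, HDBSCAN, latent class analysis and ensemble
  clustering are deliberately absent from the bench.
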