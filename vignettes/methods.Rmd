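---
title: "Methods: benchmarking OGTT-based predictors of type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking OGTT-based predictors of type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttbench)
```

# The scientific problem

A 75-g oral glucose tolerance test yields plasma glucose (PG) and serum
insulin at 0, 30, 60 and 120 minutes. The 1-hour post-load glucose is a
strong single predictor of future type 2 diabetes; serum metabolites
(mannose, α-hydroxybutyrate, bradykinin-hydroxyproline, α-tocopherol,
10:1 carnitine, and the unidentified X-12063), HbA1c and the classic
clinical risk factors (age, sex, BMI, family history) each add candidate
information. The benchmark this package implements asks, exhaustively
rather than anecdotally, which *combinations* of these markers predict
progression better than 1-h PG alone, with multiplicity honestly accounted
for.

# The pipeline

## Candidate models

A candidate model is a set of markers. Models are generated by families:
a fixed base, plus pools of combinatorial *units* from which between `min`
and `max` units are drawn. Two conventions matter:

* the clinical risk factors are one atomic four-variable unit, never
  partially included — the published family sizes (e.g. 252) only arise
  under this convention, and clinically the block travels together;
* sets are canonically ordered and deduplicated across families, so a
  model reachable through several families is evaluated once, with merged
  provenance.

The shipped default grid (`default_model_grid()`) covers the named
families — glucose combinations, glucose + clinical factors, HbA1c
combinations, metabolite subsets, each glucose time point × metabolite
subsets × {±HbA1c} × {±clinical}, insulin singles and pairs — and
enumerates 1343 unique sets. The historical benchmark reports 1527 models,
but its exact family composition lives in supplementary tables that are
not reproducible from the main text; the grid is therefore configuration,
documents its own total, and makes no claim to reconstruct 1527.

## Classifier and cross-validation

Each model is a regularized least-squares (RLS) classifier: ridge
regression on a ±1-coded outcome with an unpenalized intercept. On centred
features the solution is closed-form, and one eigendecomposition of the
Gram matrix serves the entire penalty grid — the efficiency that makes
hundreds of models × 100 repetitions feasible on one CPU.

Scores come from repeated nested cross-validation:

* **outer folds** (default 10, stratified by outcome) give out-of-fold
  scores;
* **inner folds** (default 10, stratified, within each outer training set)
  select λ from the grid `2^(-10..10)` by maximizing the pooled inner
  out-of-fold AUC. The inner selection criterion is not pinned down by the
  protocol's sources; AUC was chosen because ranking performance is the
  quantity being benchmarked, and the choice is recorded here as an
  assumption. Ties prefer the larger λ (more regularization);
* **repetitions** (default 100) re-randomize all folds; per-participant
  scores are averaged over repetitions. Repetition *r* draws its folds
  under the derived seed `seed + r`, so the run is reproducible while
  repetitions differ.

Standardization (mean/SD) is always estimated on the training portion and
applied to the held-out portion — inside inner folds too — so no
information leaks from evaluation data. A training column with zero
variance passes through unscaled rather than erroring, which keeps sparse
binary covariates safe in small folds.

The outcome coding (±1) affects only the affine scale of scores, not their
ranking, so every ROC quantity is invariant to it.

## ROC inference

* **AUC** is the Mann–Whitney probability that a random progressor
  outscores a random non-progressor, ties at ½; it equals the trapezoidal
  area under the empirical ROC curve (property-tested).
* **Operating cutoff**: the F-index, the harmonic mean of sensitivity and
  specificity, maximized over ROC thresholds; the harmonic mean at a
  degenerate corner is defined as 0. When two thresholds tie, the one with
  higher sensitivity is chosen (a screening context favours sensitivity);
  the tie-break is deliberate and tested.
* **Confidence intervals**: DeLong's structural-component variance gives
  the analytic normal interval (default), clipped to [0, 1]. A stratified
  bootstrap (resampling within each class, percentile interval, default
  2000 replicates) is also provided because the protocol's description
  conflates the two; both are implemented, agree at moderate n, and the
  analytic form is the default for speed and determinism.
* **Paired comparison**: DeLong's test for correlated ROC curves,
  z = ΔAUC / √(v_a + v_b − 2c_ab), with components computed from midranks
  in O(n log n); the fast path is property-tested against the naive O(mn)
  double sum. If two models rank participants identically the variance of
  the difference vanishes; the comparison is then flagged degenerate and
  reported as p = 1 rather than 0/0.

## Multiplicity

The batch of all non-reference comparison p-values becomes positive-FDR
q-values. The π₀ (null-proportion) estimator is not specified by the
historical protocol; the default is Storey's fixed-λ estimator at λ = 0.5,
capped at 1, with `pi0_method = "fixed_one"` as the conservative switch —
under π₀ = 1 the q-values equal Benjamini–Hochberg adjusted p-values
exactly, which is the closed-form cross-check in the tests.

Significance follows the two-decimal rounding rule: round the q-value to
two decimals (round-half-even, R's default IEC 60559 behaviour; the
rounding mode was not specified upstream and is documented here as a
choice) and call significance only on strict q < 0.05. Thus q = 0.049 is
*not* significant. Note the call is two-sided — a model significantly
*worse* than the reference is also flagged — so calls must be read with
the sign of ΔAUC.

## Pairing models with different complete-case subsets

Missingness is handled by two deliberate policies: metabolite columns are
imputed with the column minimum (missingness in untargeted metabolomics is
mostly below-detection-limit), while clinical, glucose, insulin and HbA1c
variables use per-model complete-case exclusion. Whether minimum
imputation should extend beyond metabolites is genuinely open; it is
configurable via `impute_metabolites(cohort, vars = ...)`.

Because complete-case subsets differ between models, a paired DeLong test
is only valid on the participants shared by both models. The pipeline
recomputes the reference model's scores on each comparison's common subset
whenever that subset differs from the reference's own; `n_common` and
`recomputed` in the comparisons table record exactly when this happened.

# The synthetic cohort generator

No raw data from the emulated prospective cohort is public, so the
generator is the package's test bed. It draws a latent Gaussian vector per
participant with

* a **fixed progressor count** (543 participants, 146 progressors by
  default — stratified, not Bernoulli, so class balance is exact);
* a **class mean shift** δ per marker on the standardized latent scale.
  Within-class variances stay at 1, so the binormal identity
  AUC = Φ(δ/√2) holds exactly and `calibrate_effect()` inverts it;
* a **residual covariance** chosen so the *observed mixture* reproduces
  the target correlation matrix: for prevalence p and shifts δ, the
  residual entry is t_ij·sd_i·sd_j − p(1−p)δ_iδ_j with sd_i = √(1+p(1−p)δ_i²).
  An indefinite matrix (possible with user-supplied targets) is repaired
  by eigenvalue clipping and the repair is messaged, never silent.

Continuous markers are mapped affinely to measurement scales (glucose in
mmol/L, insulin in pmol/L, HbA1c in %, metabolites stay standardized).
Glucose is floored at 0.1 mmol/L so downstream WHO classification stays
defined; insulin at 0. Sex and family history are dichotomized from their
latent columns at the empirical quantile matching prevalences 0.50 and
0.45. Rows meeting the WHO diabetes criteria at baseline
(FPG ≥ 7.0 or 2-h PG ≥ 11.1 mmol/L) are redrawn by rejection — the
emulated cohort is nondiabetic at baseline — which slightly truncates the
upper glucose tail; the single-marker AUC recovery tests tolerate the
resulting small downward bias. Missingness is injected completely at
random per marker (defaults: 2% metabolites, 1% insulin and HbA1c).

Calibration defaults:

* correlation targets use the published metabolite–glucose values
  (mannose: 0.30/0.32/0.26/0.14 against FPG/30-min/1-h/2-h PG; AHB 0.37
  with 1-h PG; bradykinin-hydroxyproline −0.25 with 1-h PG; X-12063 0.35
  with 2-h PG; HbA1c 0.16 with mannose and X-12063), adjacent OGTT time
  points more correlated than distant ones with 30-min/1-h strongest.
  Insulin correlations are not published; the defaults are modest positive
  assumptions, flagged as such;
* effect sizes target the published single-marker discrimination levels
  (1-h PG 0.75, 30-min PG 0.71, mannose 0.70, 2-h PG 0.68, HbA1c 0.67,
  FPG 0.63); unpublished ones (insulin, remaining metabolites, clinical
  singles) are plausible values below the 1-h PG level, chosen once;
* glucose means/SDs (FPG 5.72 ± 0.55, 2-h PG 6.45 ± 1.70 mmol/L, etc.)
  were chosen so a generated baseline cohort lands near the published
  strata mix (~16% IFG, ~21% IGT); exact strata counts are not enforced.

What the generator does **not** emulate: longitudinal trajectories (only
baseline markers and the final binary outcome), non-Gaussian marginal
shapes (e.g. skewed insulin), informative missingness, assay batch
effects, and any attempt to match the historical AUCs of *multivariate*
models. Passing tests therefore demonstrate the machinery's correctness
and calibration under a realistic second-order structure — not that the
package reproduces the original cohort's exact results, which would
require the original data.

# Numerical choices and degenerate inputs

* Eigendecomposition (not Cholesky) for both the covariance square root
  and the ridge path: tolerant of semidefinite inputs and reusable across
  the λ grid. Singularity at λ = 0 errors explicitly.
* `standardize()` refuses constant vectors; `impute_min()` refuses
  all-missing vectors; `complete_cases()` errors when a variable set loses
  an entire outcome class.
* ROC curves always carry the (0, 1) and (1, 0) anchor points; undefined
  predictive values (empty denominator) are `NA`, never 0.
* π₀ estimates ≤ 0 (every p tiny) fall back to 1/m so q-values stay
  defined.
* All randomness flows from user-visible seeds through `withr::with_seed`,
  leaving the caller's RNG state untouched; identical configurations give
  bit-identical cohorts, scores and result tables.

# Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep the default run
fast while leaving the statistical bands meaningful: correlation and
effect recovery at n = 20,000 (Monte-Carlo band ±0.03 / ±0.02), nested-CV
parameter recovery at n = 5,000 with 10 repetitions (±0.02), DeLong
type-I-error calibration over 2,000 simulated paired comparisons
(0.05 ± 0.015), and a full 50-model benchmark on a 543-participant cohort
at 10 repetitions, run twice to verify byte-identical determinism. The
100-repetition default is the protocol's setting; tests scale repetitions
down because the averaging property (score variance shrinking with
repetitions) is itself verified separately.

# Known limitations

* The q-value batch covers all non-reference models of one run, mirroring
  the historical "1526 comparisons" reading; per-family batches would give
  different q-values and are not provided.
* The DeLong test is asymptotic; at very small strata (the IFG/IGT subsets
  of a 543-person cohort are ~200 each) its normal approximation is rough,
  one reason stratified reruns are conventionally read on raw p.
* Minimum imputation before cross-validation uses the whole column
  (including test folds). This mirrors the emulated preprocessing, where
  imputation preceded modelling; it is a detection-limit fill-in of a few
  percent of cells, not an outcome-bearing transform, but it is a known
  deviation from strict fold hygiene.
* The RLS learner is the only classifier, by design; the benchmark
  compares variable sets, not learning algorithms.
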