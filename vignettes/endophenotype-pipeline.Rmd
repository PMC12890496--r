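---
title: "Discovering and validating immune cell endophenotypes of myasthenia gravis subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating immune cell endophenotypes of myasthenia gravis subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgendo)
```

## The scientific problem

Early-onset and late-onset myasthenia gravis (EOMG and LOMG, split at
disease onset before or after age 50) both carry acetylcholine-receptor
autoantibodies but differ in sex ratio, genetics and — crucially for
treatment — in the prevalence of thymic hyperplasia, which makes
thymectomy beneficial mainly in the hyperplasia-associated early-onset
form. A measurable immune-cell marker of the subform (an *endophenotype*)
could help direct borderline patients, sampled around age 50, to the right
treatment.

`mgendo` implements, as a reusable and fully tested pipeline, a
discovery-and-validation strategy for such endophenotypes from
high-dimensional cytometry of two independent cohorts measured on
different marker panels:

1. **Gating** (`assign_lineages()`, `neighbor_smooth_labels()`): arcsinh
   preprocessing, ordered threshold gates into the six main lymphocyte
   lineages (B, CD4 T, CD8 T, gamma-delta T, NK, ILC), refined by one pass
   of k-nearest-neighbour majority voting in marker space.
2. **Supervised differential-abundance selection**
   (`score_cells_3group()`, `select_candidates()`): every discovery-cohort
   cell is scored by a chi-square statistic comparing its neighbourhood's
   donor-weighted EOMG/LOMG/control composition with the donor-balanced
   expectation; cells above a donor-label-permutation null quantile are
   candidates.
3. **Subclustering** (`subcluster_selected()`): candidates are partitioned
   into a fixed budget of candidate clusters (61 by default).
4. **Cross-cohort transfer** (`build_common_space()`,
   `transfer_labels()`, `eligible_clusters()`): validation cells are
   assigned to candidate clusters by 1-NN against the selected training
   cells in a common-marker space standardized by training statistics;
   only clusters recovered with strictly more than 50 validation cells are
   eligible for inference.
5. **Nested directional testing** (`assign_direction()`,
   `rank_sum_one_tailed()`, `nested_select()`): each eligible cluster gets
   one pre-assigned direction (the patient group with the lowest training
   median is hypothesized LOW) and must pass three one-tailed Wilcoxon
   comparisons at 0.05 — training case vs case, training case vs control,
   and validation case vs case — to be selected.
6. **Classification** (`fit_plsda()`, `classify_samples()`): a
   one-component PLS-DA on the selected clusters' log frequencies, with
   threshold and preprocessing frozen on the training cohort and
   transferred unchanged.
7. **Associations** (`blood_thymus_spearman()`, `grade_pearson()`,
   `repertoire_stats()`): paired blood–thymus correlations,
   hyperplasia-grade correlations, and TCR repertoire contingency tests.

Because the motivating study's raw data are access-restricted, the package
ships a first-class synthetic study generator (`synthetic_spec()`,
`generate_study()`, `generate_repertoire()`) whose defaults mirror the
emulated design: a discovery cohort of 12 EOMG / 16 LOMG / 20 controls at
20,000 cells per donor with paired thymus samples for 10 donors, and a
validation cohort of 8 EOMG / 6 LOMG donors at 4,500 cells per donor on a
reduced panel.

## The error-rate calculus of nested selection

Requiring one-tailed significance at $\alpha = 0.05$ in three independent
comparisons bounds the per-cluster false-positive rate by
$\alpha^3 = 1.25\times 10^{-4}$, i.e. 1 in 8,000 — far stricter than a
Bonferroni correction over the 11 eligible clusters
($0.05/11 = 0.0045$, 1 in 220) and less punishing than combining both
(1 in 88,000):

```{r calculus}
unlist(error_rate_calculus(alpha = 0.05, n_tests_nested = 3,
                           n_comparisons = 11))
```

`null_selection_rate()` verifies the calculus by Monte Carlo: donor-level
frequencies i.i.d. from a continuous distribution at the study's group
sizes, directions fixed a priori, three independent comparisons combined
by `nested_select()`. The attained rate is slightly *below* the nominal
$\alpha^3$ because the exact rank-sum test is discrete (the largest
attainable one-tailed level below 0.05 for an 8-vs-6 comparison is about
0.041) and the large-sample comparisons use a continuity-corrected normal
approximation.

```{r nullrate, eval = FALSE}
null_selection_rate(n_reps = 5e5, seed = 1)$rate
#> about 8.8e-05
```

One caveat the package makes explicit rather than hiding: in the actual
nested design the training case sample is *shared* between the first two
comparisons, and the induced positive dependence (correlation about 0.58
between the two training U statistics) inflates the joint rate several
fold above $\alpha^3$ — `null_selection_rate(share_cases = TRUE)` measures
roughly $5$–$6\times 10^{-4}$. The $\alpha^3$ bookkeeping is therefore an
independence idealization; the validation comparison, which really is
independent, is what caps the rate at $0.05 \times$ (joint training
rate). The function exposes both designs so users can quote either
operating characteristic.

A second caveat: when directions are chosen from the same training data
being tested (as `assign_direction()` does), the two training comparisons
are further inflated by selection; the pipeline-level null behaviour is
therefore assessed empirically (below) rather than analytically.

## What the synthetic generator emulates — and what it does not

Per donor, lineage counts are multinomial in a fixed mixture (40% CD4 T,
25% CD8 T, 15% NK, 12% B, 4% each gamma-delta T and ILC). Within a
lineage, each planted subpopulation is a Gaussian blob (sd 0.3 on the
transformed scale against a background sd of 0.55) whose donor-level
frequency is logit-normal around `baseline_freq` times the donor group's
effect factor. The three default templates mirror the discriminant
populations the method is designed to find: a naive-like CCR7+CD45RA+
CD8 T population (9% of CD8 T), a MAIT-like CD161+CD45RA-lo CD8 T
population (3%), both planted LOMG-low, and a terminally differentiated
CD57+CD16-hi NK population (6%) planted EOMG-low, with effect factor 0.5
(a halving) by default.

Numerical choices, each fixed once:

* **Between-donor variability** is logit-normal with sd 0.3. No
  donor-variance model is published for these populations; 0.3
  corresponds to a realistic ~30% coefficient of variation and was
  calibrated once, by truth-level power analysis, so that the generator
  meets its specified operating characteristic (planted effects of factor
  0.5 recoverable in at least 80% of seeds at the default donor counts —
  the condition the pipeline is benchmarked against). Thymus frequencies
  add logit noise of sd 0.25 around the donor's blood value, which yields
  strong paired blood–thymus rank correlations, as observed for real
  paired compartments.
* **Hyperplasia grade** is ordinal 0–3 (0 = atrophic/normal thymus, 3 =
  marked hyperplasia) — a stand-in scale, as grading schemes vary. The
  grade is a thresholded latent variable equal to `hyperplasia_link`
  times the designated subpopulation's standardized log10 blood frequency
  plus Gaussian noise (sd 0.6); the default link of −1.2 makes low NK-like
  frequencies accompany high grades.
* **TCR layer**: clone sizes are 1 + geometric (no repertoire model is
  published; the geometric is the simplest heavy-ties choice), with
  near-singleton clones in the naive and MAIT-like templates; the
  MAIT-like template carries the invariant Va7.2/Ja33 alpha pair in 26%
  of cells versus 0.4% elsewhere, and its clones are enriched for Vb6 and
  depleted of Vb7.

Features of real data the generator does **not** emulate: spectral
spillover and unmixing artifacts, doublets and dead cells, platform batch
effects between cohorts (the two synthetic cohorts differ only in panel
and sampling depth), non-Gaussian population shapes, and donor-specific
covariance structure. Passing tests therefore demonstrate the pipeline's
statistical machinery and its operating characteristics under an
idealized generative model, not performance on raw instrument data. One
visible consequence: nearly all 61 candidate clusters survive transfer to
the synthetic validation cohort, whereas with real cross-platform data
only a minority would — the >50-cell filter bites much harder in
practice.

## Method parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| arcsinh cofactor | 3000 | intensity | fluorescence-scale convention; per-marker configurable |
| gate threshold | 1.65 | transformed scale | midpoint between the synthetic "low" (0.3) and "high" (3.0) marker modes |
| smoothing k | 20 | neighbours | one conservative cleanup pass; ties keep the original label |
| DA neighbourhood k | 150 | neighbours | the chi-square signal of a planted effect grows linearly in k while the permutation null does not; k = 150 puts a halving of a 6%-of-lineage population (signal about 9) clearly past the null's 90th percentile (about 4.7). k = 50 was measured to leave such cells straddling the threshold |
| selection quantile | 0.9 | permutation null | yields ~10% selected under the null; on planted-effect data the realized fractions span roughly 8–20% by lineage, the magnitude observed in comparable studies |
| permutations | 200 | — | donor-label permutations per lineage |
| cluster budget | 61 | clusters | study-scale anchor for the catalog size; allocated across lineages proportionally to selected-cell counts |
| overcluster factor | 3 | — | first-stage k-means granularity before Ward merging (see below) |
| transfer gate | 0.99 | quantile | validation cells farther than the 99th percentile of within-cluster training 1-NN distances stay unassigned |
| eligibility | >50 | validation cells | strict inequality; 51 passes, 50 fails |
| nested alpha | 0.05 | — | per-comparison one-tailed level |
| log offset | 0.01 | percentage points | shared by the classifier and the grade correlations for zero frequencies |

Two design choices deserve their own note:

* **Two-stage subclustering.** A single k-means pass at the 61-cluster
  budget shatters a coherent subpopulation that makes up a third of a
  lineage's selected cells into about five shards (measured Jaccard with
  the planted population ≤ 0.27), because k-means allocates centres by
  mass, not by mode. The package therefore overclusters by a factor of 3
  and then merges the size-weighted k-means centres by Ward's criterion
  down to the budget — the metaclustering pattern standard in cytometry —
  which restores planted-population Jaccard overlaps of 0.8–1.0 while
  keeping the catalog size at the budget.
* **Direction ties and control-low clusters.** A cluster whose lowest
  median belongs to the controls has no patient-group hypothesis and is
  ineligible; an exact tie between patient groups (essentially impossible
  with continuous frequencies) is treated the same way, conservatively.

Degenerate inputs are errors, not silent repairs: empty panel
intersections, zero-variance markers in the common space, groups with no
non-missing donors, constant PLS-DA predictors, and constant vectors in
the correlation functions all stop with explicit messages.

## Operating characteristics computed by the test suite

The package's acceptance tests (in `tests/testthat/test-acceptance.R`)
re-derive the design's quantitative claims at documented problem sizes:

* the error-rate calculus exactly;
* the nested type-I rate by 500,000-replicate Monte Carlo (a few seconds,
  thanks to a vectorized pairwise-indicator implementation whose p-values
  are test-identical to `rank_sum_one_tailed()`);
* exhaustive-enumeration equivalence of the exact rank-sum tail (all
  partitions with combined n ≤ 10), Fisher's exact test (tables with
  total ≤ 40), Benjamini–Hochberg, exact Spearman permutation p-values
  (n ≤ 7) and the ROC area;
* planted-effect recovery and null silence of the full pipeline over 20
  seeds each. These runs use the default study design and validation
  depth (4,500 cells per donor) but reduce the discovery cohort to 1,600
  cells per donor and use plain threshold gating; at this depth the
  rarest planted population still has 8–15 cells per donor, so donor
  frequencies are not dominated by counting noise, which they would be at
  a few hundred cells per donor (the reason the full 20,000 is not needed
  for the property to be testable).

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(cells_per_donor = c(train = 1600, val = 4500),
                       seed = 7)
res <- run_endotype_pipeline(spec, smooth = FALSE)

res$nested[res$nested$selected, ]
planted_recovery(res)
influence_fractions(res$model)
res$confusion_train
res$confusion_val
```

The thymus arm, on the same generated study:

```{r thymus, eval = FALSE}
study <- res$study
thy <- study$meta[study$meta$has_thymus, ]
nk_cluster <- res$nested$cluster_id[res$nested$selected &
                                      grepl("^NK", res$nested$cluster_id)][1]
blood <- study$train[study$train$tissue == "blood", ]
thymus <- study$train[study$train$tissue == "thymus", ]
fb <- cluster_frequencies(blood, res$catalog)
tr_thy <- transfer_labels(res$catalog, blood, thymus, res$space)
ft <- cluster_frequencies(thymus, res$catalog,
                          assignments = tr_thy$assignments)
blood_thymus_spearman(fb[thy$donor_id, nk_cluster],
                      ft[thy$donor_id, nk_cluster])
grade_pearson(fb[thy$donor_id, nk_cluster], thy$hyperplasia_grade)
```

## Known limitations

* The chi-square neighbourhood score is this package's concrete
  instantiation of supervised three-group differential-abundance
  scoring; published neighbourhood methods differ in their weighting and
  null models, and none of their internals were available to copy.
* The exact neighbour-vote rule, PLS-DA preprocessing and threshold rule
  of comparable real-data analyses are rarely reported; the choices here
  (one pass, majority vote with conservative ties; log10 with offset
  0.01, z-scoring, midpoint threshold, ties to LOMG) are declared and
  recorded in the model object for auditability.
* Selection-induced dependence makes the three nested tests non-independent
  on real pipelines (directions are data-chosen and the training sample is
  shared); the package quantifies this honestly via
  `null_selection_rate(share_cases = TRUE)` and the pipeline-level null
  runs rather than claiming the idealized $\alpha^3$ for the full
  procedure.
* No batch-effect correction is attempted: cross-cohort transfer relies
  entirely on common-marker Euclidean geometry, as in the emulated
  design.
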