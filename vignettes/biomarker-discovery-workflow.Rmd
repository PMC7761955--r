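---
title: "Methods: LC-MS biomarker panel discovery with metabopanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LC-MS biomarker panel discovery with metabopanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopanel)
```

metabopanel implements a complete discovery-to-validation workflow for
untargeted LC-MS metabolomics biomarker studies of the kind run on
clinical cohorts (for example urine or plasma profiling of ovarian-tumor
patients): feature-table preprocessing, multivariate pattern analysis
with permutation validation, univariate differential selection, SVM panel
search, and transfer of a frozen decision cutoff from a discovery to a
validation cohort. This vignette is the package's account of the methods:
what each stage computes, which choices were open and how they were
decided, and what the synthetic-cohort tests do and do not demonstrate.

## Data model

A *feature table* holds nonnegative intensities for features (identified
by retention time in minutes and m/z) across samples; a zero encodes a
missing value, the usual convention for peak areas that fell below the
detection limit. `NA` values are rejected rather than silently treated as
zero — upstream peak-picking software emits zeros, and a genuine `NA`
usually signals a malformed file. Sample metadata carries the clinical
group (`normal`, `benign`, `borderline`, `malignant`, or `qc` for pooled
quality-control injections), the cohort assignment
(`discovery`/`validation`), the batch, optional clinical markers such as
CA125 (U/mL) and an optional FIGO stage. The discovery/validation split
is always read from the metadata; the package never splits samples
itself.

## Preprocessing

`preprocess_pipeline()` applies, in order:

1. **Missingness filter ("80% rule")** — features missing in >= 20% (default
   `missing_fraction_threshold = 0.20`) of samples are removed. The
   denominator is the non-QC samples: QC injections are technical
   replicates, not biological observations, so they should neither rescue
   nor condemn a feature. The rule is applied per run over all cohorts
   being processed together (a per-group variant can be had by filtering
   the metadata first).
2. **QC coefficient-of-variation filter** — features whose CV
   (sd/mean on raw intensities) across non-missing QC values is *strictly*
   greater than 30% (default `qc_cv_threshold = 0.30`) are removed: an
   analyte that cannot be measured reproducibly in identical pooled
   samples cannot be trusted across biological ones. A feature needs at
   least `min_qc_observations = 3` non-missing QC values for its CV to be
   estimable; features below that are removed and counted separately in
   the report. QC values are pooled over batches.
3. **Half-minimum imputation** — each zero is replaced by half the
   feature's minimum positive intensity, the standard stand-in for a value
   censored at the detection limit. The per-feature reading is the
   default; `half_min_scope = "global"` switches to half the global
   minimum.
4. **Median normalization** — every sample is rescaled so its median
   intensity equals the median of all sample medians. Any positive
   reference constant would yield identical downstream log2 fold-change
   *differences*; the median-of-medians keeps intensities on their
   original scale.
5. **log2 transform** — applied last, after imputation guarantees strict
   positivity.

The stage report records counts removed at each step, so a constructed
table can be checked feature-by-feature. Filters operate on
pre-imputation zeros, which makes imputation provably unable to change
which features survive.

## OPLS-DA, Q2 and the permutation test

The multivariate model is two-class OPLS-DA: `n_orthogonal` components of
variation orthogonal to the class response are removed, then a single
predictive PLS component is fitted to the centred 0/1 dummy response.
Pareto scaling (divide centred columns by the square root of the standard
deviation) is the default pretreatment, the common choice for log-scale
metabolomics intensities; PCA diagnostics default to unit-variance
scaling. With `n_orthogonal = 0` the model reduces exactly to PLS1-DA,
which the test suite exploits as an oracle.

Open choices and how they were fixed:

* **Number of orthogonal components**: one, the customary default in
  chemometrics software for a two-class model; configurable, with
  `n_orthogonal = "auto"` adding components while cross-validated Q2
  improves by more than 0.01.
* **Q2** is `1 - PRESS/TSS` over stratified, seeded `cv_folds = 7`-fold
  cross-validation. Scaling parameters are re-estimated inside every
  training fold: fitting the scaler on all samples first would leak
  held-out information into PRESS. Stratification keeps class proportions
  stable in small cohorts.
* **VIP** is computed over the single predictive component:
  `VIP_j = sqrt(p * w_j^2 / sum(w^2))`, so the mean squared VIP is exactly
  1 and `VIP > 1` reads as "above-average contribution".
* **Permutation test**: the model is refitted on `n_permutations = 1000`
  label permutations and `pQ2` is the add-one estimator
  `(#{permuted Q2 >= observed} + 1) / (n + 1)`. The add-one form is valid
  (it can never report 0) and its minimum is `1/(n+1)`; note that with
  fewer than 20 permutations it cannot fall below 0.05, so small
  permutation counts are only useful for smoke tests. A model is declared
  **overfit** when `pQ2 >= 0.05`, and `run_pipeline()` then refuses to
  proceed to panel search unless forced — an unpredictive multivariate
  model means downstream "biomarkers" would be noise.
* **Sign convention**: the predictive component is oriented so the
  positive class has positive mean score, removing the sign ambiguity of
  NIPALS-style fits.

## Differential selection

Per feature, a two-sided Wilcoxon rank-sum p-value (midrank ties,
tie-corrected normal approximation with continuity correction; exact
enumeration for tie-free groups of at most 10), Benjamini–Hochberg FDR
across *all* features surviving preprocessing, and
`log2FC = mean(case) - mean(reference)` on the log2 table — a feature
lower in the case group is negative. Selection is the joint rule
`VIP > 1 AND FDR < 0.1` (`fdr_rule`) or `VIP > 1 AND p < 0.05` (`p_rule`),
all inequalities strict. The `p_rule` exists for comparisons with little
power (small borderline groups) where an FDR threshold would select
nothing; its cost is a weaker error guarantee, which is why both the raw
p and the FDR are always reported. The FDR family is the full surviving
feature set of the comparison, not an annotated subset: adjusting only
over annotatable features would understate the multiplicity actually
searched. Borderline-into-malignant merging, when a comparison calls for
it, is a metadata relabelling controlled by `comparison_spec()`.

## Panel search, SVM and cutoff transfer

`exhaustive_panel_search()` scores candidate subsets of size 1-10 by mean
cross-validated AUC of a radial-kernel SVM (stratified 7-fold, seeded,
scaling refit per training fold). True exhaustion over all subsets of
~50+ candidates is combinatorially impossible (~1e10 subsets up to size
10), so a budget (default 1e6 subset evaluations) triggers seeded greedy
forward selection, recorded in the search report; within budget the
search provably equals full enumeration. Mean CV AUC is the objective
because the panel's purpose is ranked discrimination; accuracy at an
arbitrary 0.5 threshold would conflate the panel with the later cutoff
choice.

The final classifier is a radial-kernel SVM (defaults `gamma = 0.1`,
`cost = 100`, the printed values of the reference analysis for the
normal-versus-tumor comparison; `cost = 10` is typical for the smaller
contrasts). Probabilities come from cross-validated Platt calibration:
decision values for every training sample are computed with seeded
stratified folds and mapped through a logistic fit. This serves two
purposes — the seed makes refits bit-identical, and the cross-validated
probabilities are free of resubstitution optimism. For that reason the
**discovery ROC and the Youden-optimal cutoff are computed on the
cross-validated probabilities**, not on resubstitution scores; an
optimistically placed cutoff would not transfer. The cutoff maximizing
sensitivity + specificity - 1 over observed thresholds (ties broken
toward higher specificity, then the larger threshold) is frozen into the
model and applied unchanged to validation samples: `evaluate_panel()`
re-estimates nothing — not the scaler, not the classifier, not the
cutoff. AUC itself is cutoff-free and is reported alongside.

ROC curves call a sample positive when its score is `>=` the threshold;
the trapezoidal AUC then equals the normalized Mann–Whitney U statistic
exactly, ties counting one half — an identity the acceptance tests check
on random score vectors.

Hybrid models append the log2-transformed clinical marker (with a +1
offset so a zero concentration stays finite) as an additional SVM column;
samples missing the marker are excluded from marker-dependent models only
and counted. A raw marker can also be evaluated directly as a score
(`clinical_marker_roc()`), with either the Youden cutoff or a fixed
clinical one such as 35 U/mL for CA125.

## Annotation

`match_features()` performs precursor-only matching of feature m/z
against a user-supplied reference list (positive-mode adduct m/z already
applied — adduct assumptions belong to the list, not the matcher), with a
signed ppm delta and an inclusive tolerance of 20 ppm, the conventional
QTOF precursor tolerance. MS2 fragment evidence is out of scope, so
candidates are putative by construction; taxonomy columns pass through
untouched.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with known ground truth:

* log-normal feature intensities (`2^N(18, 2.5)` baselines — peak areas
  in the 10^4–10^7 range typical of QTOF data) with per-feature
  biological noise sd drawn log-normally around 0.8 log2 units;
* a minority of differential features with planted log2 effects (default
  2, the effect size used throughout the recovery tests), benign and
  malignant sharing the shift while borderline receives an independently
  signed one — borderline tumors do not sit on a benign-to-malignant
  axis;
* planted features are restricted to reliably detected features
  (expected missingness < 10%): biomarker candidates are by definition
  quantifiable, and a feature censored away by the 80% rule could never
  carry a panel;
* missing-not-at-random zeros: the probability of a zero decreases
  logistically (slope 0.8 per log2 unit) with the underlying intensity
  around a 5% baseline — the detection-limit behaviour implied by
  zero-encoding and half-minimum imputation; a zero slope gives the
  completely-at-random ablation;
* multiplicative batch effects (per-feature log2 offsets, sd 0.1, over 2
  batches) and a spiked internal-standard feature (constant
  concentration, ~5% RSD, never missing);
* pooled QC injections — the mean of a random 20% of the real samples
  times multiplicative noise (sd 0.1 on the natural-log scale, i.e. ~10%
  RSD), one per 20 real samples;
* a CA125-like marker drawn per group from a moment-matched log-normal
  (group means/sds default to 8.35/5.81, 83.45/234.82, 183.88/326.63,
  1254.34/1597.27 U/mL for normal/benign/borderline/malignant — standard
  deviations exceeding means imply the strong right skew the log-normal
  reproduces), and FIGO stages assigned to borderline/malignant samples
  with early-stage fractions matching a typical discovery cohort;
* group sizes defaulting to 40/36/13/74.

Every draw flows from the single spec seed, and a `template` argument
reuses a cohort's feature-level parameters so a validation cohort is
drawn i.i.d. from the same generative model — the design assumption
behind cutoff transfer.

What the generator does **not** emulate: feature-feature correlation
(real metabolite intensities are strongly correlated within pathways;
independent features make multivariate separation easier than reality),
retention-time drift, batch-by-intensity interactions, and non-log-normal
heavy tails. Passing tests therefore demonstrate the correctness and
calibration of the machinery under the stated model, not field
performance on any particular biofluid.

## Numerical choices and degenerate inputs

* Scaling divisors of zero (constant features) are an error listing the
  features; callers drop them deliberately rather than silently.
* All-zero features abort imputation by name — they should have been
  filtered.
* Complete ties in the Wilcoxon test return p = 1 (the normal
  approximation is 0/0 there).
* Degenerate ROCs (all scores equal) abort cutoff selection.
* The libsvm decision-value sign depends on class order of appearance; an
  explicit orientation step pins "higher score = positive class" before
  calibration.
* Cross-validation folds everywhere are stratified and derived
  deterministically from the caller's seed; derived seeds stay below
  2^31.

## Problem sizes in the tests and acceptance script

The test suite exercises the stack at deliberately modest sizes — null
calibration uses 100 cohorts of 40 + 40 samples by 200 features with 99
permutations; recovery uses 1000 features with 50 planted effects;
cutoff transfer uses 150 + 150 samples per cohort over 10 seeds — sizes
at which the checked properties (binomial calibration bands, >= 90%
recovery, AUC transfer within 0.07) are statistically meaningful. The
acceptance script runs the full workflow at the study scale: a
40/36/13/74 discovery cohort and a 40/45/7/76 validation cohort, 1300
features with 100 planted effects spanning |log2FC| 0.25–2.5, and the
full 1000-permutation test.

## Known limitations

* Two-class OPLS-DA only; multi-class contrasts are run pairwise.
* The exported model JSON is provenance, not a reloadable classifier.
* Annotation is precursor-mass-only; identification confidence beyond
  "putative" requires MS2 evidence the package does not model.
* The greedy fallback of the panel search can miss interaction-only
  panels (e.g. XOR pairs) that full enumeration would find; the report
  always states which method ran.
* With per-feature effects as strong as the defaults, a single planted
  feature can saturate the discovery AUC; the cutoff-transfer tests use
  weaker effects (0.65) precisely to keep the operating point
  informative.
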