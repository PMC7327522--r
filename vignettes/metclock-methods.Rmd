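---
title: "Methods: models, parameters and numerical choices in metclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in metclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metclock` implements an end-to-end analysis of longitudinal untargeted
LC-MS pregnancy metabolomics. This vignette explains the statistical models
behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical decisions taken where
the design was genuinely open. It states no empirical result beyond what the
package's tests and `scripts/acceptance.R` themselves compute.

## The data model

The unit of data is a features × samples intensity matrix accompanied by a
feature table (`feature_id`, m/z, retention time, ion mode) and per-sample
metadata (subject, gestational age at draw anchored to first-trimester
ultrasound, delivery gestational age, analytical batch, run order, blank /
postpartum flags, birth weight, natural-labor-onset flag). Raw intensities
are linear-scale and positive where observed; an empty cell is a missing
value, which in LC-MS is informative (missing-not-at-random, concentrated at
low intensity). All analyses after preprocessing work on log2 intensities.

## Preprocessing

The stage order is fixed and each stage is a pure function:

1. **Feature filtering.** A feature is kept iff it is quantified (observed
   and > 0) in at least 30% of non-blank samples *and* its median intensity
   is at least twice its noise level, the median signal across blank runs.
   A feature never quantified in any blank passes the signal-to-noise
   criterion outright — absence from blanks indicates a clean noise floor.
   Both keep-side boundaries are inclusive; the sample-missingness boundary
   below is strict (>50%), following the natural reading of "less than 30%"
   / "more than 50%".
2. **Log2 + run-median centring.** Each run's median over observed features
   is set to zero, absorbing differences in total material.
3. **Drift correction.** Per feature and batch, ordinary least squares of
   log abundance on run order; the *centred* fit is subtracted so the
   within-batch mean is untouched (the next stage re-centres levels anyway,
   and subtracting the uncentred fit would double-shift them). Batches with
   fewer than 3 observations for a feature are left alone.
4. **Batch median centring** per feature (idempotent).
5. **Sparse-sample removal** (strictly more than 50% missing).
6. **KNN imputation.** Neighbours are *features* (profile-wise), the
   convention for omics matrices. Distance is the Euclidean distance over
   jointly observed samples rescaled by the square root of the overlap
   fraction, making pairs with different overlap comparable; each missing
   cell takes the unweighted mean of the k = 10 nearest features observed at
   that sample, falling back to all available neighbours and finally to the
   feature's own mean. Observed cells are never altered.
7. **PCA QC** on feature-centred (unscaled) data; a sample is flagged when
   any retained score exceeds 4 SD of that axis. Unit-variance scaling is
   deliberately not applied: batch centring has already harmonized scales,
   and scaling would inflate near-constant features.

**What exactness means here.** With zero measurement noise and flat
(constant) features, injected per-feature batch offsets and linear run-order
drift are removed *exactly* (to machine precision), provided the feature
intercepts are spaced more widely than the artifacts move them — then the
run-median is the same physical feature everywhere and all fits are exact.
With time-varying trajectories the guarantee weakens in two precise ways:
the per-run median mixes features, and the per-batch drift OLS picks up the
finite-sample covariance between the clean trajectory and the randomized run
order. The tests therefore assert exact recovery in the rank-stable flat
configuration, assert that processing (clean + artifacts) equals processing
(clean) under rank stability, and quantify the realistic case by the ≥10×
shrinkage of re-fitted drift slopes.

**A caveat of median normalization worth knowing.** When rising and falling
features do not balance exactly in a given cohort, their net trend enters
the per-run median and is subtracted from *every* feature — after which
nominally "unchanging" features genuinely correlate with gestational age.
This is a property of median normalization, not of the significance
procedure; the package's FDR calibration is therefore assessed where null
labels still apply (pre-normalization signal plus noise), while sensitivity
is assessed on the fully processed table.

## MS/MS annotation

Features match spectra by accurate mass (±25 ppm) and retention time
(±30 s); all matching spectra are used. Similarity is a forward
dot-product: intensities are base-peak normalized and square-root weighted
(damping dominance of the base peak, the common choice for Orbitrap data),
fragments are greedily paired by nearest m/z within 0.02 Da with each
fragment used at most once, and the score is the cosine of the paired
weights with unpaired fragments contributing to the norms only. The score is
symmetric, bounded by 1 (Cauchy–Schwarz), and invariant to global intensity
rescaling. The 0.02 Da tolerance and √-weighting are conventions, not
derivable from the underlying method description, and are config-exposed.
Identity assignment is tiered: authentic standard (±5 ppm, MSI level 1) >
library MS/MS match with similarity ≥ 0.5 (level 2) > imported MetDNA call
(level 4; MetDNA itself is an external tool and is never computed here).
Ties break by similarity, then |Δm/z|, then compound name — deterministic by
construction.

## Significance analysis (SAM-style)

The per-feature statistic is the Spearman rank correlation with gestational
age (average ranks on ties), making it invariant to monotone transforms.
The null ensemble is built from sample-wise permutations of the GA vector.
For a threshold *t* on |r|, the estimated FDR is the median permutation
count of null statistics ≥ *t* divided by the observed count; a feature's
q-value is the smallest estimated FDR over thresholds that include it, which
makes q monotone non-increasing in |r|. This is a self-contained analog of
the "distribution-independent ranking test" flavour of SAM, not a clone of
any particular implementation. Whether the quantitative response should be
raw or delivery-scaled GA is left to the caller; the default is raw.

Top changers are defined by per-feature OLS slope of log2 abundance on
gestational weeks with the strict rule |slope| > log2(1.5)/40 ≈ 0.0147
(at least 1.5-fold over a 40-week gestation). Weekly profiles bin samples by
the floor of adjusted GA (delivery rescaled to 40 weeks; postpartum pooled
as "PP") and are ordered by average-linkage hierarchical clustering on
Manhattan distances, with subtrees oriented by mean profile level so the
leaf order is deterministic.

## Partial-correlation network

Variables are standardized and a sparse Gaussian precision matrix is
estimated by graphical lasso (block coordinate descent, written from
scratch) along a 100-point log-spaced penalty path with warm starts. The
penalty is selected by the extended BIC, `-2·loglik + E·log n + 4·γ·E·log p`
with γ = 0.5 and E the number of nonzero off-diagonal pairs. Because EBIC
definitions vary on one decisive point, the convention used here is: the
log-likelihood is evaluated on the *support-constrained unpenalized refit*
(the penalized likelihood conflates shrinkage with lack of fit and
systematically over-selects). Ties in EBIC resolve to the sparsest (largest)
penalty. Edge weights are the partial correlations
`-K_ij / sqrt(K_ii K_jj)` of the selected precision. Centralities follow the
standard definitions: strength = Σ|w|; shortest paths on lengths 1/|w|;
closeness = 1/(Σ distances), set to 0 for nodes that cannot reach everyone;
betweenness = shortest-path counting. One caveat is asserted rather than
assumed in the tests: the exact lasso active set is not nested along the
penalty path — single-edge transient flickers occur — so monotone sparsity
holds at scale (a substantially larger penalty never has more edges) rather
than literally between adjacent grid points.

## The metabolic clock

Lasso regression (glmnet's coordinate descent) of gestational age on
metabolite abundances, predictors standardized internally, coefficients
reported on the original scale. Cross-validation folds are formed *by
subject* — subjects shuffled and dealt round-robin — so no fold ever
contains samples of a training subject; this is the guard against
person-specific leakage and is asserted as an invariant. λ is chosen to
minimize pooled held-out squared error (the plain minimizer, not the 1-SE
rule, which the underlying method description does not invoke), then
inflated to the smallest grid value at which the full-data refit keeps at
most five predictors — the cap is enforced on the refit support, which is
the quantity one reports as "the panel". The discovery evaluation pools
out-of-fold predictions; independent cohorts are scored with the frozen
model, optionally followed by a linear rescale when a cohort was normalized
independently (this changes RMSE but not R). Contributions are
|β_i| / Σ|β_j| over the nonzero predictors. Postpartum samples are excluded
throughout: the clock is a pregnancy model.

Two behaviours of the capped lasso are worth stating plainly. First, with
noise-free data the minimum-ℓ1 interpolant may use more features than the
clinical cap, so exact recovery is a property of the *uncapped* model; the
capped model retains a small penalty-induced bias. Second, the capped
model's predictions are shrunk toward the mean (the pred-vs-truth slope sits
near R² times the residual shrinkage), so its raw RMSE contains a
regression-to-the-mean component; evaluation reports raw RMSE regardless.

## Timing classifiers

Binary labels: gestational age strictly above a cutoff (all pregnancy
samples for cutoffs ≤ 28 weeks; third-trimester samples only for 32 and 37),
or delivery within c weeks of the draw (strict <, third trimester only,
subjects with natural labor onset only — scheduled C-sections and pre-onset
inductions are excluded, post-onset augmentation is allowed). The model is a
logistic lasso under the same subject-wise CV and cap machinery (≤ 3
predictors), scored by linear predictors; AUROC is the tie-aware
Mann–Whitney probability, and its confidence interval is a percentile
bootstrap over *subjects* (1000 resamples; a resample carries all of a
person's samples; single-class resamples are redrawn). A percentile rather
than BCa interval is used — nothing in the method description demands more.

## Personal clock deviations

Only out-of-sample predictions enter (out-of-fold for discovery, frozen
model for validation; the code refuses predictions tagged in-sample). Per
subject: mean Δ(GA_metabolic − GA_ultrasound), RMSE, and the Pearson
correlation with its p-value (requiring ≥ 3 samples). Birth weight is
residualized on delivery GA by OLS; mean Δ is then correlated against those
residuals (all subjects) and against delivery GA (natural onsets only).
Per-person correlation p-values combine by Fisher's method, `X² = −2Σ ln p`
on 2k degrees of freedom. A concordance table counts subjects whose clock
ran > 1 week ahead (behind) and delivered before (after) the 40-week due
date; subjects within a week are reported but not classified either way.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with defaults fixed once as the package's study conditions:

* 30 subjects, weekly visits from week 5 to delivery attended with
  probability 0.7 (≈ 780 pregnancy samples) plus one postpartum sample at
  delivery + 6 weeks; delivery ~ Normal(40, 1.2) truncated to [37, 42].
* A latent per-subject clock offset δ ~ N(0, 1.25 wk): the subject's
  metabolic age is GA + δ. Delivery advances by 0.55 wk per week of δ, and
  birth weight gains 400 g per week of δ on top of a 170 g/week trend in
  delivery GA plus 120 g of unexplained noise. These couplings were
  calibrated once to the reported person-level effect sizes (mean Δ spread
  of roughly ±2 weeks; strong positive birth-weight and negative
  delivery-timing correlations) *as observed through the clock's own
  estimation error* — attenuation through ~1 week of per-subject Δ noise and
  the delivery-GA residualization halves naive correlations, so weaker
  couplings cannot reproduce the reported regime.
* 1000 log-normal features with intercepts U(11, 24) log2 units in four
  trajectory classes (30% linear-increasing, 30% linear-decreasing, 10%
  early-saturating with logistic midpoints ~18 wk, 30% null). Five features
  form a dominant "clock panel" — steroid-like slopes of 0.07–0.10
  log2/week, mutually correlated through a shared per-sample family factor,
  low independent noise — emulating the dense central steroid cluster that
  carries most of the timing signal in real pregnancy metabolomes. The bulk
  changes modestly (|slope| 0.012–0.025, independent noise 0.5 log2). This
  two-tier structure is essential: if hundreds of features were equally
  informative, a 5-predictor capped lasso would be forced into extreme
  shrinkage, a regime inconsistent with the reported accuracy.
* A pre-delivery surge (1.2 log2 units × exp(−WD/3)) on 5% of features,
  giving the weeks-to-delivery classifiers their physiological signal.
* Per-feature batch offsets (SD 0.4) across 12 batches, within-batch linear
  run-order drift (slope SD 0.01/run), blank runs (2 per batch) at 5 ± 1.5
  log2 units below each feature's level with 30% of features absent from
  blanks, and MNAR missingness P(missing) = logistic((13 − log2 x)/1.5).
* All noise terms scale with `sigma_noise`, so a zero-noise configuration is
  exactly clean; a single RNG stream seeded from `config$seed` makes
  regeneration bit-identical.

What it does *not* emulate: chromatographic peak shapes, adducts and
isotopes, between-feature correlation beyond the clock-panel factor,
non-linear drift, informative dropout of whole runs, demographic covariates.
Consequently, passing tests demonstrate that the *procedures* behave as
specified under the assumed data model — they do not certify performance on
any real cohort.

MS/MS fixtures pair each library spectrum (5–20 fragments) with a jittered
query (m/z SD 0.004 Da, well inside the 0.02 Da tolerance; log-normal
intensity jitter; Poisson noise peaks) and with decoy queries that share a
precursor but carry unrelated fragments, so MS1 matching alone cannot
separate them.

## Problem sizes used by the tests

Module tests run on small cohorts (≈ 12 subjects × 120 features) and
closed-form toys; the acceptance checks use the default 30 × 1000 cohort,
an all-null 500 × 200 FDR calibration at 300 permutations, a chain-precision
network at p = 20 / n = 500, three replicate cohorts for the person-level
correlations, and 500 subject-level replicates for type-I calibration —
sizes chosen so the whole suite completes in about a minute while every
stochastic assertion retains comfortable margins.

## Known limitations

* The SAM analog is rank-based with a permutation-median FDR; it is not an
  exact reimplementation of any published SAM variant.
* The graphical lasso is dense-matrix R code, comfortable to p of a few
  hundred; it is not written for thousands of nodes.
* Pathway activity requires an externally supplied pathway map; enrichment
  and topology statistics are out of scope.
* The clock's capped lasso reports shrunk coefficients by design;
  contributions are relative weights within the panel, not effect sizes.
* Median normalization can endow unchanging features with apparent
  gestational-age association when trajectory classes are unbalanced (see
  the preprocessing caveat above); interpret feature-level "significance
  fractions" on real cohorts accordingly.
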