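# metclock

Longitudinal pregnancy metabolomics in R: from a raw untargeted LC-MS
feature table to a sparse **metabolic clock** that tells gestational time
from a blood sample.

Pregnancy reorganizes the blood metabolome on a precise schedule: steroid
hormones such as estriol-16-glucuronide and THDOC rise over orders of
magnitude while many lipids (lysophosphatidylcholines, monoacylglycerides)
steadily fall, and most of these changes snap back to baseline after
delivery. `metclock` implements the complete analysis chain used to exploit
that schedule in weekly-sampled cohorts:

* **Preprocessing** — presence filtering (features quantified in ≥ 30% of
  samples), signal-to-noise filtering against blank runs (median ≥ 2× the
  blank median), log2 transform with per-run median centring, per-batch
  linear run-order drift correction, per-batch median centring, removal of
  samples > 50% missing, k-nearest-neighbour imputation (k = 10), and PCA
  outlier screening.
* **MS/MS annotation** — accurate-mass (± 25 ppm) and retention-time
  (± 30 s) matching of features to spectra, forward dot-product similarity
  over tolerance-paired, √-intensity-weighted fragments (cutoff 0.5), and
  tiered identities: authentic standard (MSI level 1) > spectral library
  match (level 2) > imported MetDNA call (level 4).
* **Significance analysis** — a SAM-style procedure with a Spearman
  rank-correlation statistic against gestational age and a sample-wise
  permutation FDR; top changers by the log2(1.5)/40 ≈ 0.015 log2-units/week
  slope rule; delivery-scaled ("adjusted") gestational ages; baseline
  normalization against all samples before week 14; Manhattan-distance
  hierarchical ordering of weekly profiles.
* **Network analysis** — an EBIC-selected (γ = 0.5) graphical-lasso
  partial-correlation network over pregnancy-related compounds with
  strength, closeness and betweenness centralities.
* **Pathway activity** — mean metabolite intensity per pathway (≥ 3 mapped
  compounds) across adjusted gestational-week windows, baseline-subtracted.
* **The metabolic clock** — L1-penalized (lasso) linear regression of
  gestational age on metabolite abundances with *subject-wise* 10-fold
  cross-validation, the penalty inflated until at most five predictors
  remain, pooled out-of-fold evaluation (Pearson R, R², RMSE), frozen-model
  validation of independent cohorts, and per-predictor contributions
  |β<sub>i</sub>| / Σ|β<sub>j</sub>|.
* **Timing classifiers** — logistic-lasso models (≤ 3 metabolites) for
  gestational-age cutoffs (20, 24, 28, 32, 37 weeks) and imminent delivery
  (within 2, 4, 8 weeks; natural labor onsets only), with AUROC and
  person-level bootstrap confidence intervals.
* **Personal clock deviations** — per-subject mean
  Δ(GA<sub>metabolic</sub> − GA<sub>ultrasound</sub>), correlated against
  delivery-timing-adjusted birth-weight residuals and against actual
  delivery timing; per-person correlation p-values combined with Fisher's
  method.
* **Synthetic cohorts** — `generate_cohort()` simulates the whole data
  generating process (trajectory classes, a dominant correlated steroid-like
  clock panel, batch offsets, run-order drift, intensity-dependent
  missingness, blank runs, a latent per-subject clock offset coupled to
  delivery timing and birth weight, MS/MS fixtures), so every stage is
  testable without any download.

## Worked example

```r
library(metclock)
library(dplyr)

co  <- generate_cohort(cohort_config(seed = 2024))   # 30 subjects, ~780 samples
pre <- run_preprocess(co$table, co$meta)             # filter/normalize/impute
m   <- filter(co$meta, sample_id %in% colnames(pre$table), !is_blank)
tab <- pre$table[, m$sample_id]
preg <- !m$is_postpartum

fit <- run_clock_pipeline(t(tab[, preg]), m$ga_ultrasound_weeks[preg],
                          m$subject_id[preg], cfg = clock_config(seed = 2024))
glance(fit)
#> # A tibble: 1 × 6
#>   n_predictors lambda lambda_cv  cv_r cv_r_squared cv_rmse
#>          <int>  <dbl>     <dbl> <dbl>        <dbl>   <dbl>
#> 1            5   2.30     0.196 0.906        0.821    4.98
```

The fitted clock uses 5 metabolites; in subject-wise 10-fold
cross-validation its predictions correlate with first-trimester-ultrasound
gestational age at Pearson R = 0.91 (R² = 0.82) with a root-mean-square
error of 5.0 weeks across 743 held-out pregnancy samples. `tidy(fit)` lists
the selected features with coefficients and contributions;
`autoplot(fit$cv)` draws the predicted-vs-ultrasound scatter.

Downstream, the personal clock analysis:

```r
subjects <- m |> filter(!is_postpartum) |>
  distinct(subject_id, birth_weight_g, delivery_ga_weeks, natural_onset)
rec <- per_subject_deviation(fit$cv_predictions, subjects)
rec$birthweight_residual <-
  birthweight_residuals(rec$birth_weight_g, rec$delivery_ga_weeks)
correlate_deviation(rec, "birthweight_residual")
#> # A tibble: 1 × 4
#>   against                  r       p     n
#>   <chr>                <dbl>   <dbl> <int>
#> 1 birthweight_residual 0.558 0.00136    30
```

Subjects whose metabolic clock runs ahead of ultrasound carry heavier
babies for their gestational length (r = 0.56, p = 0.001 here) and deliver
earlier (`correlate_deviation(rec, "delivery_ga")` is negative), the
signature of a fetoplacental input to the maternal metabolome.

`run_pipeline(co)` chains every stage (preprocess → SAM → slope filter →
partial-correlation network → clock → weeks-to-delivery classifier →
deviation analysis) in one call.

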