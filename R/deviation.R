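# Personal clock-deviation analysis ------------------------------------------
#
# Discrepancies between the metabolic clock and first-trimester ultrasound
# timing, averaged per person, related to delivery-timing-adjusted birth
# weight and to actual delivery timing; per-person correlations combined
# across subjects with Fisher's method. All inputs must be out-of-sample
# predictions (cross-validation or frozen-model validation), never
# in-sample fits.

#' Per-subject deviation records
#'
#' For each subject over their pregnancy samples: mean
#' Delta(GA_metabolic - GA_ultrasound), RMSE, and the Pearson correlation
#' (with p-value) between predicted and ultrasound gestational age.
#' Subjects with fewer than 3 samples get `NA` for r and p but still report
#' the mean deviation.
#'
#' @param predictions Tibble with `subject_id`, `ga_ultrasound`,
#'   `ga_metabolic`, and a `source` column that must not be "insample"
#'   (e.g. the `cv_predictions` of [run_clock_pipeline()]).
#' @param subjects Optional tibble with per-subject `subject_id`,
#'   `birth_weight_g`, `delivery_ga_weeks`, `natural_onset` to join on.
#' @return Tibble, one row per subject: `subject_id`, `mean_delta`, `rmse`,
#'   `r`, `p`, `n`, plus any joined subject columns.
#' @export
per_subject_deviation <- function(predictions, subjects = NULL) {
  if ("source" %in% names(predictions) &&
      any(predictions$source == "insample"))
    abort("deviation analysis requires out-of-sample predictions")
  rec <- predictions |>
    group_by(.data$subject_id) |>
    summarise(
      mean_delta = mean(.data$ga_metabolic - .data$ga_ultrasound),
      rmse = sqrt(mean((.data$ga_metabolic - .data$ga_ultrasound)^2)),
      r = if (n() >= 3 && sd(.data$ga_ultrasound) > 0 &&
              sd(.data$ga_metabolic) > 0)
        cor(.data$ga_metabolic, .data$ga_ultrasound) else NA_real_,
      p = if (n() >= 3 && sd(.data$ga_ultrasound) > 0 &&
              sd(.data$ga_metabolic) > 0)
        cor.test(.data$ga_metabolic, .data$ga_ultrasound)$p.value
      else NA_real_,
      n = n(),
      .groups = "drop"
    )
  if (!is.null(subjects)) rec <- left_join(rec, subjects, by = "subject_id")
  rec
}

#' Birth-weight residuals adjusted for delivery timing
#'
#' Ordinary least squares of birth weight on delivery gestational age across
#' subjects; the residuals represent each infant's weight deviation from the
#' cohort trend at its gestational length.
#'
#' @param birth_weight_g,delivery_ga_weeks Numeric vectors (one per
#'   subject).
#' @return Numeric residuals (summing to 0).
#' @export
birthweight_residuals <- function(birth_weight_g, delivery_ga_weeks) {
  ok <- complete.cases(birth_weight_g, delivery_ga_weeks)
  if (sum(ok) < 3) abort("need at least 3 subjects with both values")
  if (sd(delivery_ga_weeks[ok]) == 0)
    abort("constant delivery GA; slope unidentifiable")
  out <- rep(NA_real_, length(birth_weight_g))
  out[ok] <- residuals(lm(birth_weight_g[ok] ~ delivery_ga_weeks[ok]))
  out
}

#' Correlate mean clock deviation with a subject-level outcome
#'
#' Pearson correlation (two-sided p) between per-subject mean
#' Delta(GA_metabolic - GA_ultrasound) and either the delivery-timing-
#' adjusted birth-weight residual or the delivery gestational age. The
#' delivery-timing analysis is restricted to natural-labor-onset subjects
#' when `onset_filter` is set.
#'
#' @param records Output of [per_subject_deviation()] joined with subject
#'   covariates.
#' @param against `"birthweight_residual"` or `"delivery_ga"`.
#' @param onset_filter Restrict to natural-onset subjects (applies to the
#'   delivery-timing analysis; default TRUE for it, FALSE otherwise).
#' @return Tibble: `against`, `r`, `p`, `n`.
#' @export
correlate_deviation <- function(records,
                                against = c("birthweight_residual",
                                            "delivery_ga"),
                                onset_filter = against == "delivery_ga") {
  against <- match.arg(against)
  rec <- records
  if (isTRUE(onset_filter)) rec <- rec |> filter(.data$natural_onset)
  yvar <- if (against == "birthweight_residual") {
    if (!"birthweight_residual" %in% names(rec))
      rec$birthweight_residual <- birthweight_residuals(
        rec$birth_weight_g, rec$delivery_ga_weeks)
    rec$birthweight_residual
  } else {
    rec$delivery_ga_weeks
  }
  ok <- complete.cases(rec$mean_delta, yvar)
  if (sum(ok) < 3) abort("need at least 3 subjects")
  ct <- cor.test(rec$mean_delta[ok], yvar[ok])
  tibble(against = against, r = unname(ct$estimate), p = ct$p.value,
         n = sum(ok))
}

#' Combine per-person p-values with Fisher's method
#'
#' `X^2 = -2 sum log p_i` on `2k` degrees of freedom; the summary p is the
#' upper chi-square tail.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Tibble: `chisq`, `df`, `p`.
#' @export
fisher_meta <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) abort("no p-values supplied")
  if (any(p_values <= 0))
    abort("p-values must be > 0 (floor tiny values at machine epsilon)")
  if (any(p_values > 1)) abort("p-values must be <= 1")
  x2 <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  tibble(chisq = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

#' Due-date concordance table
#'
#' Counts, among subjects whose metabolic clock ran more than one week ahead
#' of ultrasound (mean Delta > +1), how many delivered before the 40-week
#' ultrasound due date, and among subjects more than one week behind
#' (mean Delta < -1), how many delivered after it. Subjects within one week
#' are reported but not classified.
#'
#' @param records Deviation records with `mean_delta` and
#'   `delivery_ga_weeks` (typically natural-onset subjects only).
#' @return Tibble: `group`, `n`, `n_concordant`.
#' @export
due_date_concordance <- function(records) {
  ahead <- records |> filter(.data$mean_delta > 1)
  behind <- records |> filter(.data$mean_delta < -1)
  tibble(
    group = c("clock_ahead_gt1wk", "clock_behind_gt1wk", "within_1wk"),
    n = c(nrow(ahead), nrow(behind),
          nrow(records) - nrow(ahead) - nrow(behind)),
    n_concordant = c(sum(ahead$delivery_ga_weeks < 40),
                     sum(behind$delivery_ga_weeks > 40), NA_integer_)
  )
}
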