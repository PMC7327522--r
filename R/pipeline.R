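# End-to-end pipeline ---------------------------------------------------------

#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates preprocessing, significance analysis, the top-changer slope
#' filter, the partial-correlation network of top changers, the metabolic
#' clock with subject-wise cross-validation, the weeks-to-delivery
#' classifier, and the personal deviation analysis. Designed for a cohort
#' from [generate_cohort()] or read from disk with [read_feature_table()] /
#' [read_sample_meta()].
#'
#' @param cohort List with `table` (raw linear intensities incl. blanks) and
#'   `meta` (sample metadata tibble).
#' @param preprocess_cfg,sig_cfg,clock_cfg,classify_cfg,network_cfg Module
#'   configurations.
#' @param wd_cutoff Weeks-to-delivery cutoff for the classification stage
#'   (default 2).
#' @param network_top_n Number of top-changing features carried into the
#'   network stage (default 30).
#' @param seed Global seed propagated into every stochastic stage.
#' @return A named list with each stage's result: `preprocess`, `sam`,
#'   `slopes`, `network`, `clock`, `classification`, `deviation`,
#'   `correlations`.
#' @export
run_pipeline <- function(cohort,
                         preprocess_cfg = preprocess_config(),
                         sig_cfg = sig_config(),
                         clock_cfg = clock_config(),
                         classify_cfg = classify_config(),
                         network_cfg = network_config(),
                         wd_cutoff = 2,
                         network_top_n = 30,
                         seed = 1L) {
  seed <- as.integer(seed)
  sig_cfg$seed <- seed
  clock_cfg$seed <- seed
  classify_cfg$seed <- seed
  meta <- cohort$meta

  pre <- run_preprocess(cohort$table, meta, preprocess_cfg)
  tab <- pre$table
  m <- meta |> filter(.data$sample_id %in% colnames(tab), !.data$is_blank)
  tab <- tab[, m$sample_id, drop = FALSE]

  preg <- !m$is_postpartum
  sam <- sam_quantitative(tab[, preg, drop = FALSE],
                          m$ga_ultrasound_weeks[preg], sig_cfg)
  slopes <- slope_filter(tab[, preg, drop = FALSE],
                         m$ga_ultrasound_weeks[preg], sig_cfg)

  top <- slopes |>
    inner_join(sam, by = "feature_id") |>
    filter(.data$top_changer, .data$significant) |>
    arrange(desc(abs(.data$slope))) |>
    head(network_top_n)
  network <- if (nrow(top) >= 3) {
    ebic_glasso(t(tab[top$feature_id, preg, drop = FALSE]), network_cfg)
  } else NULL

  X <- t(tab[, preg, drop = FALSE])
  clock <- run_clock_pipeline(X, m$ga_ultrasound_weeks[preg],
                              m$subject_id[preg], cfg = clock_cfg)

  classification <- tryCatch(
    run_classification(tab, m, "weeks_to_delivery", wd_cutoff, classify_cfg),
    error = function(e) {
      warn(paste0("classification stage skipped: ", conditionMessage(e)))
      NULL
    })

  subjects <- m |>
    filter(!.data$is_postpartum) |>
    distinct(.data$subject_id, .data$birth_weight_g, .data$delivery_ga_weeks,
             .data$natural_onset)
  records <- per_subject_deviation(clock$cv_predictions, subjects)
  records$birthweight_residual <- birthweight_residuals(
    records$birth_weight_g, records$delivery_ga_weeks)
  correlations <- bind_rows(
    correlate_deviation(records, "birthweight_residual"),
    correlate_deviation(records, "delivery_ga")
  )

  list(preprocess = pre, sam = sam, slopes = slopes, network = network,
       clock = clock, classification = classification,
       deviation = records, correlations = correlations,
       meta = m)
}
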