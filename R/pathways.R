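# Pathway activity over gestational time windows ------------------------------

#' Quantify pathway activity across gestational time windows
#'
#' For each pathway with at least `min_compounds` mapped compounds, activity
#' in a time window is the mean over its mapped compounds and the samples in
#' the window. Windows are integer adjusted-GA weeks from `baseline_week` to
#' 40 plus a postpartum (`"PP"`) window; all samples earlier than
#' `baseline_week` are pooled into the baseline, which is reported as the
#' `baseline_week` column, and every later window is reported as activity
#' minus baseline (so the baseline column is identically 0). When several
#' features map to one compound they are averaged into a compound profile
#' first.
#'
#' @param mat Log2-normalized feature matrix (features x samples).
#' @param pathway_map Tibble: `pathway_id`, `pathway_name`, `compound_id`.
#' @param annotations Tibble mapping `feature_id` to `compound` (as from
#'   [annotate_features()]).
#' @param adjusted_ga Adjusted GA per sample (delivery scaled to 40 weeks).
#' @param is_postpartum Logical per sample.
#' @param baseline_week Baseline cut (default 14).
#' @param min_compounds Minimum mapped compounds per pathway (default 3).
#' @return Tibble: `pathway_id`, `pathway_name`, `window`, `activity`,
#'   `n_compounds`.
#' @export
pathway_activity <- function(mat, pathway_map, annotations, adjusted_ga,
                             is_postpartum, baseline_week = 14,
                             min_compounds = 3) {
  stopifnot(ncol(mat) == length(adjusted_ga))
  # compound profiles: average features mapped to the same compound
  ann <- annotations |> filter(.data$feature_id %in% rownames(mat))
  if (nrow(ann) == 0) abort("no annotated features present in the table")
  cmp_profiles <- ann |>
    group_by(.data$compound) |>
    summarise(profile = list(colMeans(mat[.data$feature_id, , drop = FALSE])),
              .groups = "drop")
  cp <- do.call(rbind, cmp_profiles$profile)
  rownames(cp) <- cmp_profiles$compound

  pm <- pathway_map |> filter(.data$compound_id %in% rownames(cp))
  sizes <- pm |> count(.data$pathway_id, name = "n_compounds")
  small <- sizes$pathway_id[sizes$n_compounds < min_compounds]
  if (length(small) > 0)
    warn(sprintf("excluding %d pathway(s) with < %d mapped compounds",
                 length(small), min_compounds))
  pm <- pm |> filter(!.data$pathway_id %in% small)
  if (nrow(pm) == 0) abort("no pathway retains enough mapped compounds")

  window <- ifelse(is_postpartum, "PP",
                   as.character(pmax(floor(adjusted_ga), baseline_week)))
  window[!is_postpartum & adjusted_ga < baseline_week] <-
    as.character(baseline_week)
  baseline_cols <- !is_postpartum & adjusted_ga < baseline_week
  if (!any(baseline_cols)) abort("no samples before the baseline week")

  pm |>
    group_by(.data$pathway_id, .data$pathway_name) |>
    reframe({
      sub <- cp[unique(.data$compound_id), , drop = FALSE]
      col_act <- colMeans(sub)
      base <- mean(col_act[baseline_cols])
      act <- tapply(col_act, window, mean) - base
      act[as.character(baseline_week)] <- mean(col_act[baseline_cols]) - base
      tibble(window = names(act), activity = as.numeric(act),
             n_compounds = nrow(sub))
    }) |>
    ungroup()
}
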