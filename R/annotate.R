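# MS/MS annotation ------------------------------------------------------------
#
# Feature -> spectrum matching by accurate mass (ppm) and retention time,
# spectral similarity by a forward dot-product over tolerance-paired
# fragments with square-root intensity weighting, and identity assignment
# with tiered precedence: authentic standard > public-library MS/MS > MetDNA
# import (MSI levels 1 / 2 / 4).

#' Annotation configuration
#'
#' @param ms1_ppm MS1 accurate-mass tolerance in ppm (default 25).
#' @param rt_tol Retention-time tolerance in seconds (default 30).
#' @param standard_ppm Stricter mass tolerance for authentic standards
#'   (default 5 ppm).
#' @param fragment_tol_da Fragment m/z pairing tolerance in Da (default
#'   0.02, an Orbitrap-typical convention; config-exposed because the
#'   dot-product literature varies).
#' @param similarity_min Similarity score cutoff for a library (MSI level 2)
#'   identification (default 0.5).
#' @return An `annotation_config` list.
#' @export
annotation_config <- function(ms1_ppm = 25, rt_tol = 30, standard_ppm = 5,
                              fragment_tol_da = 0.02, similarity_min = 0.5) {
  if (any(c(ms1_ppm, rt_tol, standard_ppm, fragment_tol_da) <= 0))
    abort("all tolerances must be > 0")
  if (similarity_min < 0 || similarity_min > 1)
    abort("`similarity_min` in [0, 1]")
  structure(list(ms1_ppm = ms1_ppm, rt_tol = rt_tol,
                 standard_ppm = standard_ppm,
                 fragment_tol_da = fragment_tol_da,
                 similarity_min = similarity_min),
            class = "annotation_config")
}

#' Match a feature to candidate MS/MS spectra by mass and retention time
#'
#' Returns every spectrum whose precursor is within `ms1_ppm` of the
#' feature's m/z and whose retention time is within `rt_tol` seconds. When a
#' feature matches multiple spectra, all are returned.
#'
#' @param mz,rt Feature accurate mass and retention time (seconds).
#' @param spectra List of spectra.
#' @param cfg An [annotation_config()].
#' @param ppm Override tolerance (e.g. `cfg$standard_ppm` for standards).
#' @return Sub-list of `spectra` (possibly empty).
#' @export
match_candidates <- function(mz, rt, spectra, cfg = annotation_config(),
                             ppm = cfg$ms1_ppm) {
  if (mz <= 0) abort("feature m/z must be > 0")
  keep <- vapply(spectra, function(s) {
    abs(s$precursor_mz - mz) / mz <= ppm * 1e-6 && abs(s$rt - rt) <= cfg$rt_tol
  }, logical(1))
  spectra[keep]
}

#' Forward dot-product similarity between two MS/MS spectra
#'
#' Fragments are greedily paired by nearest m/z within `fragment_tol_da`
#' (each fragment used at most once). Intensities are base-peak normalized
#' and square-root weighted; the score is the cosine of the paired weights
#' with unpaired fragments contributing only to the norms, so it lies in
#' \[0, 1\], is symmetric, and is invariant to global intensity rescaling of
#' either spectrum.
#'
#' @param query,library_spectrum Spectra (fields `mz`, `intensity`).
#' @param cfg An [annotation_config()].
#' @return Similarity score in \[0, 1\].
#' @export
forward_dot_product <- function(query, library_spectrum,
                                cfg = annotation_config()) {
  wq <- sqrt(query$intensity / max(query$intensity))
  wl <- sqrt(library_spectrum$intensity / max(library_spectrum$intensity))
  if (!all(is.finite(wq)) || !all(is.finite(wl)) ||
      max(query$intensity) <= 0 || max(library_spectrum$intensity) <= 0)
    abort("spectra must contain positive intensities")
  # candidate pairs within tolerance, greedily accepted by |dmz|
  dmz <- abs(outer(query$mz, library_spectrum$mz, "-"))
  cand <- which(dmz <= cfg$fragment_tol_da, arr.ind = TRUE)
  num <- 0
  if (nrow(cand) > 0) {
    cand <- cand[order(dmz[cand]), , drop = FALSE]
    used_q <- logical(length(wq)); used_l <- logical(length(wl))
    for (i in seq_len(nrow(cand))) {
      qi <- cand[i, 1]; li <- cand[i, 2]
      if (!used_q[qi] && !used_l[li]) {
        used_q[qi] <- TRUE; used_l[li] <- TRUE
        num <- num + wq[qi] * wl[li]
      }
    }
  }
  num / (sqrt(sum(wq^2)) * sqrt(sum(wl^2)))
}

#' Assign an identity to a feature from scored candidates
#'
#' Precedence: authentic standard (MSI level 1) > public-library MS/MS match
#' with similarity >= `similarity_min` (MSI level 2) > imported MetDNA call
#' (MSI level 4). Within a tier the highest similarity wins; ties break by
#' smaller |delta m/z| then lexicographic compound name. Features failing
#' all tiers remain unannotated (`NULL`).
#'
#' @param candidates Tibble with columns `compound`, `evidence` (one of
#'   `standard`, `msms`, `metdna_import`), `similarity`, `dmz_ppm`.
#' @param cfg An [annotation_config()].
#' @return One-row tibble (`compound`, `msi_level`, `similarity`,
#'   `evidence`) or `NULL`.
#' @export
assign_identity <- function(candidates, cfg = annotation_config()) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  tiers <- list(
    list(evidence = "standard", level = 1L, min_sim = -Inf),
    list(evidence = "msms", level = 2L, min_sim = cfg$similarity_min),
    list(evidence = "metdna_import", level = 4L, min_sim = -Inf)
  )
  for (tier in tiers) {
    hits <- candidates |>
      filter(.data$evidence == tier$evidence,
             is.na(.data$similarity) | .data$similarity >= tier$min_sim)
    if (tier$evidence == "msms")
      hits <- filter(hits, .data$similarity >= tier$min_sim)
    if (nrow(hits) > 0) {
      best <- hits |>
        arrange(desc(.data$similarity), abs(.data$dmz_ppm), .data$compound) |>
        slice(1)
      return(tibble(compound = best$compound, msi_level = tier$level,
                    similarity = best$similarity, evidence = tier$evidence))
    }
  }
  NULL
}

#' Annotate a feature table against spectral libraries
#'
#' For each feature: MS1/RT-match query spectra, score each matched query
#' against library spectra by [forward_dot_product()], add
#' standards (matched at `standard_ppm`) and imported MetDNA calls, then
#' apply the tiered precedence of [assign_identity()].
#'
#' @param features Tibble with `feature_id`, `mz`, `rt_seconds`.
#' @param queries List of query MS/MS spectra (e.g. from [read_mgf()]).
#' @param library_spectra List of library spectra whose `id` is the compound
#'   name.
#' @param standards Optional tibble (`compound`, `mz`, `rt_seconds`) of
#'   authentic standards.
#' @param metdna Optional tibble (`feature_id`, `compound`) of imported
#'   MetDNA identifications (never computed here; MetDNA is external).
#' @param cfg An [annotation_config()].
#' @return Tibble: `feature_id`, `compound`, `msi_level`, `similarity`,
#'   `evidence` (annotated features only).
#' @export
annotate_features <- function(features, queries, library_spectra,
                              standards = NULL, metdna = NULL,
                              cfg = annotation_config()) {
  purrr::pmap_dfr(
    features[c("feature_id", "mz", "rt_seconds")],
    function(feature_id, mz, rt_seconds) {
      cand <- list()
      qs <- match_candidates(mz, rt_seconds, queries, cfg)
      if (length(qs) > 0) {
        for (q in qs) {
          ls <- match_candidates(mz, rt_seconds, library_spectra, cfg)
          for (l in ls) {
            cand[[length(cand) + 1]] <- tibble(
              compound = l$id, evidence = "msms",
              similarity = forward_dot_product(q, l, cfg),
              dmz_ppm = abs(l$precursor_mz - mz) / mz * 1e6
            )
          }
        }
      }
      if (!is.null(standards)) {
        hit <- standards |>
          filter(abs(.data$mz - .env$mz) / .env$mz <= cfg$standard_ppm * 1e-6,
                 abs(.data$rt_seconds - .env$rt_seconds) <= cfg$rt_tol)
        if (nrow(hit) > 0)
          cand[[length(cand) + 1]] <- tibble(
            compound = hit$compound, evidence = "standard",
            similarity = NA_real_,
            dmz_ppm = abs(hit$mz - mz) / mz * 1e6
          )
      }
      if (!is.null(metdna)) {
        hit <- metdna[metdna$feature_id == feature_id, ]
        if (nrow(hit) > 0)
          cand[[length(cand) + 1]] <- tibble(
            compound = hit$compound, evidence = "metdna_import",
            similarity = NA_real_, dmz_ppm = 0
          )
      }
      ann <- assign_identity(bind_rows(cand), cfg)
      if (is.null(ann)) return(NULL)
      bind_cols(tibble(feature_id = feature_id), ann)
    }
  )
}
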