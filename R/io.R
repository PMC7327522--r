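# Text I/O: feature tables, sample metadata, MGF spectra ----------------------

#' Write / read a feature intensity table
#'
#' Rows are features (leading columns `feature_id`, `mz`, `rt_seconds`,
#' `mode`, optionally `class`), remaining columns are samples; an empty cell
#' encodes a missing value. Round-trips losslessly (including the missing
#' mask) through [read_feature_table()].
#'
#' @param mat Features x samples numeric matrix (`NA` = missing) with
#'   dimnames.
#' @param features Tibble of feature metadata, first column `feature_id`
#'   matching `rownames(mat)`.
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(mat, features, path) {
  stopifnot(is.matrix(mat), nrow(mat) == nrow(features),
            all(rownames(mat) == features$feature_id))
  df <- bind_cols(features, as_tibble(mat))
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @return For `read_feature_table()`: list with `table` (matrix) and
#'   `features` (tibble).
#' @export
read_feature_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- intersect(c("feature_id", "mz", "rt_seconds", "mode", "class"),
                         names(df))
  features <- df[meta_cols]
  mat <- as.matrix(df[setdiff(names(df), meta_cols)])
  rownames(mat) <- features$feature_id
  list(table = mat, features = features)
}

#' Write / read per-sample metadata
#'
#' Columns: subject_id, sample_id, ga_ultrasound_weeks, delivery_ga_weeks,
#' batch, run_order, is_blank, is_postpartum, birth_weight_g, natural_onset.
#'
#' @param meta Sample metadata tibble.
#' @param path File path (tab-separated).
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path, na = "")
  invisible(path)
}

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    sample_id = readr::col_character(),
                    is_blank = readr::col_logical(),
                    is_postpartum = readr::col_logical(),
                    natural_onset = readr::col_logical(),
                    .default = readr::col_double()
                  ))
}

#' Write / read MS/MS spectra in MGF format
#'
#' Minimal Mascot Generic Format: one `BEGIN IONS`/`END IONS` block per
#' spectrum with `TITLE`, `PEPMASS`, `RTINSECONDS` headers and an m/z
#' intensity peak list.
#'
#' @param spectra List of spectra (fields `id`, `precursor_mz`, `rt`, `mz`,
#'   `intensity`, `source`).
#' @param path File path.
#' @export
write_mgf <- function(spectra, path) {
  lines <- purrr::map(spectra, function(s) {
    c("BEGIN IONS",
      paste0("TITLE=", s$id),
      paste0("PEPMASS=", format(s$precursor_mz, digits = 10)),
      paste0("RTINSECONDS=", format(s$rt, digits = 10)),
      sprintf("%.6f %.6g", s$mz, s$intensity),
      "END IONS", "")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' @rdname write_mgf
#' @param source Value for the `source` field of the spectra read.
#' @export
read_mgf <- function(path, source = "query") {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) abort("malformed MGF: unbalanced blocks")
  spectra <- purrr::map2(starts, ends, function(a, b) {
    block <- lines[(a + 1):(b - 1)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    peaks <- do.call(rbind, strsplit(trimws(block[!hdr]), "[ \t]+"))
    if (is.null(peaks)) abort("malformed MGF: spectrum without peaks")
    new_spectrum(
      id = vals[match("TITLE", keys)],
      precursor_mz = as.numeric(vals[match("PEPMASS", keys)]),
      rt = as.numeric(vals[match("RTINSECONDS", keys)]),
      mz = as.numeric(peaks[, 1]),
      intensity = as.numeric(peaks[, 2]),
      source = source
    )
  })
  names(spectra) <- vapply(spectra, `[[`, "", "id")
  spectra
}
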