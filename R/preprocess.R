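# Feature-table QC and normalization -----------------------------------------
#
# Fixed stage order: presence/SN filter -> log2 + run-median centering ->
# per-batch run-order drift correction -> per-batch median centering ->
# sparse-sample removal -> KNN imputation -> PCA QC. Each stage is a pure
# function of its inputs.

#' Preprocessing configuration
#'
#' @param presence_min Minimum fraction of non-blank samples in which a
#'   feature must be quantified (default 0.30; boundary inclusive).
#' @param snr_min Minimum ratio of a feature's median intensity to its blank
#'   (noise) median (default 2; boundary inclusive).
#' @param sample_missing_max Samples with a missing fraction strictly above
#'   this are dropped (default 0.50).
#' @param knn_k Number of nearest neighbour features for imputation.
#' @param pca_components Number of PCA axes retained for QC.
#' @param outlier_sd Score SD multiplier beyond which a sample is flagged.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(presence_min = 0.30, snr_min = 2,
                              sample_missing_max = 0.50, knn_k = 10,
                              pca_components = 2, outlier_sd = 4) {
  if (presence_min <= 0 || presence_min > 1) abort("`presence_min` in (0, 1]")
  if (snr_min <= 0) abort("`snr_min` must be > 0")
  if (knn_k < 1) abort("`knn_k` must be >= 1")
  structure(list(presence_min = presence_min, snr_min = snr_min,
                 sample_missing_max = sample_missing_max,
                 knn_k = as.integer(knn_k),
                 pca_components = as.integer(pca_components),
                 outlier_sd = outlier_sd),
            class = "preprocess_config")
}

#' Filter features by presence and signal-to-noise against blank runs
#'
#' Keeps a feature iff it is quantified (non-missing and > 0) in at least
#' `presence_min` of the non-blank samples AND its median intensity across
#' non-blank samples is at least `snr_min` times its noise level, where noise
#' is the median signal across blank runs. A feature with no quantitation in
#' any blank run passes the S/N criterion unconditionally (it likely has a
#' clean noise floor). Both boundaries are inclusive on the keep side.
#'
#' @param mat Raw linear-intensity matrix (features x samples, `NA` missing).
#' @param meta Sample metadata with `sample_id` and `is_blank`.
#' @param cfg A [preprocess_config()].
#' @return List: `table` (filtered matrix, blanks removed), `report` tibble
#'   of dropped features with a single `reason` code (`presence` or `snr`).
#' @export
filter_features <- function(mat, meta, cfg = preprocess_config()) {
  stopifnot(all(colnames(mat) %in% meta$sample_id))
  blank_ids <- meta$sample_id[meta$is_blank]
  bio <- mat[, setdiff(colnames(mat), blank_ids), drop = FALSE]
  quant <- !is.na(bio) & bio > 0
  presence <- rowMeans(quant)
  med <- apply(bio, 1, function(x) median(x[!is.na(x) & x > 0]))
  med[is.na(med)] <- 0

  if (length(intersect(blank_ids, colnames(mat))) == 0) {
    warn("no blank runs present; S/N criterion skipped")
    snr_ok <- rep(TRUE, nrow(mat))
  } else {
    blk <- mat[, intersect(blank_ids, colnames(mat)), drop = FALSE]
    noise <- apply(blk, 1, function(x) {
      x <- x[!is.na(x) & x > 0]
      if (length(x) == 0) NA_real_ else median(x)
    })
    snr_ok <- is.na(noise) | med >= cfg$snr_min * noise
  }
  presence_ok <- presence >= cfg$presence_min
  keep <- presence_ok & snr_ok
  report <- tibble(
    feature_id = rownames(mat)[!keep],
    reason = unname(ifelse(!presence_ok[!keep], "presence", "snr"))
  )
  list(table = bio[keep, , drop = FALSE], report = report)
}

#' Log2-transform and centre each run's median at zero
#'
#' For every sample (run), the median over its observed features is
#' subtracted, correcting for differences in total sample amount.
#'
#' @param mat Linear-intensity matrix, strictly positive where observed.
#' @return Log2-scale matrix with per-sample observed median 0.
#' @export
log_and_center_runs <- function(mat) {
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort(sprintf("non-positive intensity at feature %s, sample %s",
                  rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  lg <- log2(mat)
  med <- apply(lg, 2, median, na.rm = TRUE)
  sweep(lg, 2, med, "-")
}

#' Remove within-batch linear run-order drift
#'
#' For each feature and each batch, ordinary least squares of observed log
#' abundance on run order; the centred fit (fit minus its within-batch mean)
#' is subtracted so the within-batch mean is preserved. Missing cells stay
#' missing; feature/batch combinations with fewer than 3 observed values are
#' left unchanged.
#'
#' @param mat Log-scale matrix.
#' @param meta Metadata with `sample_id`, `batch`, `run_order`.
#' @return List: `table` (corrected matrix) and `drift` tibble
#'   (feature_id, batch, slope, intercept, n_obs).
#' @export
correct_drift <- function(mat, meta) {
  idx <- match(colnames(mat), meta$sample_id)
  if (anyNA(idx)) abort("samples in table missing from metadata")
  batch <- meta$batch[idx]
  if (anyNA(batch)) abort("unknown batch label")
  run <- meta$run_order[idx]
  out <- mat
  drift <- list()
  for (b in unique(batch)) {
    cols <- which(batch == b)
    r <- run[cols]
    sub <- mat[, cols, drop = FALSE]
    obs <- !is.na(sub)
    n_obs <- rowSums(obs)
    # vectorized per-feature OLS on observed cells
    sx <- obs %*% r
    sxx <- obs %*% r^2
    sub0 <- ifelse(obs, sub, 0)
    sy <- rowSums(sub0)
    sxy <- sub0 %*% r
    denom <- sxx - sx^2 / n_obs
    slope <- as.numeric((sxy - sx * sy / n_obs) / denom)
    slope[n_obs < 3 | abs(denom) < 1e-12] <- 0
    # subtract centred fit: slope * (r - mean of observed r per feature)
    rbar <- as.numeric(sx / n_obs)
    fit <- outer(slope, r) - slope * rbar
    out[, cols] <- sub - ifelse(obs, fit, NA)
    drift[[as.character(b)]] <- tibble(
      feature_id = rownames(mat), batch = b, slope = slope,
      intercept = as.numeric(sy / n_obs) - slope * rbar, n_obs = n_obs
    )
  }
  list(table = out, drift = bind_rows(drift))
}

#' Median-centre each feature within each batch
#'
#' After this, every feature's observed median is 0 in every batch,
#' correcting sensitivity differences between batches. Idempotent.
#'
#' @inheritParams correct_drift
#' @return Corrected matrix.
#' @export
center_batches <- function(mat, meta) {
  idx <- match(colnames(mat), meta$sample_id)
  batch <- meta$batch[idx]
  out <- mat
  for (b in unique(batch)) {
    cols <- which(batch == b)
    med <- apply(mat[, cols, drop = FALSE], 1, median, na.rm = TRUE)
    if (anyNA(med)) {
      warn(sprintf("batch %s has features with no observed values; left as-is",
                   b))
      med[is.na(med)] <- 0
    }
    out[, cols] <- sweep(mat[, cols, drop = FALSE], 1, med, "-")
  }
  out
}

#' Drop samples with too many missing values
#'
#' Samples whose missing fraction strictly exceeds `sample_missing_max` are
#' removed (a sample at exactly the boundary is kept).
#'
#' @param mat Feature matrix.
#' @param cfg A [preprocess_config()].
#' @return List: `table`, `dropped` (character vector of sample ids).
#' @export
drop_sparse_samples <- function(mat, cfg = preprocess_config()) {
  frac <- colMeans(is.na(mat))
  drop <- frac > cfg$sample_missing_max
  if (all(drop)) abort("all samples exceed the missingness limit")
  list(table = mat[, !drop, drop = FALSE], dropped = colnames(mat)[drop])
}

#' Impute missing values by k nearest neighbour features
#'
#' Each missing cell is replaced by the unweighted mean of the `knn_k`
#' nearest features (by Euclidean distance over samples observed in both,
#' rescaled by the square root of the overlap fraction so distances are
#' comparable across pairs), restricted to neighbours observed at that
#' sample. With fewer than k eligible neighbours all available are used; a
#' feature with zero overlap with every other feature falls back to its own
#' observed mean. Observed cells are never altered.
#'
#' @param mat Log-scale matrix, post-normalization.
#' @param cfg A [preprocess_config()].
#' @return Complete matrix.
#' @export
impute_knn <- function(mat, cfg = preprocess_config()) {
  p <- nrow(mat); n <- ncol(mat)
  obs <- !is.na(mat)
  if (all(obs)) return(mat)
  x0 <- ifelse(obs, mat, 0)
  # pairwise sums of squared differences over jointly observed samples
  overlap <- obs %*% t(obs)
  cross <- x0 %*% t(x0)
  sq <- (x0^2) %*% t(obs)
  ssq <- sq + t(sq) - 2 * cross
  d <- sqrt(pmax(ssq, 0) * n / pmax(overlap, 1))
  d[overlap == 0] <- Inf
  diag(d) <- Inf
  out <- mat
  row_means <- rowSums(x0) / pmax(rowSums(obs), 1)
  for (f in which(rowSums(!obs) > 0)) {
    nb_order <- order(d[f, ])
    nb_order <- nb_order[is.finite(d[f, nb_order])]
    for (s in which(!obs[f, ])) {
      eligible <- nb_order[obs[nb_order, s]]
      if (length(eligible) == 0) {
        warn(sprintf("feature %s: no eligible neighbours; using own mean",
                     rownames(mat)[f]))
        out[f, s] <- row_means[f]
      } else {
        k <- head(eligible, cfg$knn_k)
        out[f, s] <- mean(mat[k, s])
      }
    }
  }
  out
}

#' PCA quality control with outlier flagging
#'
#' Principal components of the samples on feature-centred (unscaled) data.
#' A sample is flagged when its score on any retained axis exceeds
#' `outlier_sd` times that axis's score SD.
#'
#' @param mat Complete (imputed) log-scale matrix.
#' @param cfg A [preprocess_config()].
#' @return List: `scores` tibble (sample_id, PC columns, outlier flag) and
#'   `variance` (fraction of variance per retained axis).
#' @export
pca_qc <- function(mat, cfg = preprocess_config()) {
  k <- cfg$pca_components
  if (ncol(mat) <= k) abort("fewer samples than requested components")
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  sds <- apply(scores, 2, sd)
  flag <- rowSums(abs(scores) > rep(cfg$outlier_sd * sds,
                                    each = nrow(scores)) &
                    rep(sds > 0, each = nrow(scores))) > 0
  list(
    scores = bind_cols(tibble(sample_id = colnames(mat)),
                       as_tibble(scores), tibble(outlier = flag)),
    variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  )
}

#' Run the full preprocessing pipeline
#'
#' filter -> log2/run-median centre -> drift correction -> batch centring ->
#' sparse-sample removal -> KNN imputation -> PCA QC (optionally excluding
#' flagged outliers).
#'
#' @param mat Raw linear-intensity matrix including blank runs.
#' @param meta Sample metadata tibble.
#' @param cfg A [preprocess_config()].
#' @param drop_outliers Exclude PCA-flagged samples from the returned table.
#' @return List: `table` (processed complete matrix, biological samples
#'   only), `report` (filter report, drift table, dropped samples), `qc`
#'   (PCA scores and variance fractions).
#' @export
run_preprocess <- function(mat, meta, cfg = preprocess_config(),
                           drop_outliers = TRUE) {
  filt <- filter_features(mat, meta, cfg)
  lg <- log_and_center_runs(filt$table)
  dr <- correct_drift(lg, meta)
  bc <- center_batches(dr$table, meta)
  ds <- drop_sparse_samples(bc, cfg)
  imp <- impute_knn(ds$table, cfg)
  qc <- pca_qc(imp, cfg)
  tab <- imp
  if (drop_outliers && any(qc$scores$outlier)) {
    out_ids <- qc$scores$sample_id[qc$scores$outlier]
    tab <- tab[, setdiff(colnames(tab), out_ids), drop = FALSE]
  }
  list(
    table = tab,
    report = list(dropped_features = filt$report, drift = dr$drift,
                  dropped_samples = ds$dropped,
                  outlier_samples = qc$scores$sample_id[qc$scores$outlier]),
    qc = qc
  )
}
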