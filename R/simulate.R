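# Synthetic cohort generator -------------------------------------------------
#
# Emulates the statistical structure of a weekly-sampled pregnancy
# metabolomics cohort: ~30 subjects sampled weekly from week 5 until delivery
# plus one postpartum draw, ~10^3 log-normal LC-MS features in qualitative
# trajectory classes, additive per-feature batch offsets, within-batch linear
# run-order drift, intensity-dependent (MNAR) missingness, blank runs, and a
# latent per-subject clock offset coupled to delivery timing and birth weight.

#' Configuration for the synthetic pregnancy cohort
#'
#' Defaults define the study conditions used throughout the package's tests:
#' 30 subjects, 1000 features in four trajectory classes
#' (linear-increasing, linear-decreasing, early-saturating, null), 12
#' analytical batches, weekly visits attended with probability
#' `attend_prob`, delivery drawn from Normal(40, 1.2) truncated to [37, 42]
#' weeks and advanced by `kappa` weeks per week of latent clock offset.
#'
#' @param n_subjects Number of pregnant subjects (>= 2).
#' @param p_features Number of metabolic features (>= 10).
#' @param class_fractions Named proportions for classes
#'   `increasing`, `decreasing`, `saturating`, `null`; must sum to 1.
#' @param n_batches Number of analytical batches.
#' @param sigma_batch SD of per-feature-per-batch log2 offsets.
#' @param sigma_drift SD of per-feature-per-batch log2 drift slopes
#'   (per unit run order).
#' @param sigma_noise Residual log2 SD per measurement.
#' @param sigma_offset SD (weeks) of the latent per-subject clock offset
#'   delta_i; a subject's metabolic age is `GA + delta_i`.
#' @param kappa Weeks of delivery advance per week of clock offset
#'   (delivery GA is shifted by `-kappa * delta_i`).
#' @param beta_weight Grams of birth weight per week of clock offset.
#' @param mnar_threshold,mnar_scale Intensity-dependent missingness:
#'   `P(missing) = plogis((mnar_threshold - log2 intensity) / mnar_scale)`.
#' @param attend_prob Probability that a scheduled weekly visit was attended.
#' @param n_clock_features Size of the dominant "clock panel": a small
#'   family of steroid-like features with large gestational fold changes
#'   (log2 slope 0.07-0.10/week), mutually correlated through a shared
#'   per-sample family factor and with low independent noise. Emulates the
#'   dense central steroid cluster that carries most of the
#'   gestational-timing signal in real pregnancy metabolomes; the remaining
#'   informative features change modestly (slope 0.016-0.035) with larger
#'   independent variation.
#' @param labor_amplitude,labor_frac,labor_tau Pre-delivery surge: a fraction
#'   `labor_frac` of increasing-class features additionally rise by
#'   `labor_amplitude * exp(-WD / labor_tau)` log2 units as weeks-to-delivery
#'   (WD) approaches 0. Set `labor_amplitude = 0` to disable.
#' @param natural_onset_prob Probability a subject has natural labor onset.
#' @param blanks_per_batch Number of blank (no-sample) runs per batch.
#' @param seed Integer seed; the single RNG stream for all stochastic steps.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 30,
                          p_features = 1000,
                          class_fractions = c(increasing = 0.3,
                                              decreasing = 0.3,
                                              saturating = 0.1,
                                              null = 0.3),
                          n_batches = 12,
                          sigma_batch = 0.4,
                          sigma_drift = 0.01,
                          sigma_noise = 0.5,
                          sigma_offset = 1.25,
                          kappa = 0.55,
                          beta_weight = 400,
                          mnar_threshold = 13,
                          mnar_scale = 1.5,
                          attend_prob = 0.7,
                          n_clock_features = 5,
                          labor_amplitude = 1.2,
                          labor_frac = 0.05,
                          labor_tau = 3,
                          natural_onset_prob = 0.6,
                          blanks_per_batch = 2,
                          seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2")
  if (p_features < 10) abort("`p_features` must be >= 10")
  if (n_batches < 1 || blanks_per_batch < 0) abort("invalid batch settings")
  needed <- c("increasing", "decreasing", "saturating", "null")
  if (!all(needed %in% names(class_fractions)))
    abort("`class_fractions` must name increasing/decreasing/saturating/null")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    abort("`class_fractions` must sum to 1")
  if (any(class_fractions < 0)) abort("`class_fractions` must be >= 0")
  sds <- c(sigma_batch, sigma_drift, sigma_noise, sigma_offset)
  if (any(sds < 0)) abort("all SDs must be >= 0")
  if (attend_prob <= 0 || attend_prob > 1) abort("`attend_prob` in (0, 1]")
  structure(list(
    n_subjects = as.integer(n_subjects), p_features = as.integer(p_features),
    class_fractions = class_fractions, n_batches = as.integer(n_batches),
    sigma_batch = sigma_batch, sigma_drift = sigma_drift,
    sigma_noise = sigma_noise, sigma_offset = sigma_offset,
    kappa = kappa, beta_weight = beta_weight,
    mnar_threshold = mnar_threshold, mnar_scale = mnar_scale,
    attend_prob = attend_prob,
    n_clock_features = as.integer(n_clock_features),
    labor_amplitude = labor_amplitude, labor_frac = labor_frac,
    labor_tau = labor_tau,
    natural_onset_prob = natural_onset_prob,
    blanks_per_batch = as.integer(blanks_per_batch),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  # inverse-CDF truncated normal; exact and draws one uniform per value
  u <- runif(n)
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Simulate subject-level ground truth
#'
#' Draws the per-subject latent clock offset delta_i, delivery gestational
#' age (shifted earlier by `kappa * delta_i`), birth weight (coupled to
#' delta_i through `beta_weight`), and the natural-labor-onset flag. Called
#' internally by [generate_cohort()]; exported because subject-level
#' simulations are useful on their own (e.g. null calibration of the
#' deviation analysis).
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per subject: `subject_id`, `delta`,
#'   `delivery_ga_weeks`, `birth_weight_g`, `natural_onset`.
#' @export
simulate_subjects <- function(config) {
  n <- config$n_subjects
  delta <- rnorm(n, 0, config$sigma_offset)
  base_delivery <- rnorm_trunc(n, 40, 1.2, 37, 42)
  delivery <- base_delivery - config$kappa * delta
  bw <- -3160 + 170 * delivery + config$beta_weight * delta + rnorm(n, 0, 120)
  tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    delta = delta,
    delivery_ga_weeks = delivery,
    birth_weight_g = bw,
    natural_onset = runif(n) < config$natural_onset_prob
  )
}

feature_trajectory <- function(class, slope, amplitude, midpoint, steep, t) {
  # t = metabolic age in weeks; value relative to the feature's intercept
  switch(class,
    increasing = slope * (t - 5),
    decreasing = slope * (t - 5),
    saturating = amplitude * logistic((t - midpoint) / steep),
    null = rep(0, length(t)),
    abort(paste0("unknown trajectory class: ", class))
  )
}

#' Generate a synthetic pregnancy metabolomics cohort
#'
#' Produces a raw (linear-intensity) feature table with MNAR missingness and
#' blank runs, the per-sample metadata, and the generator's ground truth.
#' Weekly samples run from week 5 through each subject's delivery plus one
#' postpartum sample at delivery + 6 weeks; feature log2 abundance is
#' intercept + trajectory(metabolic age) + batch offset + drift x run order +
#' noise, with pregnancy trajectories reverting to baseline postpartum.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `table` (features x samples intensity matrix,
#'   `NA` = missing), `features` (tibble: feature_id, mz, rt_seconds, mode,
#'   class), `meta` (per-sample tibble), and `truth` (list with `subjects`,
#'   `features` incl. true slopes, `batch_offsets`, `drift_slopes`,
#'   `clean_log2` (intercept + trajectory, pregnancy+PP samples only),
#'   `missing_mask`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  subjects <- simulate_subjects(config)

  # visit schedule: week 5 .. floor(delivery), attended w.p. attend_prob
  # (week 5 and the final pre-delivery week always attended), plus PP draw
  samples <- purrr::pmap_dfr(subjects, function(subject_id, delta,
                                                delivery_ga_weeks,
                                                birth_weight_g,
                                                natural_onset) {
    weeks <- seq(5, floor(delivery_ga_weeks))
    keep <- runif(length(weeks)) < config$attend_prob
    keep[c(1, length(weeks))] <- TRUE
    ga <- c(weeks[keep], delivery_ga_weeks + 6)
    tibble(
      subject_id = subject_id,
      ga_ultrasound_weeks = ga,
      is_postpartum = c(rep(FALSE, sum(keep)), TRUE),
      delivery_ga_weeks = delivery_ga_weeks,
      birth_weight_g = birth_weight_g,
      natural_onset = natural_onset
    )
  })
  n_bio <- nrow(samples)

  # features
  p <- config$p_features
  n_class <- round(config$class_fractions * p)
  n_class["null"] <- p - sum(n_class[c("increasing", "decreasing",
                                       "saturating")])
  class <- rep(c("increasing", "decreasing", "saturating", "null"),
               times = n_class[c("increasing", "decreasing", "saturating",
                                 "null")])
  class <- sample(class)
  slope <- numeric(p)
  amplitude <- numeric(p)
  slope[class == "increasing"] <- runif(sum(class == "increasing"),
                                        0.012, 0.025)
  slope[class == "decreasing"] <- -runif(sum(class == "decreasing"),
                                         0.012, 0.025)
  n_sat <- sum(class == "saturating")
  amplitude[class == "saturating"] <- runif(n_sat, 0.3, 0.7)
  midpoint <- rep(18, p)
  steep <- rep(3, p)
  midpoint[class == "saturating"] <- rnorm(n_sat, 18, 3)
  steep[class == "saturating"] <- runif(n_sat, 2.5, 4)
  # the dominant clock panel: steroid-like large fold changes, correlated
  # through a shared family factor, low independent noise
  lin_idx <- which(class %in% c("increasing", "decreasing"))
  clock_idx <- sample(lin_idx, min(config$n_clock_features, length(lin_idx)))
  clock_panel <- rep(FALSE, p)
  clock_panel[clock_idx] <- TRUE
  slope[clock_idx] <- sign(slope[clock_idx]) *
    runif(length(clock_idx), 0.07, 0.10)
  # secant slope equivalent for saturating features (used by recovery tests)
  sat <- class == "saturating"
  slope[sat] <- amplitude[sat] *
    (logistic((40 - midpoint[sat]) / steep[sat]) -
       logistic((5 - midpoint[sat]) / steep[sat])) / 35
  intercept <- runif(p, 11, 24)
  inc_idx <- which(class == "increasing")
  n_labor <- min(length(inc_idx), round(config$labor_frac * p))
  labor <- rep(FALSE, p)
  if (config$labor_amplitude > 0 && n_labor > 0)
    labor[sample(inc_idx, n_labor)] <- TRUE
  blank_absent <- runif(p) < 0.3
  blank_delta <- rnorm(p, 5, 1.5) # log2 distance of blank level below intercept

  features <- tibble(
    feature_id = sprintf("F%04d", seq_len(p)),
    mz = round(runif(p, 70, 1200), 4),
    rt_seconds = round(runif(p, 20, 600), 1),
    mode = sample(c("pos", "neg"), p, replace = TRUE),
    class = class
  )

  # batch / run-order assignment: biological samples randomized across
  # batches; blanks interleaved within each batch
  batch_of <- sample(rep(seq_len(config$n_batches), length.out = n_bio))
  # build blank rows
  blanks <- tibble(
    subject_id = NA_character_,
    ga_ultrasound_weeks = NA_real_,
    is_postpartum = FALSE,
    delivery_ga_weeks = NA_real_,
    birth_weight_g = NA_real_,
    natural_onset = NA,
    batch = rep(seq_len(config$n_batches), each = config$blanks_per_batch)
  )
  samples$batch <- batch_of
  samples$is_blank <- FALSE
  blanks$is_blank <- TRUE
  meta <- bind_rows(samples, blanks)
  meta <- meta |>
    group_by(.data$batch) |>
    mutate(run_order = sample.int(n())) |>
    ungroup() |>
    arrange(.data$batch, .data$run_order) |>
    mutate(sample_id = ifelse(.data$is_blank,
                              sprintf("BLK_%02d_%02d", .data$batch,
                                      .data$run_order),
                              sprintf("%s_W%04.1f", .data$subject_id,
                                      .data$ga_ultrasound_weeks))) |>
    select("subject_id", "sample_id", "ga_ultrasound_weeks",
           "delivery_ga_weeks", "batch", "run_order", "is_blank",
           "is_postpartum", "birth_weight_g", "natural_onset")

  delta_of <- setNames(subjects$delta, subjects$subject_id)

  # clean log2 signal (biological samples): intercept + trajectory(t)
  bio <- meta[!meta$is_blank, ]
  t_met <- bio$ga_ultrasound_weeks + delta_of[bio$subject_id]
  wd <- pmax(bio$delivery_ga_weeks - bio$ga_ultrasound_weeks, 0)
  clean <- matrix(intercept, nrow = p, ncol = nrow(bio))
  for (f in seq_len(p)) {
    traj <- feature_trajectory(class[f], slope[f], amplitude[f],
                               midpoint[f], steep[f], t_met)
    if (labor[f])
      traj <- traj + config$labor_amplitude * exp(-wd / config$labor_tau)
    traj[bio$is_postpartum] <- 0 # revert to baseline after delivery
    clean[f, ] <- clean[f, ] + traj
  }
  rownames(clean) <- features$feature_id
  colnames(clean) <- bio$sample_id

  batch_offsets <- matrix(rnorm(p * config$n_batches, 0, config$sigma_batch),
                          p, config$n_batches)
  drift_slopes <- matrix(rnorm(p * config$n_batches, 0, config$sigma_drift),
                         p, config$n_batches)

  # assemble observed log2 matrix over all runs (biological + blank)
  log2_mat <- matrix(NA_real_, p, nrow(meta),
                     dimnames = list(features$feature_id, meta$sample_id))
  bio_cols <- match(bio$sample_id, meta$sample_id)
  log2_mat[, bio_cols] <- clean
  blank_cols <- which(meta$is_blank)
  if (length(blank_cols) > 0) {
    blank_level <- intercept - blank_delta
    log2_mat[, blank_cols] <- blank_level +
      matrix(rnorm(p * length(blank_cols), 0, 0.1), p)
  }
  log2_mat <- log2_mat + batch_offsets[, meta$batch] +
    drift_slopes[, meta$batch] * rep(meta$run_order, each = p)
  if (config$sigma_noise > 0) {
    # clock-panel features: low independent noise plus a shared per-sample
    # family factor; bulk features: independent noise at sigma_noise. Both
    # terms scale with sigma_noise so a zero-noise cohort is exactly clean.
    noise_sd <- ifelse(clock_panel, 0.24 * config$sigma_noise,
                       config$sigma_noise)
    log2_mat[, bio_cols] <- log2_mat[, bio_cols] +
      matrix(rnorm(p * length(bio_cols), 0, noise_sd), p)
    u_fam <- rnorm(length(bio_cols), 0, 0.6 * config$sigma_noise)
    loading <- sign(slope[clock_idx]) * abs(slope[clock_idx]) / 0.085
    log2_mat[clock_idx, bio_cols] <- log2_mat[clock_idx, bio_cols] +
      outer(loading, u_fam)
  }

  # MNAR masking on biological runs; blanks: structurally absent features
  p_miss <- plogis((config$mnar_threshold - log2_mat) / config$mnar_scale)
  miss <- matrix(runif(length(p_miss)) < p_miss, p)
  miss[blank_absent, blank_cols] <- TRUE

  intensities <- 2^log2_mat
  intensities[miss] <- NA_real_

  truth_features <- features |>
    mutate(slope = .env$slope, amplitude = .env$amplitude,
           intercept = .env$intercept, labor_surge = .env$labor,
           clock_panel = .env$clock_panel, blank_absent = .env$blank_absent)

  list(
    table = intensities,
    features = features,
    meta = meta,
    truth = list(
      subjects = subjects,
      features = truth_features,
      batch_offsets = batch_offsets,
      drift_slopes = drift_slopes,
      clean_log2 = clean,
      missing_mask = miss
    )
  )
}

# MS/MS fixtures --------------------------------------------------------------

new_spectrum <- function(id, precursor_mz, rt, mz, intensity,
                         source = "query") {
  o <- order(mz)
  structure(list(id = id, precursor_mz = precursor_mz, rt = rt,
                 mz = mz[o], intensity = intensity[o], source = source),
            class = "ms2_spectrum")
}

#' Generate a small MS/MS spectral library with noisy queries and decoys
#'
#' Each library spectrum has 5-20 fragments; each true query is its library
#' spectrum with fragment m/z jitter (SD `mz_jitter`), multiplicative
#' intensity jitter, and additional low-intensity noise peaks. Decoy queries
#' share a library precursor m/z (so they pass MS1 matching) but carry
#' unrelated fragments.
#'
#' @param n_compounds Number of library compounds (>= 1).
#' @param n_decoys Number of decoy queries.
#' @param mz_jitter Fragment m/z jitter SD in Da (default 0.004, well inside
#'   the 0.02 Da matching tolerance).
#' @param intensity_jitter Log-normal SD of intensity jitter.
#' @param noise_peaks Mean number of Poisson noise peaks per query.
#' @param seed Integer seed.
#' @return List with `library` (list of spectra), `queries` (list of
#'   spectra), and `truth` (tibble: query_id, compound, is_decoy).
#' @export
generate_ms2_fixtures <- function(n_compounds, n_decoys = n_compounds,
                                  mz_jitter = 0.004, intensity_jitter = 0.2,
                                  noise_peaks = 3, seed = 1L) {
  if (n_compounds < 1) abort("`n_compounds` must be >= 1")
  set.seed(as.integer(seed))
  lib <- vector("list", n_compounds)
  for (i in seq_len(n_compounds)) {
    prec <- runif(1, 150, 800)
    k <- sample(5:20, 1)
    mz <- sort(runif(k, 50, prec - 1))
    int <- runif(k, 0.05, 1)
    int[which.max(int)] <- 1
    lib[[i]] <- new_spectrum(sprintf("CPD%03d", i), prec,
                             runif(1, 30, 600), mz, int,
                             source = "public_library")
  }
  queries <- list()
  truth <- list()
  for (i in seq_len(n_compounds)) {
    l <- lib[[i]]
    mz <- l$mz + rnorm(length(l$mz), 0, mz_jitter)
    int <- l$intensity * exp(rnorm(length(l$mz), 0, intensity_jitter))
    n_noise <- stats::rpois(1, noise_peaks)
    if (n_noise > 0) {
      mz <- c(mz, runif(n_noise, 50, l$precursor_mz - 1))
      int <- c(int, runif(n_noise, 0.01, 0.15))
    }
    qid <- sprintf("Q%03d", i)
    queries[[qid]] <- new_spectrum(qid, l$precursor_mz,
                                   l$rt + rnorm(1, 0, 3), mz, int)
    truth[[qid]] <- tibble(query_id = qid, compound = l$id, is_decoy = FALSE)
  }
  for (j in seq_len(n_decoys)) {
    tmpl <- lib[[sample.int(n_compounds, 1)]]
    k <- sample(5:20, 1)
    qid <- sprintf("DQ%03d", j)
    queries[[qid]] <- new_spectrum(qid, tmpl$precursor_mz,
                                   tmpl$rt + rnorm(1, 0, 3),
                                   sort(runif(k, 50, tmpl$precursor_mz - 1)),
                                   runif(k, 0.05, 1))
    truth[[qid]] <- tibble(query_id = qid, compound = tmpl$id, is_decoy = TRUE)
  }
  list(library = lib, queries = queries, truth = bind_rows(truth))
}

#' Build a synthetic pathway map over a set of compounds
#'
#' Assigns compounds round-robin to `n_pathways` pathways, guaranteeing at
#' least minimal overlap with realistic pathway sizes. Purely synthetic
#' plumbing for testing pathway-activity quantification.
#'
#' @param compound_ids Character vector of compound identifiers.
#' @param n_pathways Number of pathways.
#' @param seed Integer seed.
#' @return Tibble: `pathway_id`, `pathway_name`, `compound_id`.
#' @export
make_pathway_map <- function(compound_ids, n_pathways = 5, seed = 1L) {
  set.seed(as.integer(seed))
  assign <- sample(rep(seq_len(n_pathways), length.out = length(compound_ids)))
  tibble(
    pathway_id = sprintf("PW%02d", assign),
    pathway_name = sprintf("synthetic pathway %02d", assign),
    compound_id = compound_ids
  ) |> arrange(.data$pathway_id)
}

#' Write cohort fixtures to delimited text and MGF
#'
#' Writes the feature table (rows = features with id/mz/rt/mode; columns =
#' samples; empty cell = missing), sample metadata, and optionally spectra as
#' MGF so that everything round-trips losslessly through the io layer.
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Directory to write into (created if absent).
#' @param spectra Optional list of spectra to write as `spectra.mgf`.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(cohort, path, spectra = NULL) {
  if (nrow(cohort$table) == 0 || ncol(cohort$table) == 0)
    abort("refusing to write an empty feature table")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    features = file.path(path, "features.tsv"),
    meta = file.path(path, "sample_meta.tsv")
  )
  write_feature_table(cohort$table, cohort$features, paths[["features"]])
  write_sample_meta(cohort$meta, paths[["meta"]])
  if (!is.null(spectra)) {
    paths[["mgf"]] <- file.path(path, "spectra.mgf")
    write_mgf(spectra, paths[["mgf"]])
  }
  invisible(paths)
}
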