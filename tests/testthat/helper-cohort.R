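# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small cohort for module-level tests
small_cohort <- function() {
  cached_fixture("small", generate_cohort(
    cohort_config(n_subjects = 12, p_features = 120, n_batches = 4,
                  seed = 101L)))
}

small_processed <- function() {
  cached_fixture("small_processed", {
    co <- small_cohort()
    pre <- suppressWarnings(run_preprocess(co$table, co$meta))
    m <- dplyr::filter(co$meta, .data$sample_id %in% colnames(pre$table),
                       !.data$is_blank)
    list(cohort = co, tab = pre$table[, m$sample_id], meta = m)
  })
}

# the default study-conditions cohort used by the acceptance checks
default_cohort <- function() {
  cached_fixture("default", generate_cohort(cohort_config(seed = 2024L)))
}

default_processed <- function() {
  cached_fixture("default_processed", {
    co <- default_cohort()
    pre <- suppressWarnings(run_preprocess(co$table, co$meta))
    m <- dplyr::filter(co$meta, .data$sample_id %in% colnames(pre$table),
                       !.data$is_blank)
    list(cohort = co, pre = pre, tab = pre$table[, m$sample_id], meta = m)
  })
}

default_clock <- function() {
  cached_fixture("default_clock", {
    dp <- default_processed()
    preg <- !dp$meta$is_postpartum
    run_clock_pipeline(t(dp$tab[, preg, drop = FALSE]),
                       dp$meta$ga_ultrasound_weeks[preg],
                       dp$meta$subject_id[preg],
                       cfg = clock_config(seed = 2024L))
  })
}

make_meta <- function(ids, batch = 1L, run = seq_along(ids),
                      blank = FALSE) {
  tibble::tibble(sample_id = ids, batch = rep_len(batch, length(ids)),
                 run_order = run, is_blank = rep_len(blank, length(ids)))
}

# zero-measurement-noise table with injected per-feature batch offsets and
# linear run-order drift; intercepts spaced widely so the run-median feature
# is rank-stable (exact-recovery regime for the normalization stages)
make_artifact_cohort <- function(p = 21, n = 60, n_batch = 3, with_traj = 0,
                                 seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%03d", 1:n)
  batch <- rep(1:n_batch, length.out = n)
  run <- stats::ave(seq_len(n), batch, FUN = seq_along)
  ga <- runif(n, 5, 40)
  intercept <- seq(10, by = 2, length.out = p)
  slope <- runif(p, -with_traj, with_traj)
  clean <- outer(slope, ga) + intercept
  off <- matrix(runif(p * n_batch, -0.3, 0.3), p, n_batch)
  drift <- matrix(runif(p * n_batch, -0.01, 0.01), p, n_batch)
  noisy <- clean + off[, batch] + drift[, batch] * rep(run, each = p)
  dimnames(clean) <- dimnames(noisy) <- list(paste0("F", 1:p), ids)
  list(clean = clean, noisy = noisy,
       meta = make_meta(ids, batch = batch, run = run))
}

normalize_stages <- function(log2_mat, meta) {
  lg <- sweep(log2_mat, 2, apply(log2_mat, 2, median), "-")
  center_batches(correct_drift(lg, meta)$table, meta)
}

# brute-force all-pairs shortest paths (test oracle)
floyd_warshall <- function(len) {
  p <- nrow(len)
  D <- len
  D[len == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(p)) for (i in seq_len(p)) for (j in seq_len(p))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}
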