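test_that("presence and S/N filters follow the keep rules", {
  # 100 samples + 2 blanks; feature rows engineered per rule
  ids <- sprintf("smp%03d", 1:100)
  blanks <- c("blk1", "blk2")
  mat <- matrix(1000, 4, 102, dimnames = list(paste0("F", 1:4),
                                              c(ids, blanks)))
  mat["F1", 1:71] <- NA          # present in 29% of samples -> dropped
  mat["F2", c("blk1", "blk2")] <- NA  # absent from all blanks -> kept
  mat["F3", c("blk1", "blk2")] <- 500 # median exactly 2x blank -> kept
  mat["F4", c("blk1", "blk2")] <- 600 # S/N < 2 -> dropped
  meta <- make_meta(c(ids, blanks), blank = c(rep(FALSE, 100), TRUE, TRUE))
  out <- filter_features(mat, meta)
  expect_setequal(rownames(out$table), c("F2", "F3"))
  expect_equal(out$report$reason[out$report$feature_id == "F1"], "presence")
  expect_equal(out$report$reason[out$report$feature_id == "F4"], "snr")
})

test_that("missing blanks skip the S/N criterion with a warning", {
  ids <- sprintf("s%02d", 1:10)
  mat <- matrix(100, 2, 10, dimnames = list(c("A", "B"), ids))
  mat["B", 1:8] <- NA
  expect_warning(out <- filter_features(mat, make_meta(ids)), "blank")
  expect_equal(rownames(out$table), "A")
})

test_that("run-median centering is exact and scale invariant", {
  mat <- matrix(c(2, 8, 32), 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(as.numeric(log_and_center_runs(mat)), c(-2, 0, 2))

  m2 <- cbind(s1 = c(2, 8, 32), s2 = 2 * c(2, 8, 32))
  rownames(m2) <- letters[1:3]
  out <- log_and_center_runs(m2)
  expect_equal(out[, "s1"], out[, "s2"])

  const <- matrix(7, 4, 3, dimnames = list(letters[1:4], paste0("s", 1:3)))
  expect_true(all(log_and_center_runs(const) == 0))

  bad <- m2; bad[1, 1] <- -1
  expect_error(log_and_center_runs(bad), "non-positive")
})

test_that("drift correction removes exact linear drift, preserves means", {
  ids <- paste0("s", 1:10)
  meta <- make_meta(ids)
  mat <- rbind(F1 = 10 + 0.1 * (1:10), F2 = rep(5, 10))
  colnames(mat) <- ids
  out <- correct_drift(mat, meta)
  expect_equal(unname(out$table["F1", ]), rep(10 + 0.1 * mean(1:10), 10))
  expect_equal(out$table["F2", ], mat["F2", ]) # constant unchanged
  refit <- correct_drift(out$table, meta)
  expect_lt(max(abs(refit$drift$slope)), 1e-10)
  # batches with < 3 observations are left alone
  m3 <- mat; m3["F1", 4:10] <- NA
  m3["F1", 1:3] <- c(1, 2, NA)
  out3 <- correct_drift(m3, meta)
  expect_equal(out3$table["F1", 1:2], m3["F1", 1:2])
  expect_error(correct_drift(mat, make_meta(ids, batch = NA)), "batch")
})

test_that("batch centering removes offsets exactly and is idempotent", {
  ids <- paste0("s", 1:8)
  meta <- make_meta(ids, batch = rep(1:2, each = 4))
  base <- matrix(rnorm(16), 2, 8, dimnames = list(c("A", "B"), ids))
  shifted <- base
  shifted[, 5:8] <- shifted[, 5:8] + 3
  a <- center_batches(base, meta)
  b <- center_batches(shifted, meta)
  expect_equal(a, b)
  expect_equal(center_batches(b, meta), b) # idempotent
  # single batch behaves as per-feature median centering
  one <- center_batches(base, make_meta(ids))
  expect_equal(one, base - apply(base, 1, median))
})

test_that("sparse-sample dropping uses a strict boundary", {
  mat <- matrix(1, 10, 3, dimnames = list(paste0("F", 1:10),
                                          c("a", "b", "c")))
  mat[1:6, "a"] <- NA # 60% missing
  mat[1:5, "b"] <- NA # exactly 50%
  out <- drop_sparse_samples(mat)
  expect_equal(out$dropped, "a")
  expect_setequal(colnames(out$table), c("b", "c"))
  full <- drop_sparse_samples(matrix(1, 2, 2))
  expect_equal(length(full$dropped), 0)
  allna <- matrix(NA_real_, 2, 2)
  expect_error(drop_sparse_samples(allna), "all samples")
})

test_that("KNN imputation copies coherent neighbours, never observed cells", {
  set.seed(1)
  base <- matrix(rnorm(12), 1, 12)
  mat <- matrix(rep(base, 11), 11, 12, byrow = TRUE)
  rownames(mat) <- paste0("F", 1:11)
  colnames(mat) <- paste0("s", 1:12)
  mat["F1", 5] <- NA
  out <- impute_knn(mat, preprocess_config(knn_k = 10))
  expect_equal(out["F1", 5], base[5])
  expect_equal(out[-1, ], mat[-1, ]) # observed untouched

  two <- rbind(A = c(1, 2, NA, 4), B = c(1, 2, 9, 4))
  colnames(two) <- paste0("s", 1:4)
  out2 <- impute_knn(two, preprocess_config(knn_k = 1))
  expect_equal(out2["A", 3], 9)
})

test_that("imputation error versus generator truth stays near the noise", {
  co <- small_cohort()
  cfg <- cohort_config(n_subjects = 12, p_features = 120, n_batches = 4,
                       seed = 101L)
  pre <- suppressWarnings(run_preprocess(co$table, co$meta,
                                         drop_outliers = FALSE))
  bio <- dplyr::filter(co$meta, !is_blank)
  # truth on the same normalized scale: clean signal, feature-centred within
  # the processed table's samples; compare only originally-missing cells
  tab <- pre$table
  keep_f <- rownames(tab)
  clean <- co$truth$clean_log2[keep_f, colnames(tab)]
  miss <- co$truth$missing_mask[match(keep_f, rownames(co$table)),
                                match(colnames(tab), colnames(co$table))]
  centred_tab <- tab - rowMeans(tab)
  centred_clean <- clean - rowMeans(clean)
  err <- (centred_tab - centred_clean)[miss]
  expect_lt(sqrt(mean(err^2)), 2 * cfg$sigma_noise)
})

test_that("PCA QC matches an eigendecomposition oracle and flags outliers", {
  set.seed(42)
  mat <- matrix(rnorm(10 * 6), 10, 6,
                dimnames = list(paste0("F", 1:10), paste0("s", 1:6)))
  qc <- pca_qc(mat, preprocess_config(pca_components = 2))
  cv <- stats::cov(t(mat - rowMeans(mat)))
  ev <- eigen(cv, symmetric = TRUE)
  centered <- t(mat - rowMeans(mat))
  for (j in 1:2) {
    oracle <- as.numeric(centered %*% ev$vectors[, j])
    got <- qc$scores[[paste0("PC", j)]]
    expect_equal(abs(got), abs(oracle), tolerance = 1e-6)
  }

  same <- matrix(5, 8, 5, dimnames = list(paste0("F", 1:8), paste0("s", 1:5)))
  qc2 <- pca_qc(same, preprocess_config(pca_components = 2))
  expect_true(all(abs(qc2$scores$PC1) < 1e-12))
  expect_false(any(qc2$scores$outlier))

  out <- mat
  out <- cbind(out, s7 = rowMeans(mat))
  out[1, "s7"] <- out[1, "s7"] + 1000
  qc3 <- pca_qc(out, preprocess_config(pca_components = 2, outlier_sd = 2))
  expect_true(qc3$scores$outlier[qc3$scores$sample_id == "s7"])

  expect_error(pca_qc(mat[, 1:2], preprocess_config(pca_components = 2)),
               "fewer samples")
})

test_that("normalization stages never change the feature count", {
  co <- small_cohort()
  filt <- filter_features(co$table, co$meta)
  lg <- log_and_center_runs(filt$table)
  expect_equal(nrow(lg), nrow(filt$table))
  dr <- correct_drift(lg, co$meta)
  expect_equal(nrow(dr$table), nrow(lg))
  bc <- center_batches(dr$table, co$meta)
  expect_equal(nrow(bc), nrow(dr$table))
})

test_that("zero-noise flat cohort: batch offsets and drift removed exactly", {
  ac <- make_artifact_cohort(with_traj = 0)
  z <- normalize_stages(ac$noisy, ac$meta)
  spread <- apply(z - ac$clean + mean(ac$clean), 1,
                  function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9) # per-feature constant rows
})

test_that("processing artifacts equals processing the clean table", {
  ac <- make_artifact_cohort(with_traj = 0.02, seed = 2)
  zA <- normalize_stages(ac$clean, ac$meta)
  zB <- normalize_stages(ac$noisy, ac$meta)
  expect_lt(max(abs(zA - zB)), 1e-9)
})

test_that("drift correction shrinks re-fitted slopes at least 10-fold", {
  co <- small_cohort()
  filt <- suppressWarnings(filter_features(co$table, co$meta))
  lg <- log_and_center_runs(filt$table)
  before <- correct_drift(lg, co$meta)
  after <- correct_drift(before$table, co$meta)
  ratio <- mean(abs(before$drift$slope)) / mean(abs(after$drift$slope))
  expect_gte(ratio, 10)
})
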