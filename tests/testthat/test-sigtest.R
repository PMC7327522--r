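test_that("gestational ages rescale so delivery lands at 40 weeks", {
  expect_equal(scale_ga(21, 42), 20)
  expect_equal(scale_ga(38, 38), 40)
  expect_equal(scale_ga(14, 40), 14)
  expect_equal(scale_ga(46, 40, is_postpartum = TRUE), 46) # PP untouched
  expect_error(scale_ga(10, NA), "unknown")
})

sim_table <- function(p, n, seed, signal_frac = 0) {
  set.seed(seed)
  ga <- runif(n, 5, 40)
  mat <- matrix(rnorm(p * n), p, n,
                dimnames = list(sprintf("F%04d", 1:p), NULL))
  k <- round(signal_frac * p)
  if (k > 0) mat[1:k, ] <- mat[1:k, ] + outer(runif(k, 0.05, 0.1), ga)
  list(mat = mat, ga = ga, informative = seq_len(k))
}

test_that("a perfectly monotone feature dominates the q-value ranking", {
  s <- sim_table(50, 60, 1)
  s$mat[1, ] <- exp(s$ga / 10) # monotone in GA
  res <- sam_quantitative(s$mat, s$ga, sig_config(n_perm = 200))
  expect_equal(abs(res$statistic[1]), 1)
  expect_lte(res$qvalue[1], min(res$qvalue))
})

test_that("statistic is invariant under strictly monotone transforms", {
  s <- sim_table(20, 50, 2, signal_frac = 0.5)
  r1 <- sam_quantitative(s$mat, s$ga, sig_config(n_perm = 150, seed = 7))
  tr <- s$mat
  tr[3, ] <- exp(tr[3, ])
  tr[4, ] <- tr[4, ]^3
  r2 <- sam_quantitative(tr, s$ga, sig_config(n_perm = 150, seed = 7))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$qvalue, r2$qvalue)
})

test_that("q-values are monotone non-increasing in |statistic|", {
  s <- sim_table(100, 80, 3, signal_frac = 0.3)
  res <- sam_quantitative(s$mat, s$ga, sig_config(n_perm = 150))
  o <- order(abs(res$statistic), decreasing = TRUE)
  expect_true(all(diff(res$qvalue[o]) >= -1e-12))
  expect_true(all(res$qvalue >= 0 & res$qvalue <= 1))
})

test_that("constant features are assigned statistic 0 and q 1", {
  s <- sim_table(20, 40, 4)
  s$mat[5, ] <- 3
  res <- sam_quantitative(s$mat, s$ga, sig_config(n_perm = 150))
  expect_equal(res$statistic[5], 0)
  expect_equal(res$qvalue[5], 1)
})

test_that("permuting GA before analysis empties the significant set", {
  s <- sim_table(200, 80, 5, signal_frac = 0.3)
  set.seed(99)
  res <- sam_quantitative(s$mat, sample(s$ga), sig_config(n_perm = 200))
  expect_lte(mean(res$significant), 0.01)
})

test_that("slope filter keeps strictly-above-threshold features only", {
  n <- 60
  ga <- seq(5, 40, length.out = n)
  thr <- top_change_slope_threshold()
  mat <- rbind(
    keep = 0.02 * ga,
    drop_zero = rep(1, n),
    boundary = thr * ga # exactly at the threshold -> dropped
  )
  colnames(mat) <- paste0("s", 1:n)
  out <- slope_filter(mat, ga)
  expect_true(out$top_changer[1])
  expect_false(out$top_changer[2])
  expect_false(out$top_changer[3])
  expect_equal(out$slope[3], thr)
  expect_error(slope_filter(mat[, 1:2], ga[1:2]), "3 samples")
})

test_that("slope filter recovers generator top changers sensitively", {
  sp <- small_processed()
  bio <- dplyr::filter(sp$meta, !is_postpartum)
  out <- slope_filter(sp$tab[, bio$sample_id], bio$ga_ultrasound_weeks)
  thr <- top_change_slope_threshold()
  joined <- dplyr::inner_join(out, sp$cohort$truth$features,
                              by = "feature_id")
  # features whose true slope clears the threshold by more than the OLS
  # slope estimate's sampling error; truly borderline slopes (within ~1 SE
  # of the cutoff) are undetectable at any cohort size by construction
  clear <- abs(joined$slope.y) > 1.25 * thr
  near <- abs(joined$slope.y) > thr
  expect_gte(mean(joined$top_changer[clear]), 0.9)
  expect_gte(mean(joined$top_changer[near]), 0.75)
  # specificity: features with |s| below the threshold are mostly rejected
  expect_lte(mean(joined$top_changer[abs(joined$slope.y) < 0.5 * thr]), 0.05)
})

test_that("baseline normalization zeroes the baseline window", {
  mat <- rbind(A = c(5, 5, 8, 9), B = rep(2, 4))
  colnames(mat) <- paste0("s", 1:4)
  adj <- c(10, 12, 20, 30)
  out <- baseline_normalize(mat, adj)
  expect_equal(unname(out["A", ]), c(0, 0, 3, 4))
  expect_true(all(out["B", ] == 0))
  expect_equal(mean(out[, adj < 14]), 0)
  expect_error(baseline_normalize(mat, adj + 100), "baseline")
})

test_that("week clustering orders a monotone gradient monotonically", {
  weeks <- paste0("w", 1:5)
  # shared gradient with distinct spacings (no tied merge heights)
  prof <- outer(abs(rnorm(30)) + 0.1, c(1, 2, 4, 8, 16))
  colnames(prof) <- weeks
  ord <- cluster_weeks(prof)
  expect_true(identical(ord, weeks) || identical(ord, rev(weeks)))
})

test_that("identical weeks merge first and input order is irrelevant", {
  set.seed(6)
  prof <- matrix(rnorm(40), 10, 4,
                 dimnames = list(NULL, c("w1", "w2", "w3", "w4")))
  prof[, "w4"] <- prof[, "w1"]
  d <- dist(t(prof), method = "manhattan")
  hc <- hclust(d, method = "average")
  first <- labels(d)[hc$merge[1, ] < 0]
  expect_true(all(c(which(colnames(prof) == "w1"),
                    which(colnames(prof) == "w4")) %in% -hc$merge[1, ]))
  ordered1 <- cluster_weeks(prof)
  perm <- c(3, 1, 4, 2)
  ordered2 <- cluster_weeks(prof[, perm])
  expect_setequal(ordered1, ordered2)
  # adjacency of the identical pair survives permutation
  expect_equal(abs(diff(match(c("w1", "w4"), ordered2))), 1)
  expect_error(cluster_weeks(prof[, 1, drop = FALSE]), "2 weeks")
})

test_that("weekly profiles bin by floor of adjusted GA with PP last", {
  mat <- matrix(1:12, 2, 6)
  rownames(mat) <- c("A", "B")
  adj <- c(10.2, 10.9, 20.5, 20.1, 30, 46)
  pp <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  prof <- weekly_profiles(mat, adj, pp)
  expect_equal(colnames(prof), c("10", "20", "30", "PP"))
  expect_equal(prof["A", "10"], mean(mat[1, 1:2]))
  expect_equal(prof["A", "PP"], unname(mat[1, 6]))
})
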