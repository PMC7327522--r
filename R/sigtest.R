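# Significance analysis of gestational-age association -----------------------
#
# A rank-based SAM-style procedure: per-feature Spearman correlation with
# gestational age as the statistic, sample-wise permutations of the GA
# vector for the null ensemble, and a permutation-median FDR estimate. This
# is a deliberate self-contained analog of samr's distribution-independent
# ranking test, not a samr clone.

#' Significance-testing configuration
#'
#' @param fdr_max FDR threshold for the significant set (default 0.05).
#' @param n_perm Number of sample-wise permutations (default 1000).
#' @param slope_min Absolute log2/week slope defining a top changer
#'   (default [top_change_slope_threshold()], i.e. log2(1.5)/40).
#' @param baseline_week Samples with adjusted GA strictly below this form
#'   the populational baseline (default 14).
#' @param seed Integer seed for the permutation stream.
#' @return A `sig_config` list.
#' @export
sig_config <- function(fdr_max = 0.05, n_perm = 1000,
                       slope_min = top_change_slope_threshold(),
                       baseline_week = 14, seed = 1L) {
  if (fdr_max <= 0 || fdr_max >= 1) abort("`fdr_max` in (0, 1)")
  if (n_perm < 100) abort("`n_perm` must be >= 100")
  structure(list(fdr_max = fdr_max, n_perm = as.integer(n_perm),
                 slope_min = slope_min, baseline_week = baseline_week,
                 seed = as.integer(seed)),
            class = "sig_config")
}

#' Scale gestational age so every delivery falls at 40 weeks
#'
#' Pregnancy samples return `ga * 40 / delivery_ga`; postpartum samples pass
#' through unscaled (label them separately as "PP").
#'
#' @param ga Gestational age at draw (weeks).
#' @param delivery_ga Delivery gestational age (weeks); must be known.
#' @param is_postpartum Logical; postpartum samples are not rescaled.
#' @return Adjusted gestational age in weeks.
#' @export
scale_ga <- function(ga, delivery_ga, is_postpartum = FALSE) {
  if (anyNA(delivery_ga)) abort("delivery GA unknown for some samples")
  if (any(delivery_ga <= 0)) abort("delivery GA must be > 0")
  ifelse(rep_len(is_postpartum, length(ga)), ga, ga * 40 / delivery_ga)
}

#' SAM-style quantitative significance analysis
#'
#' Statistic: Spearman rank correlation between each feature's abundance and
#' gestational age (average ranks for ties). Null ensemble: `n_perm`
#' sample-wise permutations of the GA vector. For a threshold t on |r| the
#' estimated FDR is the median permutation exceedance count divided by the
#' observed exceedance count; a feature's q-value is the smallest estimated
#' FDR over thresholds that include it, which makes q monotone
#' non-increasing in |r|.
#'
#' @param mat Complete feature matrix (features x samples).
#' @param ga Gestational age per sample (same order as columns).
#' @param cfg A [sig_config()].
#' @return A `sam_result` tibble: `feature_id`, `statistic`, `qvalue`,
#'   `significant`.
#' @export
sam_quantitative <- function(mat, ga, cfg = sig_config()) {
  stopifnot(ncol(mat) == length(ga))
  if (ncol(mat) < 20) abort("need at least 20 samples")
  set.seed(cfg$seed)
  n <- ncol(mat)
  feat_ranks <- t(apply(mat, 1, rank))
  constant <- apply(mat, 1, function(x) length(unique(x)) == 1)
  fr <- scale(t(feat_ranks)) # samples x features, standardized ranks
  fr[, constant] <- 0
  ga_r <- as.numeric(scale(rank(ga)))
  r_obs <- as.numeric(crossprod(fr, ga_r)) / (n - 1)
  r_obs[constant] <- 0

  perms <- replicate(cfg$n_perm, sample(ga_r))
  r_null <- crossprod(fr, perms) / (n - 1) # features x n_perm

  # thresholds = observed |r| values, most stringent first; observed count at
  # the k-th threshold is k. The median (over permutations) null exceedance
  # count at t equals #{k : M_k >= t} where M_k is the median k-th largest
  # null |r| across permutations (M is non-increasing in k).
  thresholds <- sort(abs(r_obs), decreasing = TRUE)
  a_null_sorted <- apply(abs(r_null), 2, sort, decreasing = TRUE)
  m_null <- apply(a_null_sorted, 1, median)
  null_counts <- vapply(thresholds, function(t) sum(m_null >= t), numeric(1))
  fdr_at <- pmin(null_counts / seq_along(thresholds), 1)
  # a feature at rank k is included at thresholds k..p; q = min over those
  q_sorted <- rev(cummin(rev(fdr_at)))
  ord <- order(abs(r_obs), decreasing = TRUE)
  q <- numeric(length(r_obs))
  q[ord] <- q_sorted
  q[constant] <- 1

  structure(tibble(
    feature_id = rownames(mat) %||% sprintf("F%04d", seq_len(nrow(mat))),
    statistic = r_obs,
    qvalue = q,
    significant = q <= cfg$fdr_max
  ), class = c("sam_result", class(tibble())))
}

#' Top-changer selection by absolute regression slope
#'
#' Per-feature ordinary least squares of log2 abundance on gestational
#' weeks; a feature is kept iff its absolute slope is strictly larger than
#' `cfg$slope_min` (log2(1.5)/40 by default, i.e. at least a 1.5-fold change
#' over a 40-week gestation).
#'
#' @param mat Log2 feature matrix, pregnancy samples only.
#' @param ga Gestational weeks per sample.
#' @param cfg A [sig_config()].
#' @return Tibble: `feature_id`, `slope`, `top_changer`.
#' @export
slope_filter <- function(mat, ga, cfg = sig_config()) {
  if (ncol(mat) < 3) abort("need at least 3 samples")
  gc <- ga - mean(ga)
  slope <- as.numeric(mat %*% gc) / sum(gc^2)
  tibble(
    feature_id = rownames(mat) %||% sprintf("F%04d", seq_len(nrow(mat))),
    slope = slope,
    top_changer = abs(slope) > cfg$slope_min
  )
}

#' Subtract the populational early-pregnancy baseline
#'
#' The baseline is each feature's mean over all samples with adjusted GA
#' strictly below `cfg$baseline_week`; the returned table holds deltas
#' against it, so the baseline window's mean is 0 by construction.
#'
#' @param mat Feature matrix.
#' @param adjusted_ga Adjusted GA per sample (postpartum excluded from the
#'   baseline by construction since PP > baseline_week).
#' @param cfg A [sig_config()].
#' @return Matrix of deltas.
#' @export
baseline_normalize <- function(mat, adjusted_ga, cfg = sig_config()) {
  base_cols <- which(adjusted_ga < cfg$baseline_week)
  if (length(base_cols) == 0)
    abort("no samples before the baseline week")
  base <- rowMeans(mat[, base_cols, drop = FALSE])
  sweep(mat, 1, base, "-")
}

#' Mean weekly profiles on the adjusted-GA axis
#'
#' Bins samples by floor of adjusted GA (postpartum pooled as `"PP"`) and
#' averages each feature within a bin.
#'
#' @param mat Feature matrix.
#' @param adjusted_ga Adjusted GA per sample.
#' @param is_postpartum Logical per sample.
#' @return Matrix features x week-bins, ordered by week with PP last.
#' @export
weekly_profiles <- function(mat, adjusted_ga, is_postpartum) {
  bin <- ifelse(is_postpartum, "PP", as.character(floor(adjusted_ga)))
  bins <- unique(bin)
  num <- suppressWarnings(as.numeric(bins))
  bins <- bins[order(is.na(num), num)]
  prof <- vapply(bins, function(b) rowMeans(mat[, bin == b, drop = FALSE]),
                 numeric(nrow(mat)))
  colnames(prof) <- bins
  prof
}

#' Order gestational weeks by hierarchical clustering of their profiles
#'
#' Average-linkage hierarchical clustering on Manhattan (L1) distances
#' between per-week mean profiles; returns the dendrogram leaf order. With
#' informative features this ordering largely coincides with the true
#' temporal order of the weeks.
#'
#' @param profiles Matrix features x weeks (as from [weekly_profiles()]).
#' @param method Linkage (default "average").
#' @return Character vector of week labels in leaf order.
#' @export
cluster_weeks <- function(profiles, method = "average") {
  if (ncol(profiles) < 2) abort("need at least 2 weeks")
  d <- dist(t(profiles), method = "manhattan")
  hc <- hclust(d, method = method)
  # orient subtrees by mean profile level (heatmap convention) so the leaf
  # order is deterministic rather than an arbitrary subtree flip
  dend <- stats::reorder(as.dendrogram(hc), colMeans(profiles),
                         agglo.FUN = mean)
  colnames(profiles)[order.dendrogram(dend)]
}
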