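# Categorical predictors of pregnancy timing ---------------------------------
#
# Logistic-lasso classifiers for gestational-age cutoffs (has the pregnancy
# passed week c?) and weeks-to-delivery (will delivery occur within c
# weeks?), with subject-wise cross-validation, a small predictor cap, and
# person-level bootstrap confidence intervals for the AUROC.

#' Classification configuration
#'
#' @param ga_cutoffs Gestational-age cutoffs in weeks (defaults
#'   20, 24, 28, 32, 37).
#' @param wd_cutoffs Weeks-to-delivery cutoffs (defaults 2, 4, 8).
#' @param third_trimester_min Week defining the third trimester (default
#'   28); late GA cutoffs (> this) and all WD tasks use third-trimester
#'   samples only.
#' @param max_predictors Cap on model predictors (default 3).
#' @param n_boot Bootstrap resamples for the AUROC CI (default 1000).
#' @param ci_level Confidence level (default 0.95).
#' @param n_folds Subject-wise CV folds (default 10).
#' @param seed Integer seed.
#' @return A `classify_config` list.
#' @export
classify_config <- function(ga_cutoffs = c(20, 24, 28, 32, 37),
                            wd_cutoffs = c(2, 4, 8),
                            third_trimester_min = 28, max_predictors = 3,
                            n_boot = 1000, ci_level = 0.95, n_folds = 10,
                            seed = 1L) {
  if (any(c(ga_cutoffs, wd_cutoffs) <= 0)) abort("cutoffs must be positive")
  if (ci_level <= 0 || ci_level >= 1) abort("`ci_level` in (0, 1)")
  structure(list(ga_cutoffs = ga_cutoffs, wd_cutoffs = wd_cutoffs,
                 third_trimester_min = third_trimester_min,
                 max_predictors = max_predictors,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "classify_config")
}

#' Build binary labels for a timing task
#'
#' `task = "ga_cutoff"`: label is (GA at draw > cutoff); the sample universe
#' is all pregnancy samples for cutoffs at or below `third_trimester_min`,
#' and third-trimester samples only for later cutoffs. `task =
#' "weeks_to_delivery"`: label is (delivery GA - GA at draw < cutoff);
#' third-trimester samples only, restricted to subjects with natural labor
#' onset (scheduled C-section and pre-onset induction excluded).
#'
#' @param meta Sample metadata (pregnancy samples; postpartum and blanks are
#'   excluded automatically).
#' @param task `"ga_cutoff"` or `"weeks_to_delivery"`.
#' @param cutoff Cutoff in weeks.
#' @param cfg A [classify_config()].
#' @return A `labeled_cohort` list: `samples` tibble (sample_id, subject_id,
#'   label), `excluded` tibble (sample_id, reason), `task`, `cutoff`.
#' @export
make_labels <- function(meta, task = c("ga_cutoff", "weeks_to_delivery"),
                        cutoff, cfg = classify_config()) {
  task <- match.arg(task)
  m <- meta |> filter(!.data$is_blank, !.data$is_postpartum)
  excluded <- list()
  if (task == "weeks_to_delivery" || cutoff > cfg$third_trimester_min) {
    out <- m |> filter(.data$ga_ultrasound_weeks <= cfg$third_trimester_min)
    excluded[["trimester"]] <- tibble(sample_id = out$sample_id,
                                      reason = "trimester")
    m <- m |> filter(.data$ga_ultrasound_weeks > cfg$third_trimester_min)
  }
  if (task == "weeks_to_delivery") {
    if (anyNA(m$delivery_ga_weeks)) abort("delivery GA unknown")
    out <- m |> filter(!.data$natural_onset)
    excluded[["onset"]] <- tibble(sample_id = out$sample_id, reason = "onset")
    m <- m |> filter(.data$natural_onset)
    label <- (m$delivery_ga_weeks - m$ga_ultrasound_weeks) < cutoff
  } else {
    label <- m$ga_ultrasound_weeks > cutoff
  }
  if (all(label) || !any(label))
    abort("task has no positive or no negative labels")
  structure(list(
    samples = tibble(sample_id = m$sample_id, subject_id = m$subject_id,
                     label = label),
    excluded = bind_rows(excluded), task = task, cutoff = cutoff
  ), class = "labeled_cohort")
}

#' L1-penalized logistic regression with subject-wise CV and a support cap
#'
#' The penalty is chosen by subject-wise cross-validated binomial deviance
#' and then inflated until the full-data refit support has at most
#' `max_predictors` nonzero coefficients. Scores are linear-predictor
#' values (AUROC is threshold-free, so no calibration is attempted).
#'
#' @param X Samples x predictors matrix.
#' @param labels Logical or 0/1 vector.
#' @param subject_ids Subject id per sample.
#' @param cfg A [classify_config()].
#' @return A `logistic_clock_model` list: `predictors`, `coefficients`,
#'   `intercept`, `lambda`, `contributions`, `cv_scores` (out-of-fold linear
#'   predictors), `folds`.
#' @export
fit_logistic_lasso <- function(X, labels, subject_ids,
                               cfg = classify_config()) {
  y <- as.integer(labels)
  folds <- subject_folds(subject_ids,
                         clock_config(n_folds = cfg$n_folds, seed = cfg$seed))
  # refold (merge) if a fold is single-class in the training complement
  for (k in unique(folds)) {
    if (length(unique(y[folds != k])) < 2) {
      warn("degenerate single-class training set; merging fold")
      folds[folds == max(folds)] <- k
    }
  }
  full_fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1)
  lambda <- full_fit$lambda
  dev <- matrix(NA_real_, length(y), length(lambda))
  oof <- matrix(NA_real_, length(y), length(lambda))
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit_k <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                            family = "binomial", alpha = 1, lambda = lambda)
    eta <- predict(fit_k, X[test, , drop = FALSE], s = lambda)
    pr <- 1 / (1 + exp(-eta))
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    dev[test, seq_len(ncol(pr))] <-
      -2 * (y[test] * log(pr) + (1 - y[test]) * log(1 - pr))
    oof[test, seq_len(ncol(eta))] <- eta
  }
  mean_dev <- colMeans(dev)
  lambda_cv <- lambda[which.min(mean_dev)]
  support <- colSums(as.matrix(coef(full_fit)[-1, , drop = FALSE]) != 0)
  eligible <- which(lambda >= lambda_cv & support <= cfg$max_predictors)
  lambda_star <- if (length(eligible) == 0) {
    warn("no penalty achieves the predictor cap; using the largest")
    lambda[1]
  } else min(lambda[eligible])
  cf <- coef(full_fit, s = lambda_star)
  coefs <- setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  nz <- coefs[coefs != 0]
  structure(list(
    predictors = names(nz), coefficients = nz, intercept = as.numeric(cf)[1],
    lambda = lambda_star, lambda_cv = lambda_cv,
    contributions = if (length(nz) > 0) contributions(coefs) else numeric(0),
    cv_scores = oof[, match(lambda_star, lambda)], folds = folds
  ), class = "logistic_clock_model")
}

#' @export
predict.logistic_clock_model <- function(object, newdata, ...) {
  as.numeric(object$intercept +
               newdata[, object$predictors, drop = FALSE] %*%
               object$coefficients)
}

#' Area under the ROC curve
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted 1/2 (Mann-Whitney U over n+ x n- pairs).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Person-level bootstrap confidence interval for the AUROC
#'
#' Resamples subjects with replacement `n_boot` times (each resample carries
#' all of a subject's samples, so no replicate ever splits a person);
#' single-class resamples are redrawn. The interval is the percentile
#' interval at `ci_level`.
#'
#' @param scores,labels Per-sample scores and labels.
#' @param subject_ids Subject id per sample.
#' @param cfg A [classify_config()].
#' @return Tibble: `auroc`, `lower`, `upper`, `n_boot`.
#' @export
bootstrap_auroc_ci <- function(scores, labels, subject_ids,
                               cfg = classify_config()) {
  labels <- as.logical(labels)
  subj <- unique(subject_ids)
  pos_subj <- unique(subject_ids[labels])
  neg_subj <- unique(subject_ids[!labels])
  if (length(pos_subj) < 2 || length(neg_subj) < 2)
    abort("need at least 2 subjects per class")
  set.seed(cfg$seed)
  idx_of <- split(seq_along(scores), subject_ids)
  boots <- numeric(cfg$n_boot)
  for (b in seq_len(cfg$n_boot)) {
    for (try in 1:100) {
      take <- sample(subj, length(subj), replace = TRUE)
      idx <- unlist(idx_of[take], use.names = FALSE)
      if (length(unique(labels[idx])) == 2) break
      if (try == 100) abort("cannot form two-class resamples")
    }
    boots[b] <- auroc(scores[idx], labels[idx])
  }
  alpha <- (1 - cfg$ci_level) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble(auroc = auroc(scores, labels), lower = ci[1], upper = ci[2],
         n_boot = cfg$n_boot)
}

#' Run one classification task end to end
#'
#' Labels the cohort, fits the capped logistic lasso with subject-wise CV,
#' and reports pooled out-of-fold AUROC with a person-level bootstrap CI.
#'
#' @param mat Feature matrix (features x samples, pregnancy samples).
#' @param meta Sample metadata.
#' @param task,cutoff Task specification (see [make_labels()]).
#' @param cfg A [classify_config()].
#' @return A `classification_result` list: `model`, `labels`
#'   (`labeled_cohort`), `cv_auroc` tibble (point + CI), `scores` tibble.
#' @export
run_classification <- function(mat, meta, task, cutoff,
                               cfg = classify_config()) {
  lab <- make_labels(meta, task, cutoff, cfg)
  ids <- lab$samples$sample_id
  missing_ids <- setdiff(ids, colnames(mat))
  if (length(missing_ids) > 0) {
    lab$samples <- lab$samples |> filter(.data$sample_id %in% colnames(mat))
    ids <- lab$samples$sample_id
  }
  X <- t(mat[, ids, drop = FALSE])
  n_subj <- length(unique(lab$samples$subject_id))
  eff_cfg <- cfg
  eff_cfg$n_folds <- min(cfg$n_folds, n_subj)
  model <- fit_logistic_lasso(X, lab$samples$label, lab$samples$subject_id,
                              eff_cfg)
  ci <- bootstrap_auroc_ci(model$cv_scores, lab$samples$label,
                           lab$samples$subject_id, cfg)
  structure(list(
    model = model, labels = lab, cv_auroc = ci,
    scores = tibble(sample_id = ids, subject_id = lab$samples$subject_id,
                    label = lab$samples$label, score = model$cv_scores)
  ), class = "classification_result")
}

#' @exportS3Method generics::tidy
tidy.logistic_clock_model <- function(x, ...) {
  tibble(term = x$predictors, estimate = as.numeric(x$coefficients),
         contribution = as.numeric(x$contributions))
}

#' @exportS3Method generics::glance
glance.classification_result <- function(x, ...) {
  bind_cols(tibble(n_predictors = length(x$model$predictors),
                   lambda = x$model$lambda), x$cv_auroc)
}
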