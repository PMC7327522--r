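# The metabolic clock ---------------------------------------------------------
#
# L1-penalized linear regression of gestational age on metabolite
# abundances: subject-wise 10-fold cross-validation chooses the penalty, the
# penalty is then inflated until the full-data refit uses at most
# `max_predictors` predictors (the reported panel), held-out predictions are
# pooled across folds for the discovery evaluation, and frozen models score
# independent validation cohorts. glmnet provides the coordinate-descent
# lasso path.

#' Clock configuration
#'
#' @param n_folds Number of subject-wise CV folds (default 10).
#' @param max_predictors Cap on the predictors of the final model
#'   (default 5). Use `Inf` to disable.
#' @param lambda_grid Optional descending positive penalty grid (default:
#'   100 log-spaced values chosen by glmnet).
#' @param standardize Standardize predictors inside the solver
#'   (coefficients are always returned on the original scale).
#' @param seed Integer seed (fold shuffling).
#' @return A `clock_config` list.
#' @export
clock_config <- function(n_folds = 10, max_predictors = 5,
                         lambda_grid = NULL, standardize = TRUE, seed = 1L) {
  if (n_folds < 2) abort("`n_folds` must be >= 2")
  if (max_predictors < 1) abort("`max_predictors` must be >= 1")
  if (!is.null(lambda_grid) &&
      (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid))))
    abort("`lambda_grid` must be positive and descending")
  structure(list(n_folds = as.integer(n_folds),
                 max_predictors = max_predictors,
                 lambda_grid = lambda_grid, standardize = standardize,
                 seed = as.integer(seed)),
            class = "clock_config")
}

#' Assign samples to cross-validation folds by subject
#'
#' Subjects are shuffled (seeded) and dealt round-robin into `n_folds`
#' folds; every sample inherits its subject's fold, so no subject ever spans
#' folds and no held-out prediction comes from a model that saw the same
#' person.
#'
#' @param subject_ids Character vector, one entry per sample.
#' @param cfg A [clock_config()].
#' @return Integer fold id per sample.
#' @export
subject_folds <- function(subject_ids, cfg = clock_config()) {
  subjects <- unique(subject_ids)
  if (length(subjects) < cfg$n_folds)
    abort("fewer subjects than folds")
  set.seed(cfg$seed)
  shuffled <- sample(subjects)
  fold_of <- setNames(rep(seq_len(cfg$n_folds),
                          length.out = length(subjects)), shuffled)
  as.integer(fold_of[subject_ids])
}

#' Lasso coefficient path
#'
#' Coordinate-descent solutions of
#' `min ||y - b0 - X b||^2 / (2n) + lambda ||b||_1` along a descending
#' penalty grid (glmnet), coefficients reported on the original predictor
#' scale.
#'
#' @param X Samples x predictors matrix (complete).
#' @param y Response (gestational weeks).
#' @param cfg A [clock_config()].
#' @return A `glmnet` fit object.
#' @export
fit_lasso_path <- function(X, y, cfg = clock_config()) {
  if (!all(is.finite(X)) || !all(is.finite(y)))
    abort("non-finite values in predictors or response")
  glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                 lambda = cfg$lambda_grid, standardize = cfg$standardize)
}

#' Select the penalty by subject-wise cross-validation with a support cap
#'
#' `lambda_cv` minimizes the pooled held-out mean squared error over the
#' grid; `lambda*` is then the smallest grid value >= `lambda_cv` whose
#' refit-on-all-data support has at most `max_predictors` nonzero
#' coefficients. If no grid value achieves the cap the largest is used with
#' a warning.
#'
#' @param X,y Training data.
#' @param folds Integer fold id per sample (from [subject_folds()]).
#' @param cfg A [clock_config()].
#' @return List: `lambda` (lambda*), `lambda_cv`, `cv_mse` tibble,
#'   `full_fit` (glmnet fit on all data).
#' @export
select_lambda <- function(X, y, folds, cfg = clock_config()) {
  full_fit <- fit_lasso_path(X, y, cfg)
  lambda <- full_fit$lambda
  sq_err <- matrix(NA_real_, nrow(X), length(lambda))
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit_k <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                            family = "gaussian", alpha = 1, lambda = lambda,
                            standardize = cfg$standardize)
    pred <- predict(fit_k, X[test, , drop = FALSE], s = lambda)
    sq_err[test, seq_len(ncol(pred))] <- (pred - y[test])^2
  }
  mse <- colMeans(sq_err)
  lambda_cv <- lambda[which.min(mse)]
  support <- colSums(as.matrix(coef(full_fit)[-1, , drop = FALSE]) != 0)
  eligible <- which(lambda >= lambda_cv & support <= cfg$max_predictors)
  if (length(eligible) == 0) {
    warn("no penalty achieves the predictor cap; using the largest")
    lambda_star <- lambda[1]
  } else {
    lambda_star <- min(lambda[eligible]) # smallest lambda >= lambda_cv
  }
  list(lambda = lambda_star, lambda_cv = lambda_cv,
       cv_mse = tibble(lambda = lambda, mse = mse), full_fit = full_fit)
}

#' Per-predictor contributions of a sparse linear model
#'
#' `contribution_i = |beta_i| / sum_j |beta_j|` over the nonzero predictors.
#'
#' @param coefs Named numeric vector of coefficients (no intercept).
#' @return Named contributions summing to 1.
#' @export
contributions <- function(coefs) {
  nz <- coefs[coefs != 0]
  if (length(nz) == 0) abort("all coefficients are zero")
  abs(nz) / sum(abs(nz))
}

new_clock_model <- function(coefs, intercept, lambda, cfg) {
  nz <- coefs[coefs != 0]
  structure(list(
    predictors = names(nz), coefficients = nz, intercept = intercept,
    lambda = lambda,
    contributions = if (length(nz) > 0) contributions(coefs) else numeric(0),
    config = cfg
  ), class = "clock_model")
}

#' Predict gestational age with a clock model
#'
#' @param object A `clock_model`.
#' @param newdata Samples x predictors matrix containing the model's
#'   predictor columns.
#' @param ... Unused.
#' @return Numeric vector of predicted gestational ages (weeks).
#' @export
predict.clock_model <- function(object, newdata, ...) {
  missing_p <- setdiff(object$predictors, colnames(newdata))
  if (length(missing_p) > 0)
    abort(paste0("missing predictor column(s): ",
                 paste(missing_p, collapse = ", ")))
  as.numeric(object$intercept +
               newdata[, object$predictors, drop = FALSE] %*%
               object$coefficients)
}

#' Evaluate predictions against reference gestational ages
#'
#' Reports Pearson R, R^2 (of the prediction-vs-truth linear fit) and RMSE.
#'
#' @param predicted,actual Numeric vectors (weeks).
#' @return A `clock_evaluation` tibble row: `r`, `r_squared`, `rmse`, `n`,
#'   with the per-sample predictions in attribute `"predictions"`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  r <- if (sd(predicted) == 0 || sd(actual) == 0) 0 else cor(predicted, actual)
  out <- tibble(r = r, r_squared = r^2,
                rmse = sqrt(mean((predicted - actual)^2)),
                n = length(actual))
  attr(out, "predictions") <- tibble(ga_ultrasound = actual,
                                     ga_metabolic = predicted)
  class(out) <- c("clock_evaluation", class(out))
  out
}

#' Fit and evaluate the metabolic clock end to end
#'
#' On the discovery cohort: subject-wise folds, penalty selection with the
#' predictor cap, pooled out-of-fold predictions for the CV evaluation
#' (every held-out prediction comes from a model whose training folds
#' exclude that subject), and a final model refit on all discovery data at
#' the selected penalty. Validation cohorts are scored with the frozen
#' model; a cohort normalized independently of the discovery data may be
#' linearly rescaled post hoc (`rescale = TRUE`), which leaves R unchanged
#' and re-anchors the scale.
#'
#' Postpartum samples must be excluded by the caller (the clock is defined
#' on pregnancy samples only).
#'
#' @param X Discovery samples x predictors matrix.
#' @param y Discovery gestational ages (weeks).
#' @param subject_ids Subject id per discovery sample.
#' @param validation Optional named list of `list(X = , y = )` validation
#'   cohorts.
#' @param rescale Logical (recycled over validation cohorts): linearly
#'   rescale frozen-model predictions to the cohort's own scale.
#' @param cfg A [clock_config()].
#' @return A `clock_fit` list: `model` (`clock_model`), `cv` evaluation,
#'   `cv_predictions` tibble (subject_id, fold, ga_ultrasound,
#'   ga_metabolic), `validation` (named list of evaluations), `lambda`,
#'   `lambda_cv`, `folds`.
#' @export
run_clock_pipeline <- function(X, y, subject_ids, validation = list(),
                               rescale = FALSE, cfg = clock_config()) {
  folds <- subject_folds(subject_ids, cfg)
  sel <- select_lambda(X, y, folds, cfg)
  # pooled out-of-fold predictions at lambda*
  oof <- rep(NA_real_, length(y))
  for (k in sort(unique(folds))) {
    test <- folds == k
    if (any(subject_ids[test] %in% subject_ids[!test]))
      abort("subject leakage across folds") # defensive; cannot happen
    fit_k <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                            family = "gaussian", alpha = 1,
                            lambda = sel$full_fit$lambda,
                            standardize = cfg$standardize)
    oof[test] <- as.numeric(predict(fit_k, X[test, , drop = FALSE],
                                    s = sel$lambda))
  }
  cv_eval <- evaluate_predictions(oof, y)

  cf <- coef(sel$full_fit, s = sel$lambda)
  coefs <- setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  model <- new_clock_model(coefs, as.numeric(cf)[1], sel$lambda, cfg)
  if (length(model$predictors) > cfg$max_predictors)
    abort("final model exceeds the predictor cap") # hard assertion

  rescale <- rep_len(rescale, length(validation))
  val_evals <- purrr::map2(validation, seq_along(validation), function(v, i) {
    pred <- predict(model, v$X)
    if (rescale[[i]]) {
      sc <- lm(v$y ~ pred)
      pred <- as.numeric(predict(sc))
    }
    evaluate_predictions(pred, v$y)
  })

  structure(list(model = model, cv = cv_eval,
                 cv_predictions = tibble(subject_id = subject_ids,
                                         fold = folds, ga_ultrasound = y,
                                         ga_metabolic = oof,
                                         source = "cv"),
                 validation = val_evals, lambda = sel$lambda,
                 lambda_cv = sel$lambda_cv, cv_mse = sel$cv_mse,
                 folds = folds),
            class = "clock_fit")
}

#' @exportS3Method generics::tidy
tidy.clock_model <- function(x, ...) {
  tibble(term = x$predictors, estimate = as.numeric(x$coefficients),
         contribution = as.numeric(x$contributions))
}

#' @exportS3Method generics::tidy
tidy.clock_fit <- function(x, ...) tidy(x$model)

#' @exportS3Method generics::glance
glance.clock_fit <- function(x, ...) {
  tibble(n_predictors = length(x$model$predictors), lambda = x$lambda,
         lambda_cv = x$lambda_cv, cv_r = x$cv$r, cv_r_squared = x$cv$r_squared,
         cv_rmse = x$cv$rmse)
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Metabolic clock model (", length(x$predictors), " predictors, lambda=",
      signif(x$lambda, 4), ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
print.clock_fit <- function(x, ...) {
  cat("Metabolic clock fit\n")
  print(glance(x))
  invisible(x)
}
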