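test_that("subject-wise folds never split a subject and are reproducible", {
  subj <- rep(sprintf("S%02d", 1:21), times = sample(20:30, 21, replace = TRUE))
  f1 <- subject_folds(subj, clock_config(seed = 3))
  f2 <- subject_folds(subj, clock_config(seed = 3))
  expect_identical(f1, f2)
  per_subject <- tapply(f1, subj, function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
  sizes <- table(tapply(f1, subj, unique))
  expect_true(all(sizes %in% c(2, 3))) # 21 subjects over 10 folds
  expect_error(subject_folds(rep("a", 5), clock_config(n_folds = 10)),
               "fewer subjects")
})

test_that("lasso path obeys the KKT threshold and matches OLS at tiny lambda", {
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.3)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / n
  grid <- c(lambda_max * 1.01, lambda_max * 10^seq(0, -6, length.out = 40))
  fit <- fit_lasso_path(X, y, clock_config(lambda_grid = grid,
                                           standardize = FALSE))
  expect_true(all(coef(fit, s = grid[1])[-1] == 0))
  ols <- coef(lm(y ~ X))
  expect_equal(as.numeric(coef(fit, s = min(grid))),
               as.numeric(ols), tolerance = 1e-4)
  expect_error(fit_lasso_path(cbind(X, NA), y), "non-finite")
})

test_that("orthonormal design gives soft-thresholded OLS coefficients", {
  set.seed(5)
  n <- 64
  M <- scale(matrix(rnorm(n * 4), n, 4), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n) # column-centred with X'X = n I
  colnames(Q) <- paste0("v", 1:4)
  y <- Q %*% c(3, -1.5, 0.5, 0) + rnorm(n, 0, 0.2)
  bhat <- crossprod(Q, y - mean(y)) / n # OLS on centred response
  for (lam in c(0.25, 1, 2)) {
    fit <- glmnet::glmnet(Q, y, lambda = lam, standardize = FALSE,
                          thresh = 1e-12)
    soft <- sign(bhat) * pmax(abs(bhat) - lam, 0)
    expect_equal(as.numeric(coef(fit)[-1]), as.numeric(soft),
                 tolerance = 1e-6)
  }
})

test_that("lambda selection honours the predictor cap", {
  set.seed(6)
  n <- 200; p <- 40
  subj <- rep(sprintf("S%02d", 1:20), each = 10)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- X[, 1:20] %*% runif(20, 0.5, 1) + rnorm(n, 0, 0.5)
  folds <- subject_folds(subj, clock_config())
  dense <- select_lambda(X, as.numeric(y), folds, clock_config())
  supp <- sum(coef(dense$full_fit, s = dense$lambda)[-1] != 0)
  expect_lte(supp, 5)
  expect_gte(dense$lambda, dense$lambda_cv)
  uncapped <- select_lambda(X, as.numeric(y), folds,
                            clock_config(max_predictors = Inf))
  expect_equal(uncapped$lambda, uncapped$lambda_cv)

  # sparse truth: cap inactive, lambda* = lambda_cv
  y2 <- X[, 1] * 3 + rnorm(n, 0, 0.3)
  sparse <- select_lambda(X, y2, folds, clock_config())
  expect_equal(sparse$lambda, sparse$lambda_cv)
})

test_that("support size is monotone non-increasing along the lambda path", {
  set.seed(7)
  X <- matrix(rnorm(150 * 30), 150, 30)
  y <- X[, 1:5] %*% runif(5, 0.5, 2) + rnorm(150, 0, 0.5)
  fit <- fit_lasso_path(X, as.numeric(y), clock_config())
  expect_true(all(diff(fit$df) >= 0)) # lambda descends along the path
})

test_that("evaluation statistics match direct arithmetic", {
  ev <- evaluate_predictions(c(10, 20, 30), c(10, 20, 30))
  expect_equal(ev$r, 1); expect_equal(ev$rmse, 0)
  ev2 <- evaluate_predictions(c(12, 22, 32), c(10, 20, 30))
  expect_equal(ev2$r, 1); expect_equal(ev2$rmse, 2)
  ev3 <- evaluate_predictions(c(12, 18, 33), c(10, 20, 30))
  expect_equal(ev3$rmse, sqrt(mean(c(2, -2, 3)^2)))
  expect_equal(ev3$r, cor(c(12, 18, 33), c(10, 20, 30)))
  expect_equal(ev3$r_squared, ev3$r^2)
})

test_that("contributions follow |beta| / sum|beta|", {
  expect_equal(unname(contributions(c(a = 2, b = -1, c = 1))),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(contributions(c(x = -3))), 1)
  set.seed(8)
  cc <- contributions(setNames(rnorm(7), letters[1:7]))
  expect_equal(sum(cc), 1)
  expect_error(contributions(c(a = 0, b = 0)), "zero")
})

test_that("zero-noise cohort: the clock recovers GA exactly in-sample", {
  cfg <- cohort_config(n_subjects = 10, p_features = 60, n_batches = 2,
                       sigma_batch = 0, sigma_drift = 0, sigma_noise = 0,
                       sigma_offset = 0, mnar_threshold = -100,
                       labor_amplitude = 0, seed = 12L)
  co <- generate_cohort(cfg)
  bio <- dplyr::filter(co$meta, !is_blank, !is_postpartum)
  lg <- log2(co$table[, bio$sample_id])
  lg <- sweep(lg, 2, apply(lg, 2, median)) # run-median normalization
  X <- t(lg)
  y <- bio$ga_ultrasound_weeks
  grid <- max(abs(crossprod(scale(X), y - mean(y)))) / length(y) *
    10^seq(0, -10, length.out = 60)
  # uncapped: exact noise-free recovery (the minimum-l1 interpolant may use
  # more features than the clinical cap, which is a separate constraint)
  fit <- run_clock_pipeline(X, y, bio$subject_id,
                            cfg = clock_config(lambda_grid = grid,
                                               max_predictors = Inf,
                                               n_folds = 5, seed = 1))
  pred <- predict(fit$model, X)
  expect_lt(sqrt(mean((pred - y)^2)), 1e-6)
  # the capped model remains near-exact (small penalty-induced bias only)
  capped <- run_clock_pipeline(X, y, bio$subject_id,
                               cfg = clock_config(lambda_grid = grid,
                                                  n_folds = 5, seed = 1))
  expect_lte(length(capped$model$predictors), 5)
  expect_lt(capped$cv$rmse, 0.5)
})

test_that("no held-out prediction comes from a fold containing its subject", {
  sp <- small_processed()
  bio <- dplyr::filter(sp$meta, !is_postpartum)
  lg <- sp$tab[, bio$sample_id]
  fit <- run_clock_pipeline(t(lg), bio$ga_ultrasound_weeks, bio$subject_id,
                            cfg = clock_config(n_folds = 6, seed = 2))
  leak <- fit$cv_predictions |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(nf = dplyr::n_distinct(fold))
  expect_true(all(leak$nf == 1))
  expect_true(all(is.finite(fit$cv_predictions$ga_metabolic)))
})

test_that("frozen-model validation scores an independent cohort", {
  sp <- small_processed()
  bio <- dplyr::filter(sp$meta, !is_postpartum)
  X <- t(sp$tab[, bio$sample_id]); y <- bio$ga_ultrasound_weeks
  half <- bio$subject_id %in% unique(bio$subject_id)[1:8]
  fit <- run_clock_pipeline(X[half, ], y[half], bio$subject_id[half],
                            validation = list(test1 = list(X = X[!half, ],
                                                           y = y[!half])),
                            rescale = TRUE,
                            cfg = clock_config(n_folds = 5, seed = 3))
  expect_named(fit$validation, "test1")
  expect_gte(fit$validation$test1$r, 0.5)
  expect_error(predict(fit$model, X[, 1:2]), "missing predictor")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "contribution") %in% names(td)))
  expect_equal(sum(td$contribution), 1)
})
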