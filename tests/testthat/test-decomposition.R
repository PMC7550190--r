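test_that("noiseless sparse mixtures are recovered at light regularization", {
  rgc <- archetype_design()
  y <- 0.7 * rgc$avg_scores[3, ] + 0.3 * rgc$avg_scores[7, ]
  fit <- fit_unit(y, rgc, lambda = 1e-5)
  expect_true(all(fit$weights >= 0))
  expect_equal(fit$weights[3], 0.7, tolerance = 0.02)
  expect_equal(fit$weights[7], 0.3, tolerance = 0.02)
  expect_lt(max(fit$weights[-c(3, 7)]), 0.02)
  expect_gt(fit$r2_score, 0.99)

  # all-zero target: all-zero model
  f0 <- fit_unit(rep(0, 15), rgc, lambda = 1e-5)
  expect_equal(unname(f0$weights), rep(0, 10))
  expect_equal(f0$bias, 0)

  expect_error(fit_unit(y, rgc, lambda_grid = c(0, 0.1)), "positive")
  expect_error(nonneg_lasso(matrix(0, 15, 3), rnorm(15), 0.01), "all-zero")
})

test_that("the fitted objective matches brute-force search on 3-input toys", {
  set.seed(16)
  rgc <- archetype_design()
  grid <- seq(0, 2, by = 0.05)
  gw <- as.matrix(expand.grid(grid, grid, grid))
  for (rep in 1:5) {
    x <- t(rgc$avg_scores[sample(10, 3), ])
    y <- as.vector(x %*% runif(3, 0, 1.5)) + rnorm(15, 0, 0.1)
    lam <- 10^runif(1, -5, -1)
    fit <- nonneg_lasso(x, y, lam)
    gobj <- apply(gw, 1, function(w) oracle_nnlasso_objective(x, y, w, lam))
    # the solver must never be worse than the best grid point, and the grid
    # optimum can only exceed it by the local resolution of the grid
    expect_lte(fit$objective, min(gobj) + 1e-9)
    near <- oracle_nnlasso_objective(
      x, y, pmin(pmax(round(fit$weights / 0.05) * 0.05, 0), 2), lam)
    expect_lte(min(gobj) - fit$objective, near - fit$objective + 1e-9)
  }
})

test_that("the solver agrees with an independent penalized regression", {
  skip_if_not_installed("glmnet")
  set.seed(17)
  for (rep in 1:10) {
    n <- 15; m <- 6
    x <- matrix(runif(n * m), n, m)
    y <- as.vector(x %*% c(1, 0.5, 0, 0, 0.2, 0)) + rnorm(n, 0, 0.1)
    lam <- 10^runif(1, -4, -1)
    mine <- nonneg_lasso(x, y, lam)
    # glmnet minimizes RSS/(2n) + a*sum(w); a = lam/(2n) matches our cost
    gf <- glmnet::glmnet(x, y, lambda = lam / (2 * n), lower.limits = 0,
                         standardize = FALSE, intercept = TRUE,
                         thresh = 1e-14)
    gw <- as.numeric(stats::coef(gf))[-1]
    expect_equal(mine$weights, gw, tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(mine$objective,
                 oracle_nnlasso_objective(x, y, gw, lam),
                 tolerance = 1e-6)
  }
})

test_that("score prediction is the bias plus weighted cluster averages", {
  rgc <- archetype_design()
  expect_equal(predict_scores(rep(0, 10), 0.3, rgc), rep(0.3, 15))
  w <- replace(rep(0, 10), 4, 1)
  expect_equal(predict_scores(w, 0.1, rgc),
               unname(rgc$avg_scores[4, ] + 0.1), ignore_attr = TRUE)
  set.seed(18)
  wr <- runif(10)
  expect_equal(predict_scores(wr, 0.2, rgc),
               as.vector(0.2 + t(rgc$avg_scores) %*% wr),
               ignore_attr = TRUE)
})

test_that("trace prediction reports correlation and flags degenerate cases", {
  rgc <- archetype_design()
  set.seed(19)
  w <- c(0.8, 0, 0, 0.4, rep(0, 6))
  measured <- 0.1 + as.vector(w %*% rgc$avg_traces)
  pt <- predict_trace(w, 0.1, rgc$avg_traces, measured)
  expect_equal(pt$r_trace, 1, tolerance = 1e-12)
  expect_false(pt$flagged)

  # all-zero weights: flat prediction, correlation undefined
  pt0 <- predict_trace(rep(0, 10), 0.1, rgc$avg_traces, measured)
  expect_true(pt0$flagged)
  expect_true(is.na(pt0$r_trace))
})

test_that("random-weight null is reproducible and below a generative fit", {
  reg <- default_regressors()
  rgc <- archetype_design()
  sim <- simulate_tectal_population(reg, n_units = 1, noise_sigma = 0.05,
                                    seed = 20)
  trace <- sim$trials[[1]][1, ]
  y <- score_population(sim$trials, reg, presmooth = TRUE)$scores[1, ]
  fit <- fit_unit(y, rgc, lambda = 1e-3)
  n1 <- random_weight_null(fit, rgc$avg_traces, trace, n_draws = 200,
                           seed = 5)
  n2 <- random_weight_null(fit, rgc$avg_traces, trace, n_draws = 200,
                           seed = 5)
  expect_identical(n1$null, n2$null)
  expect_gte(n1$quantile, 0.95)
  expect_length(random_weight_null(fit, rgc$avg_traces, trace,
                                   n_draws = 1, seed = 1)$null, 1)
})

test_that("trial-split cross-validation generalizes and absorbs shifts", {
  rgc <- archetype_design()
  y <- 0.6 * rgc$avg_scores[2, ] + 0.4 * rgc$avg_scores[9, ] + 0.05
  cv <- cross_validate_by_trial(y, y, rgc, lambda = 1e-5)
  expect_lt(cv$rmse_cv, 0.01)

  # a constant shift between trials is absorbed by the refit bias
  shift <- 0.5
  cv2 <- cross_validate_by_trial(y, y + shift, rgc, lambda = 1e-5)
  expect_lt(cv2$rmse_cv, shift / 20)

  expect_error(cross_validate_by_trial(y, NULL, rgc), "second trial")
})

test_that("heavy regularization collapses the model to its bias", {
  rgc <- archetype_design()
  set.seed(21)
  y <- runif(15)
  fit <- fit_unit(y, rgc, lambda = 1e6)
  expect_equal(unname(fit$weights), rep(0, 10))
  expect_equal(fit$bias, mean(y))
  expect_identical(fit$n_active, 0L)
})

test_that("per-unit CV picks the penalty with smallest stored CV error", {
  rgc <- archetype_design()
  set.seed(22)
  y <- as.vector(t(rgc$avg_scores) %*% replace(rep(0, 10), c(1, 6),
                                               c(0.8, 0.5))) +
    rnorm(15, 0, 0.05)
  fit <- fit_unit(y, rgc)
  expect_true(all(fit$weights >= 0))
  tab <- fit$cv_table
  expect_equal(min(tab$cv_mse), tab$cv_mse[tab$lambda == fit$lambda][1],
               tolerance = 1e-12)
})

test_that("population-level penalty selection minimizes trial-split error", {
  reg <- default_regressors()
  rgc <- archetype_design()
  sim <- simulate_tectal_population(reg, n_units = 40, noise_sigma = 0.1,
                                    seed = 23)
  ts <- lapply(1:2, function(t)
    score_population(sim$trials[t], reg, presmooth = TRUE)$scores)
  sel <- select_lambda_population(ts, rgc)
  expect_identical(sel$lambda,
                   sel$cv_table$lambda[which.min(sel$cv_table$cv_mse)])
  comb <- score_population(sim$trials, reg, presmooth = TRUE)$scores
  res <- decompose_units(comb, rgc, traces = sim$trials[[1]],
                         trial_scores = ts)
  expect_true(all(res$lambda == sel$lambda))
  expect_true(all(as.matrix(res[, paste0("w_", 1:10)]) >= 0))
  expect_true(all(res$n_active == rowSums(res[, paste0("w_", 1:10)] > 0)))
})
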