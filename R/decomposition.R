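#' Non-negative L1-regularized least squares (coordinate descent)
#'
#' Minimizes `sum_i (y_i - b - sum_j w_j x_ij)^2 + lambda * sum_j w_j`
#' subject to `w_j >= 0`, with a free, unpenalized intercept `b`. Cyclic
#' coordinate descent with exact non-negative soft-threshold updates; the
#' penalty applies to the raw (already non-negative) weights, so the update
#' for coordinate j is `max(0, (x_j . r_j - lambda/2) / (x_j . x_j))`.
#'
#' Because the intercept is free and unpenalized, the problem is solved on
#' centered data in Gram form, where the stationarity conditions reduce to
#' a non-negative least-squares problem with target `X'y - lambda/2`:
#' active coordinates satisfy `(Gw)_j = (X'y)_j - lambda/2`, inactive ones
#' `(Gw)_j >= (X'y)_j - lambda/2`. A Lawson-Hanson active-set iteration
#' solves this exactly (weights of inactive coordinates are exact zeros).
#' The bias is recovered as `mean(y) - sum(w * colMeans(x))`.
#'
#' @param x Design matrix (observations x predictors).
#' @param y Response vector.
#' @param lambda Penalty strength (>= 0).
#' @param max_iter Safety cap on active-set changes.
#' @param tol Tolerance on the optimality (KKT) checks.
#' @param init Ignored (kept for call compatibility); the active-set solve
#'   is exact and needs no warm start.
#' @return List with `weights`, `bias`, `objective`, `iterations`.
#' @export
nonneg_lasso <- function(x, y, lambda, max_iter = 1000, tol = 1e-12,
                         init = NULL) {
  stopifnot(is.matrix(x), length(y) == nrow(x), lambda >= 0,
            all(is.finite(x)), all(is.finite(y)))
  if (all(x == 0)) stop("all-zero design matrix")
  m <- ncol(x)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  g <- crossprod(xc)
  b_t <- as.vector(crossprod(xc, yc)) - lambda / 2
  scale <- max(abs(b_t), 1)
  w <- numeric(m)
  active <- logical(m)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) break
    grad <- b_t - as.vector(g %*% w)
    cand <- which(!active & grad > tol * scale & diag(g) > 0)
    if (!length(cand)) break
    active[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      s <- which(active)
      ws <- tryCatch(solve(g[s, s, drop = FALSE], b_t[s]),
                     error = function(e) NULL)
      if (is.null(ws)) {  # singular active Gram: drop the newest coordinate
        active[s[length(s)]] <- FALSE
        break
      }
      if (all(ws > 0)) {
        w[] <- 0
        w[s] <- ws
        break
      }
      # step toward ws until the first coordinate hits zero, then drop it
      neg <- which(ws <= 0)
      alpha <- min(w[s][neg] / (w[s][neg] - ws[neg]))
      w[s] <- w[s] + alpha * (ws - w[s])
      active[s][ws <= 0 & w[s] <= tol * scale] <- FALSE
      w[!active] <- 0
    }
  }
  rss <- sum((yc - as.vector(xc %*% w))^2)
  list(weights = w, bias = ym - sum(w * xm),
       objective = rss + lambda * sum(w), iterations = it)
}

#' Default regularization grid
#'
#' Log-scale grid between 1e-5 and 1e-1.
#' @param n Number of grid points (default 9).
#' @return Numeric vector.
#' @export
lambda_grid_default <- function(n = 9) 10^seq(-5, -1, length.out = n)

cv_folds_dims <- function(n_obs, n_folds) ((seq_len(n_obs) - 1L) %% n_folds) + 1L

#' Fit the RGC-input decomposition of one tectal unit
#'
#' Non-negative L1-regularized regression of the unit's 15-dimensional
#' score vector on the 15-dimensional average scores of the RGC clusters.
#' The penalty strength is chosen from a log-scale grid over [1e-5, 1e-1]
#' by minimizing cross-validated mean squared error (deterministic 5-fold
#' split over the 15 score dimensions), then the model is refit on all
#' dimensions.
#'
#' @param y The unit's 15-dim score vector.
#' @param rgc An `rgc_cluster_matrix` (see [rgc_cluster_matrix()]) or a
#'   clusters x 15 matrix of average scores.
#' @param lambda_grid Candidate penalties (> 0).
#' @param n_folds Folds of the inner CV (default 5).
#' @param unit_id Carried through.
#' @param lambda Fixed penalty; when given (e.g. a population-level value
#'   from [select_lambda_population()]) the per-unit CV is skipped.
#' @return A `decomposition_result`: `weights` (non-negative, one per RGC
#'   cluster), `bias`, `lambda`, `r2_score` (squared Pearson correlation of
#'   predicted vs measured scores), `n_active`, `cv_table`, `objective`.
#' @export
fit_unit <- function(y, rgc, lambda_grid = lambda_grid_default(),
                     n_folds = 5, unit_id = NA, lambda = NULL) {
  avg <- if (is.list(rgc)) rgc$avg_scores else rgc
  stopifnot(is.matrix(avg), length(y) == ncol(avg),
            length(lambda_grid) >= 1)
  if (any(lambda_grid <= 0)) stop("lambda grid values must be positive")
  x <- t(avg)
  if (!is.null(lambda)) {
    fit <- nonneg_lasso(x, y, lambda)
    pred <- fit$bias + as.vector(x %*% fit$weights)
    r2 <- if (stats::sd(pred) > 0 && stats::sd(y) > 0)
      stats::cor(pred, y)^2 else NA_real_
    return(structure(list(unit_id = unit_id, weights = fit$weights,
                          bias = fit$bias, lambda = lambda, r2_score = r2,
                          n_active = sum(fit$weights > 0),
                          objective = fit$objective, cv_table = NULL),
                     class = "decomposition_result"))
  }
  folds <- cv_folds_dims(length(y), n_folds)
  ord <- order(lambda_grid, decreasing = TRUE)  # warm starts down the path
  cv_se <- numeric(length(lambda_grid))
  for (f in unique(folds)) {
    tr <- folds != f
    w0 <- NULL
    for (li in ord) {
      fit <- nonneg_lasso(x[tr, , drop = FALSE], y[tr], lambda_grid[li],
                          init = w0)
      w0 <- fit$weights
      pred <- fit$bias + as.vector(x[!tr, , drop = FALSE] %*% fit$weights)
      cv_se[li] <- cv_se[li] + sum((y[!tr] - pred)^2)
    }
  }
  cv_mse <- cv_se / length(y)
  # ties toward the larger (sparser) penalty
  best <- which(cv_mse <= min(cv_mse) + 1e-15)
  lam <- max(lambda_grid[best])
  fit <- nonneg_lasso(x, y, lam)
  pred <- fit$bias + as.vector(x %*% fit$weights)
  r2 <- if (stats::sd(pred) > 0 && stats::sd(y) > 0)
    stats::cor(pred, y)^2 else NA_real_
  structure(list(unit_id = unit_id, weights = fit$weights, bias = fit$bias,
                 lambda = lam, r2_score = r2,
                 n_active = sum(fit$weights > 0),
                 objective = fit$objective,
                 cv_table = data.frame(lambda = lambda_grid,
                                       cv_mse = cv_mse)),
            class = "decomposition_result")
}

#' Predict a 15-dim score vector from fitted weights
#'
#' `PredScore = b + sum_j w_j AvgScore_RGC_j`, elementwise over the 15
#' regressor dimensions.
#'
#' @param weights Non-negative weight vector (one per RGC cluster).
#' @param bias Scalar intercept.
#' @param rgc `rgc_cluster_matrix` or clusters x 15 average-score matrix.
#' @return Numeric vector of 15 predicted scores.
#' @export
predict_scores <- function(weights, bias, rgc) {
  avg <- if (is.list(rgc)) rgc$avg_scores else rgc
  stopifnot(length(weights) == nrow(avg))
  bias + as.vector(weights %*% avg)
}

#' Predict a calcium trace from weighted RGC cluster averages
#'
#' Predicted trace = bias + dot product of the weights with the cluster
#' average dF/F traces; `r_trace` is its Pearson correlation with the
#' measured trace (undefined and flagged when either trace has zero
#' variance).
#'
#' @param weights,bias Fitted decomposition parameters.
#' @param avg_traces Clusters x time matrix of cluster-mean dF/F.
#' @param measured Measured dF/F trace of the unit.
#' @return List with `predicted`, `r_trace` (`NA` when undefined),
#'   `flagged`.
#' @export
predict_trace <- function(weights, bias, avg_traces, measured) {
  stopifnot(length(weights) == nrow(avg_traces),
            length(measured) == ncol(avg_traces))
  pred <- bias + as.vector(weights %*% avg_traces)
  flagged <- stats::sd(measured) == 0 || stats::sd(pred) == 0
  r <- if (flagged) NA_real_ else stats::cor(pred, measured)
  list(predicted = pred, r_trace = r, flagged = flagged)
}

#' Random-weight null distribution for the trace prediction
#'
#' Draws `n_draws` non-negative weight vectors on the scale of the fitted
#' weights (each coordinate Uniform[0, 2 x max fitted weight]; unit scale
#' when all fitted weights are zero), computes `r_trace` for each draw, and
#' locates the fitted model's correlation within the null.
#'
#' @param fitted A `decomposition_result`.
#' @param avg_traces Clusters x time matrix of cluster-mean dF/F.
#' @param measured Measured dF/F trace.
#' @param n_draws Number of null draws (default 1000).
#' @param seed RNG seed.
#' @return List with `null` (r_trace per draw), `r_fit`, `quantile`
#'   (fraction of null draws below the fitted r_trace).
#' @export
random_weight_null <- function(fitted, avg_traces, measured,
                               n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  scale <- 2 * max(fitted$weights)
  if (scale <= 0) scale <- 1
  set.seed(seed)
  m <- nrow(avg_traces)
  null <- vapply(seq_len(n_draws), function(i) {
    w <- stats::runif(m, 0, scale)
    predict_trace(w, fitted$bias, avg_traces, measured)$r_trace
  }, numeric(1))
  r_fit <- predict_trace(fitted$weights, fitted$bias, avg_traces,
                         measured)$r_trace
  list(null = null, r_fit = r_fit, quantile = mean(null < r_fit))
}

#' Population-level penalty selection by trial-split cross-validation
#'
#' Grid search for the regularization strength shared by all units: for
#' every candidate, each unit's model is fit on one trial's score vector
#' and evaluated (mean squared error) on the other trial's, in both
#' directions; the penalty minimizing the population mean is returned.
#' This mirrors validating the model by holding out one of the two
#' acquisition trials per cell.
#'
#' @param trial_scores List of two units x 15 score matrices (one per
#'   trial).
#' @param rgc `rgc_cluster_matrix` or clusters x 15 average-score matrix.
#' @param lambda_grid Candidate penalties.
#' @return List with `lambda` and `cv_table` (lambda, cv_mse).
#' @export
select_lambda_population <- function(trial_scores, rgc,
                                     lambda_grid = lambda_grid_default()) {
  stopifnot(length(trial_scores) == 2)
  avg <- if (is.list(rgc)) rgc$avg_scores else rgc
  x <- t(avg)
  s1 <- trial_scores[[1]]; s2 <- trial_scores[[2]]
  stopifnot(nrow(s1) == nrow(s2))
  cv <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(nrow(s1)), function(i) {
      f1 <- nonneg_lasso(x, s1[i, ], lam)
      f2 <- nonneg_lasso(x, s2[i, ], lam)
      (mean((s2[i, ] - (f1$bias + as.vector(x %*% f1$weights)))^2) +
       mean((s1[i, ] - (f2$bias + as.vector(x %*% f2$weights)))^2)) / 2
    }, numeric(1)))
  }, numeric(1))
  list(lambda = lambda_grid[which.min(cv)],
       cv_table = data.frame(lambda = lambda_grid, cv_mse = cv))
}

#' Trial-split cross-validation of the decomposition
#'
#' Fits the model on the score vector of one trial and evaluates the root
#' mean squared error of the predicted vs the other trial's scores; both
#' directions are averaged. The unpenalized intercept models a
#' trial-specific baseline offset, so it is re-estimated on the held-out
#' trial: the RMSE judges the weighted RGC component, not baseline drift
#' between acquisitions.
#'
#' @param y_trial1,y_trial2 The unit's 15-dim score vectors per trial.
#' @param rgc `rgc_cluster_matrix` or average-score matrix.
#' @param ... Passed to [fit_unit()].
#' @return List with `rmse_cv` and the two directional RMSEs.
#' @export
cross_validate_by_trial <- function(y_trial1, y_trial2, rgc, ...) {
  if (is.null(y_trial2)) stop("second trial missing")
  one <- function(ytr, yte) {
    fit <- fit_unit(ytr, rgc, ...)
    pred <- predict_scores(fit$weights, 0, rgc)
    sqrt(mean((yte - pred - mean(yte - pred))^2))
  }
  r12 <- one(y_trial1, y_trial2)
  r21 <- one(y_trial2, y_trial1)
  list(rmse_cv = (r12 + r21) / 2, rmse_12 = r12, rmse_21 = r21)
}

#' Average RGC cluster scores and traces from a cluster model
#'
#' Builds the decomposition design: per final RGC cluster, the mean score
#' vector of its member units and the mean dF/F trace (averaged over
#' members and trials).
#'
#' @param labels Per-unit final cluster labels (`NA` = unclustered).
#' @param scores Units x 15 score matrix (same rows as `labels`).
#' @param trials List of dF/F matrices (units x time), one per trial.
#' @return An `rgc_cluster_matrix`: `avg_scores` (clusters x 15),
#'   `avg_traces` (clusters x time), `cluster_sizes`.
#' @export
rgc_cluster_matrix <- function(labels, scores, trials) {
  ks <- sort(unique(labels[!is.na(labels)]))
  stopifnot(length(ks) >= 1)
  avg_scores <- t(vapply(ks, function(k)
    colMeans(scores[which(labels == k), , drop = FALSE]),
    numeric(ncol(scores))))
  mean_trace <- Reduce(`+`, trials) / length(trials)
  avg_traces <- t(vapply(ks, function(k)
    colMeans(mean_trace[which(labels == k), , drop = FALSE]),
    numeric(ncol(mean_trace))))
  rownames(avg_scores) <- rownames(avg_traces) <- paste0("RGC", ks)
  structure(list(avg_scores = avg_scores, avg_traces = avg_traces,
                 cluster_sizes = as.integer(table(labels)[as.character(ks)])),
            class = "rgc_cluster_matrix")
}

#' Decompose a population of tectal units
#'
#' Driver over [fit_unit()], [predict_trace()] and
#' [cross_validate_by_trial()], returning one row per unit in the result
#' table layout used for export. When per-trial scores are available the
#' penalty is selected once for the whole population by
#' [select_lambda_population()] (trial-split grid search); otherwise each
#' unit runs its own inner CV.
#'
#' @param scores Units x 15 combined score matrix.
#' @param rgc An `rgc_cluster_matrix`.
#' @param traces Optional units x time dF/F matrix for `r_trace`.
#' @param trial_scores Optional list of two per-trial score matrices for
#'   penalty selection and `rmse_cv`.
#' @param lambda_grid Candidate penalties.
#' @param lambda Fixed penalty overriding selection.
#' @param ... Passed to [fit_unit()].
#' @return `data.frame`: unit_id, w_1..w_K, bias, lambda, r2_score,
#'   r_trace, rmse_cv, n_active.
#' @export
decompose_units <- function(scores, rgc, traces = NULL,
                            trial_scores = NULL,
                            lambda_grid = lambda_grid_default(),
                            lambda = NULL, ...) {
  n <- nrow(scores)
  k <- nrow(rgc$avg_scores)
  if (is.null(lambda) && !is.null(trial_scores))
    lambda <- select_lambda_population(trial_scores, rgc, lambda_grid)$lambda
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- fit_unit(scores[i, ], rgc, lambda_grid = lambda_grid,
                    unit_id = i, lambda = lambda, ...)
    rt <- if (!is.null(traces))
      predict_trace(fit$weights, fit$bias, rgc$avg_traces,
                    traces[i, ])$r_trace else NA_real_
    rmse <- if (!is.null(trial_scores))
      cross_validate_by_trial(trial_scores[[1]][i, ], trial_scores[[2]][i, ],
                              rgc, lambda_grid = lambda_grid,
                              lambda = lambda, ...)$rmse_cv else NA_real_
    row <- c(list(unit_id = i),
             stats::setNames(as.list(fit$weights), paste0("w_", seq_len(k))),
             list(bias = fit$bias, lambda = fit$lambda,
                  r2_score = fit$r2_score, r_trace = rt, rmse_cv = rmse,
                  n_active = fit$n_active))
    out[[i]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}
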