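#' Compute dF/F from a raw fluorescence trace
#'
#' The trace is uniformly filtered over three frames (reflect padding at the
#' edges), the baseline F0 is the 5th percentile of the filtered trace
#' (linear-interpolation percentile), and dF/F = (F - F0) / F0.
#'
#' @param raw Numeric vector of raw fluorescence.
#' @return Numeric dF/F vector of the same length.
#' @export
compute_dff <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 3, all(is.finite(raw)))
  sm <- uniform3(raw)
  f0 <- stats::quantile(sm, 0.05, names = FALSE, type = 7)
  if (f0 <= 0) stop("invalid baseline: 5th percentile of filtered trace <= 0")
  (sm - f0) / f0
}

uniform3 <- function(x) {
  n <- length(x)
  xp <- c(x[2], x, x[n - 1])  # reflect padding
  (xp[1:n] + xp[2:(n + 1)] + xp[3:(n + 2)]) / 3
}

#' Score a unit's dF/F trace against every regressor
#'
#' For each of the 15 regressors, an ordinary least-squares fit (free
#' intercept) of the dF/F on the regressor within that regressor's response
#' window gives the coefficient of regression CR (in dF/F units) and the
#' squared Pearson correlation R-squared of the fit; the response score is
#' CR x R-squared. Zero-variance regressors (or windows with constant dF/F)
#' get score 0, R-squared 0, and a flag.
#'
#' @param dff dF/F vector, same length as the regressor matrix.
#' @param regressors A `regressor_matrix`.
#' @param unit_id Optional identifier carried through.
#' @return A `score_vector`: `scores`, `cr`, `r2` (each length 15, named),
#'   `flagged` logical, `unit_id`, `normalized = FALSE`.
#' @export
score_unit <- function(dff, regressors, unit_id = NA) {
  stopifnot(length(dff) == nrow(regressors$values), all(is.finite(dff)))
  ch <- regressors$regressor_names
  cr <- r2 <- sc <- stats::setNames(numeric(length(ch)), ch)
  flagged <- stats::setNames(logical(length(ch)), ch)
  for (j in seq_along(ch)) {
    m <- window_mask(regressors, j)
    x <- regressors$values[m, j]
    y <- dff[m]
    vx <- stats::var(x)
    if (!any(m) || vx == 0 || stats::var(y) == 0) {
      flagged[j] <- TRUE
      next
    }
    slope <- stats::cov(x, y) / vx
    r <- stats::cor(x, y)
    cr[j] <- slope
    r2[j] <- r * r
    sc[j] <- slope * r * r
  }
  structure(list(unit_id = unit_id, scores = sc, cr = cr, r2 = r2,
                 flagged = flagged, normalized = FALSE),
            class = "score_vector")
}

#' Combine the score vectors of the two trials
#'
#' Per regressor, the final score is the R-squared-weighted average of the
#' two trial scores, `(s1 r1 + s2 r2) / (r1 + r2)`; if both R-squared are 0
#' the combined score is 0. The combined R-squared uses the same weighting.
#'
#' @param s1,s2 `score_vector`s for the same unit and regressor set.
#' @return A combined `score_vector`.
#' @export
combine_trials <- function(s1, s2) {
  stopifnot(inherits(s1, "score_vector"), inherits(s2, "score_vector"))
  if (!identical(s1$unit_id, s2$unit_id))
    stop("mismatched unit ids: ", s1$unit_id, " vs ", s2$unit_id)
  stopifnot(identical(names(s1$scores), names(s2$scores)))
  w <- s1$r2 + s2$r2
  sc <- ifelse(w > 0, (s1$scores * s1$r2 + s2$scores * s2$r2) / w, 0)
  r2 <- ifelse(w > 0, (s1$r2^2 + s2$r2^2) / w, 0)
  cr <- ifelse(w > 0, (s1$cr * s1$r2 + s2$cr * s2$r2) / w, 0)
  structure(list(unit_id = s1$unit_id, scores = sc, cr = cr, r2 = r2,
                 flagged = s1$flagged & s2$flagged, normalized = FALSE),
            class = "score_vector")
}

#' Score a population of traces, combining trials
#'
#' Convenience driver over [score_unit()] and [combine_trials()]: takes one
#' dF/F matrix per trial (units x time, aligned rows) and returns the
#' combined per-unit score matrix.
#'
#' @param trials List of dF/F matrices (units x time), one per trial.
#' @param regressors A `regressor_matrix`.
#' @param unit_ids Optional row identifiers.
#' @param presmooth Apply the 3-frame uniform filter to each trace first.
#'   Use for traces that entered as dF/F directly and so skipped the
#'   filtering step of [compute_dff()]; leave `FALSE` for traces already
#'   processed by it.
#' @return List with `scores` and `r2` (units x 15 matrices).
#' @export
score_population <- function(trials, regressors, unit_ids = NULL,
                             presmooth = FALSE) {
  stopifnot(is.list(trials), length(trials) >= 1)
  if (presmooth)
    trials <- lapply(trials, function(m) t(apply(m, 1, uniform3)))
  n <- nrow(trials[[1]])
  if (is.null(unit_ids)) unit_ids <- seq_len(n)
  ch <- regressors$regressor_names
  scores <- r2 <- matrix(0, n, length(ch),
                         dimnames = list(unit_ids, ch))
  for (i in seq_len(n)) {
    sv <- score_unit(trials[[1]][i, ], regressors, unit_id = unit_ids[i])
    for (tr in seq_along(trials)[-1])
      sv <- combine_trials(sv, score_unit(trials[[tr]][i, ], regressors,
                                          unit_id = unit_ids[i]))
    scores[i, ] <- sv$scores
    r2[i, ] <- sv$r2
  }
  list(scores = scores, r2 = r2)
}

#' Normalize scores per fish to the 99th percentile
#'
#' Every score of a fish's units is divided by the 99th percentile
#' (linear-interpolation percentile) of all score values recorded for that
#' fish, so score magnitudes are comparable across fish.
#'
#' @param scores Units x 15 score matrix.
#' @param fish Fish identifier per unit (recycled if length 1).
#' @return List with `scores` (normalized matrix) and `factors` (named
#'   per-fish 99th percentiles).
#' @export
normalize_scores <- function(scores, fish = 1L) {
  stopifnot(is.matrix(scores))
  if (length(fish) == 1L) fish <- rep(fish, nrow(scores))
  stopifnot(length(fish) == nrow(scores))
  out <- scores
  fids <- unique(fish)
  factors <- stats::setNames(numeric(length(fids)), fids)
  for (f in fids) {
    rows <- fish == f
    p99 <- stats::quantile(scores[rows, , drop = FALSE], 0.99,
                           names = FALSE, type = 7)
    if (p99 <= 0) stop("99th percentile of scores <= 0 for fish ", f)
    out[rows, ] <- scores[rows, , drop = FALSE] / p99
    factors[as.character(f)] <- p99
  }
  list(scores = out, factors = factors)
}
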