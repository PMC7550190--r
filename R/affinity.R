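#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing on a similarity
#' matrix of negative squared Euclidean distances, with the preference
#' (self-similarity) set to the median of the off-diagonal similarities.
#' Exemplars are points whose self responsibility plus availability is
#' positive; every point is assigned to its most similar exemplar.
#'
#' @param x Numeric matrix, observations in rows.
#' @param preference Self-similarity; default median off-diagonal
#'   similarity.
#' @param damping Message damping factor in (0.5, 1); default 0.9.
#' @param max_iter Maximum iterations (default 1000).
#' @param conv_iter Stop once the exemplar set is unchanged for this many
#'   consecutive iterations (default 100).
#' @return List with `exemplars` (row indices), `labels` (per-row exemplar
#'   index), `iterations`.
#' @export
affinity_propagation <- function(x, preference = NULL, damping = 0.9,
                                 max_iter = 1000, conv_iter = 100) {
  stopifnot(is.matrix(x), nrow(x) >= 2, damping >= 0.5, damping < 1)
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  if (all(d2 < 1e-24)) {  # degenerate: all rows identical
    return(list(exemplars = 1L, labels = rep(1L, n), iterations = 0L))
  }
  s <- -d2
  if (is.null(preference))
    preference <- stats::median(s[upper.tri(s) | lower.tri(s)])
  diag(s) <- preference
  # tiny deterministic jitter to break exact ties (standard practice)
  s <- s + s * 1e-12 * matrix(seq_len(n * n) %% 7 - 3, n, n) / 3

  r <- a <- matrix(0, n, n)
  stable <- 0L
  last_ex <- integer(0)
  it <- 0L
  idx <- seq_len(n)
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    as_ <- a + s
    m1 <- apply(as_, 1, max)
    w1 <- max.col(as_, ties.method = "first")
    as2 <- as_
    as2[cbind(idx, w1)] <- -Inf
    m2 <- apply(as2, 1, max)
    mx <- matrix(m1, n, n)
    mx[cbind(idx, w1)] <- m2
    r <- damping * r + (1 - damping) * (s - mx)
    # availabilities
    rp <- pmax(r, 0)
    diag(rp) <- diag(r)
    cs <- rep(colSums(rp), each = n)
    anew <- matrix(cs, n, n) - rp
    dA <- diag(anew)
    anew <- pmin(anew, 0)
    diag(anew) <- dA
    a <- damping * a + (1 - damping) * anew
    ex <- which(diag(r) + diag(a) > 0)
    if (length(ex) && identical(ex, last_ex)) stable <- stable + 1L
    else { stable <- 0L; last_ex <- ex }
    if (stable >= conv_iter) break
  }
  if (stable < conv_iter || length(last_ex) == 0)
    stop(sprintf(
      "affinity propagation did not converge within %d iterations (damping %.2f)",
      max_iter, damping))
  ex <- last_ex
  labels <- ex[max.col(s[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  list(exemplars = ex, labels = labels, iterations = it)
}
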