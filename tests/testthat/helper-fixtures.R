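# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles are deliberately naive implementations kept
# separate from the package's code paths.

default_regressors <- function() {
  if (is.null(.fixture_env$reg))
    .fixture_env$reg <- build_regressors(build_default_protocol(2),
                                         make_kernel(sampling_rate = 2))
  .fixture_env$reg
}
.fixture_env <- new.env()

# archetype score matrix as the decomposition design (scored, presmoothed
# noiseless archetype traces)
archetype_design <- function() {
  if (is.null(.fixture_env$design)) {
    reg <- default_regressors()
    a <- rgc_archetypes()
    tr <- a %*% t(reg$values)
    sc <- score_population(list(tr), reg, presmooth = TRUE)$scores
    rownames(sc) <- rownames(a)
    .fixture_env$design <- list(avg_scores = sc, avg_traces = tr)
  }
  .fixture_env$design
}

# O(T*K) sample-by-sample convolution
oracle_convolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n))
    for (j in seq_len(min(t, length(k))))
      out[t] <- out[t] + x[t - j + 1] * k[j]
  out
}

# two-pass closed-form OLS of y on x (slope, intercept, squared Pearson r)
oracle_ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(cr = slope, r2 = r2, score = slope * r2)
}

# naive UPGMA agglomeration on a distance matrix; returns merge heights and
# a function giving labels at a cut height
oracle_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  merges <- list()
  dm <- d
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- c(NA, NA); bh <- Inf
    for (a in idx) for (b in idx) if (a < b && dm[a, b] < bh) {
      bh <- dm[a, b]; best <- c(a, b)
    }
    a <- best[1]; b <- best[2]
    newc <- c(clusters[[a]], clusters[[b]])
    clusters[[length(clusters) + 1]] <- newc
    merges[[length(merges) + 1]] <- list(members = newc, height = bh)
    active[c(a, b)] <- FALSE
    active <- c(active, TRUE)
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    newrow <- (na * dm[a, ] + nb * dm[b, ]) / (na + nb)
    dm <- rbind(cbind(dm, newrow), c(newrow, Inf))
    dm[length(clusters), length(clusters)] <- Inf
    dm[!c(active, rep(FALSE, nrow(dm) - length(active))), ] <- Inf
    dm[, !active] <- Inf
  }
  labels_at <- function(h) {
    lab <- seq_len(n)
    for (m in merges) if (m$height <= h) lab[m$members] <- min(lab[m$members])
    as.integer(factor(lab))
  }
  list(labels_at = labels_at,
       heights = vapply(merges, `[[`, numeric(1), "height"))
}

# mean silhouette from first principles on a distance matrix
oracle_silhouette <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Andrew monotone-chain convex hull area
oracle_hull_area <- function(xy) {
  xy <- unique(xy[order(xy[, 1], xy[, 2]), , drop = FALSE])
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(pts) {
    h <- list()
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], p) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- p
    }
    h
  }
  lower <- build(xy)
  upper <- build(xy[rev(seq_len(n)), , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  i2 <- c(2:nrow(hull), 1)
  abs(sum(hull[, 1] * hull[i2, 2] - hull[i2, 1] * hull[, 2])) / 2
}

# brute-force objective of the non-negative L1 problem with optimal bias
oracle_nnlasso_objective <- function(x, y, w, lambda) {
  b <- mean(y - x %*% w)
  sum((y - b - x %*% w)^2) + lambda * sum(w)
}
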