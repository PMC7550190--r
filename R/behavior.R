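gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- ceiling(4 * sigma)
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Segment swim bouts from the tail-tip angle trace
#'
#' Change-point detection on the derivative of the tail angle, realized as
#' hysteresis thresholding of the Gaussian-smoothed absolute first
#' derivative: epochs exceeding the high threshold, extended to the
#' surrounding low-threshold crossings, become bouts. Epochs closer than
#' `min_gap_frames` are merged; bouts shorter than `min_bout_frames` are
#' dropped. Defaults are tuned for 500 Hz tracking.
#'
#' @param tail_tip_angle Signed tail-tip angle per frame, degrees
#'   (positive = rightward bend).
#' @param frame_rate Hz (default 500).
#' @param smooth_sigma Gaussian smoothing sigma, frames (default 2).
#' @param high_threshold,low_threshold Hysteresis thresholds on the
#'   smoothed |derivative|, degrees/second (defaults 300 and 150; both sit
#'   well below the derivative peak of even a weak bout and well above the
#'   smoothed tracking-noise floor).
#' @param min_bout_frames Minimum bout duration (default 20).
#' @param min_gap_frames Minimum inter-bout gap (default 10).
#' @return `data.frame` with `start_frame`, `end_frame` (empty on a flat
#'   trace).
#' @export
segment_bouts <- function(tail_tip_angle, frame_rate = 500,
                          smooth_sigma = 2, high_threshold = 300,
                          low_threshold = 150, min_bout_frames = 20,
                          min_gap_frames = 10) {
  stopifnot(length(tail_tip_angle) > 2, frame_rate > 0,
            high_threshold >= low_threshold)
  d <- c(0, diff(tail_tip_angle)) * frame_rate
  s <- gaussian_smooth(abs(d), smooth_sigma)
  above_low <- s > low_threshold
  r <- rle(above_low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  # keep runs that reach the high threshold (hysteresis)
  keep <- vapply(seq_len(nrow(runs)), function(i)
    any(s[runs$start[i]:runs$end[i]] > high_threshold), logical(1))
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  # merge runs separated by less than the minimum gap
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] < min_gap_frames)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  merged <- merged[merged$end - merged$start + 1L >= min_bout_frames, ,
                   drop = FALSE]
  data.frame(start_frame = merged$start, end_frame = merged$end)
}

#' Per-fish eye-convergence threshold from the bimodal angle distribution
#'
#' Kernel density estimate (Gaussian, Scott's-rule bandwidth) of the eye
#' convergence angles; the threshold is the interior local minimum of the
#' density between its two largest modes. Errors if the distribution is
#' unimodal.
#'
#' @param convergence_angle Convergence angle samples, degrees (>= 1000
#'   samples).
#' @return Threshold angle, degrees.
#' @export
convergence_threshold <- function(convergence_angle) {
  stopifnot(length(convergence_angle) >= 1000)
  d <- stats::density(convergence_angle, bw = "nrd")
  y <- d$y
  n <- length(y)
  ismax <- which(y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(ismax) < 2)
    stop("convergence-angle distribution is unimodal; no threshold")
  peaks <- ismax[order(-y[ismax])][1:2]
  lo <- min(peaks); hi <- max(peaks)
  between <- lo:hi
  d$x[between[which.min(y[between])]]
}

#' Fraction of time spent hunting (eyes converged)
#'
#' @param convergence_angle Convergence angle per frame, degrees.
#' @param threshold Per-fish convergence threshold, degrees.
#' @return Fraction of frames with convergence above threshold, in [0, 1].
#' @export
hunting_fraction <- function(convergence_angle, threshold) {
  stopifnot(is.finite(threshold))
  mean(convergence_angle > threshold)
}

#' Signed tail-angle integral of one bout
#'
#' Sum of the tail-tip angle samples over the bout; positive values
#' indicate a rightward turn, negative a leftward turn.
#'
#' @param tail_tip_angle Tail-tip angle per frame, degrees.
#' @param start_frame,end_frame Bout extent (inclusive).
#' @return Signed integral, degree-frames.
#' @export
bout_integral <- function(tail_tip_angle, start_frame, end_frame) {
  stopifnot(start_frame >= 1, end_frame <= length(tail_tip_angle),
            start_frame < end_frame)
  sum(tail_tip_angle[start_frame:end_frame])
}

#' Assemble the bout table with eye-convergence context
#'
#' For each segmented bout: the signed integral, turn direction (sign of
#' the integral), eye-convergence state before and after (mean convergence
#' over `flank` frames on each side, against the per-fish threshold), and
#' the J-turn flag -- a bout with eyes unconverged before and converged
#' after.
#'
#' @param tail_tip_angle Tail-tip angle per frame, degrees.
#' @param bouts Output of [segment_bouts()].
#' @param convergence_angle Convergence angle per frame, degrees.
#' @param threshold Per-fish convergence threshold, degrees.
#' @param flank Frames averaged on each side of the bout (default 25).
#' @return `data.frame` with `start_frame`, `end_frame`, `integral`,
#'   `direction`, `converged_before`, `converged_after`, `is_j_turn`.
#' @export
bout_table <- function(tail_tip_angle, bouts, convergence_angle, threshold,
                       flank = 25) {
  n <- length(convergence_angle)
  rows <- lapply(seq_len(nrow(bouts)), function(i) {
    s <- bouts$start_frame[i]; e <- bouts$end_frame[i]
    integ <- bout_integral(tail_tip_angle, s, e)
    pre <- max(1, s - flank):(max(1, s - 1))
    post <- min(n, e + 1):min(n, e + flank)
    cb <- mean(convergence_angle[pre]) > threshold
    ca <- mean(convergence_angle[post]) > threshold
    data.frame(start_frame = s, end_frame = e, integral = integ,
               direction = if (integ > 0) "right" else "left",
               converged_before = cb, converged_after = ca,
               is_j_turn = !cb && ca)
  })
  if (!length(rows))
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      integral = numeric(0), direction = character(0),
                      converged_before = logical(0),
                      converged_after = logical(0),
                      is_j_turn = logical(0)))
  do.call(rbind, rows)
}

#' Direction selectivity index of the initial J-turns
#'
#' `DSI = (# right J-turns - # left J-turns) / (total # J-turns)`: 1 when
#' all J-turns are rightward, -1 when all are leftward, 0 for no overall
#' bias. Turn direction is the sign of the bout integral. With zero
#' J-turns the index is undefined (`NA` with a warning).
#'
#' @param bouts A bout table (see [bout_table()]) with `integral` and
#'   `is_j_turn` columns.
#' @return DSI in [-1, 1], or `NA` if there are no J-turns.
#' @export
direction_selectivity_index <- function(bouts) {
  j <- bouts[bouts$is_j_turn, , drop = FALSE]
  if (nrow(j) == 0) {
    warning("no J-turns: direction selectivity index undefined")
    return(NA_real_)
  }
  n_right <- sum(j$integral > 0)
  n_left <- sum(j$integral < 0)
  (n_right - n_left) / nrow(j)
}

#' Compare a per-fish statistic between two treatment groups
#'
#' Two-sided Mann-Whitney U test on per-fish summary statistics (hunting
#' fractions or direction selectivity indices).
#'
#' @param values Per-fish statistic.
#' @param groups Group label per fish (exactly two groups, >= 2 fish
#'   each).
#' @return List with `statistic` (U), `p_value`, `groups`.
#' @export
compare_groups <- function(values, groups) {
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  a <- values[groups == gl[1]]
  b <- values[groups == gl[2]]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 fish")
  wt <- suppressWarnings(stats::wilcox.test(a, b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, groups = gl)
}

#' Per-fish prey-capture summary
#'
#' End-to-end behavior analysis of one tracked trajectory: bout
#' segmentation, per-fish convergence threshold, bout table, hunting
#' fraction and J-turn direction selectivity.
#'
#' @param track `data.frame` with columns `frame`, `tail_angle_deg`,
#'   `left_eye_deg`, `right_eye_deg`.
#' @param frame_rate Hz (default 500).
#' @param ... Passed to [segment_bouts()].
#' @return List with `bouts` (bout table), `threshold`,
#'   `hunting_fraction`, `n_j_turns`, `dsi`.
#' @export
analyze_trajectory <- function(track, frame_rate = 500, ...) {
  need <- c("tail_angle_deg", "left_eye_deg", "right_eye_deg")
  stopifnot(all(need %in% names(track)))
  conv <- track$left_eye_deg + track$right_eye_deg
  thr <- convergence_threshold(conv)
  seg <- segment_bouts(track$tail_angle_deg, frame_rate, ...)
  bouts <- bout_table(track$tail_angle_deg, seg, conv, thr)
  nj <- sum(bouts$is_j_turn)
  dsi <- if (nj > 0) direction_selectivity_index(bouts) else NA_real_
  list(bouts = bouts, threshold = thr,
       hunting_fraction = hunting_fraction(conv, thr),
       n_j_turns = nj, dsi = dsi)
}
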