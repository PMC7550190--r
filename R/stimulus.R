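#' Names of the 15 regressor channels
#'
#' The stimulus battery decomposes into 15 predictor channels: the 5 degree
#' dot in forward (temporal-to-nasal) and backward directions at two screen
#' elevations (4), the 30 degree dot forward/backward (2), the 5 degree
#' grating forward/backward (2), fast and slow looming discs (2), dark and
#' bright luminance ramps (2), dark and bright flashes (2), and the
#' sustained-dark (post-looming black screen) epoch (1).
#'
#' @return Character vector of length 15.
#' @export
stim_channel_names <- function() {
  c("dot5_fwd_e1", "dot5_bwd_e1", "dot5_fwd_e2", "dot5_bwd_e2",
    "dot30_fwd", "dot30_bwd",
    "grating_fwd", "grating_bwd",
    "loom_fast", "loom_slow",
    "dark_ramp", "bright_ramp", "dark_flash", "bright_flash",
    "sustained_dark")
}

#' Construct a stimulus protocol from an event table
#'
#' @param events Data frame with columns `kind`, `onset`, `duration`,
#'   `size`, `speed`, `direction`, `elevation`, `channel` (channel names
#'   from [stim_channel_names()]). Events must not overlap in time.
#' @param sampling_rate Hz.
#' @param total_duration Seconds; at least the last event offset.
#' @param n_repetitions Number of acquisitions of the protocol (trials).
#' @return A `stim_protocol`.
#' @export
stim_protocol <- function(events, sampling_rate, total_duration,
                          n_repetitions = 2) {
  stopifnot(is.data.frame(events), sampling_rate > 0, total_duration > 0)
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 0) {
    stopifnot(all(events$onset >= 0), all(events$duration > 0))
    off <- events$onset + events$duration
    if (nrow(events) > 1 &&
        any(events$onset[-1] < off[-nrow(events)] - 1e-9))
      stop("stimulus events overlap in time")
    if (total_duration < max(off))
      stop("total_duration shorter than last event")
  }
  structure(list(events = events, sampling_rate = sampling_rate,
                 total_duration = total_duration,
                 n_repetitions = n_repetitions),
            class = "stim_protocol")
}

#' Build the default visual stimulation protocol
#'
#' One pass of the battery, in presentation order: dark ramp (3 s), bright
#' ramp (3 s), dark flash, bright flash; 5 degree dot (90 deg/s) forward
#' then backward, two repetitions each, at the equatorial plane and at
#' ~20 degrees elevation; 30 degree dot forward/backward, two repetitions;
#' 5 degree grating forward/backward at 90 deg/s, two repetitions; fast
#' (~60 deg/s) and slow (~20 deg/s) looming discs, two repetitions each,
#' every looming presentation ending in a sustained black screen. The whole
#' protocol is acquired twice (two trials).
#'
#' @param sampling_rate Imaging frame rate, Hz.
#' @param gap Inter-stimulus interval, seconds.
#' @param ramp_duration,flash_duration,dot_duration,grating_duration
#'   Event durations, seconds.
#' @param loom_fast_duration,loom_slow_duration Looming expansion times,
#'   seconds (fast ~60 deg/s, slow ~20 deg/s linear expansion).
#' @param post_loom_dark Duration of the black screen after each looming
#'   presentation, seconds.
#' @param n_repetitions Number of acquisitions of the full protocol
#'   (trials).
#' @return A `stim_protocol`: ordered event table plus timing metadata.
#' @export
build_default_protocol <- function(sampling_rate = 2, gap = 5,
                                   ramp_duration = 3, flash_duration = 1,
                                   dot_duration = 2, grating_duration = 2,
                                   loom_fast_duration = 1.5,
                                   loom_slow_duration = 4.5,
                                   post_loom_dark = 3,
                                   n_repetitions = 2) {
  stopifnot(sampling_rate > 0)
  dirsuf <- c(forward = "fwd", backward = "bwd")
  ev <- list()
  t <- gap
  add <- function(kind, duration, channel, size = NA_real_,
                  speed = NA_real_, direction = "none",
                  elevation = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, onset = t, duration = duration, size = size,
      speed = speed, direction = direction, elevation = elevation,
      channel = channel, stringsAsFactors = FALSE)
    t <<- t + duration + gap
  }

  add("dark_ramp", ramp_duration, "dark_ramp")
  add("bright_ramp", ramp_duration, "bright_ramp")
  add("dark_flash", flash_duration, "dark_flash")
  add("bright_flash", flash_duration, "bright_flash")
  for (elev in c(0, 20)) {
    suff <- if (elev == 0) "e1" else "e2"
    for (dir in c("forward", "backward"))
      for (rep in 1:2)
        add("dot", dot_duration, paste0("dot5_", dirsuf[dir], "_", suff),
            size = 5, speed = 90, direction = dir, elevation = elev)
  }
  for (dir in c("forward", "backward"))
    for (rep in 1:2)
      add("dot", dot_duration, paste0("dot30_", dirsuf[dir]),
          size = 30, speed = 90, direction = dir, elevation = 10)
  for (dir in c("forward", "backward"))
    for (rep in 1:2)
      add("grating", grating_duration, paste0("grating_", dirsuf[dir]),
          size = 5, speed = 90, direction = dir)
  for (speed_kind in list(c(60, "loom_fast"), c(20, "loom_slow"))) {
    dur <- if (speed_kind[2] == "loom_fast") loom_fast_duration
           else loom_slow_duration
    for (rep in 1:2) {
      add("looming", dur, speed_kind[2], speed = as.numeric(speed_kind[1]))
      add("blank", post_loom_dark, "sustained_dark")
    }
  }
  events <- do.call(rbind, ev)
  stim_protocol(events, sampling_rate, total_duration = t,
                n_repetitions = n_repetitions)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d events, %.1f s/pass x %d passes, %g Hz\n",
              nrow(x$events), x$total_duration, x$n_repetitions,
              x$sampling_rate))
  print(table(x$events$channel))
  invisible(x)
}

#' Construct a GCaMP calcium impulse-response kernel
#'
#' Double-exponential impulse response
#' \eqn{(1 - e^{-t/\tau_{rise}}) e^{-t/\tau_{decay}}}, normalized to unit
#' peak and truncated once the tail falls below 1e-3 of the peak. Default
#' time constants follow typical published GCaMP6 kinetics (decay 1.8 s for
#' the slow 6s variants, 0.5 s for 6f; rise 0.1 s).
#'
#' @param variant One of `"nls_gcamp6s"`, `"cyto_gcamp6s"`, `"nls_gcamp6f"`.
#' @param sampling_rate Hz.
#' @param rise_tau,decay_tau Optional overrides, seconds.
#' @return A `calcium_kernel`: sampled trace plus time constants.
#' @export
make_kernel <- function(variant = c("nls_gcamp6s", "cyto_gcamp6s",
                                    "nls_gcamp6f"),
                        sampling_rate = 2, rise_tau = NULL,
                        decay_tau = NULL) {
  variant <- match.arg(variant)
  if (is.null(rise_tau)) rise_tau <- 0.1
  if (is.null(decay_tau))
    decay_tau <- if (variant == "nls_gcamp6f") 0.5 else 1.8
  stopifnot(decay_tau > rise_tau, sampling_rate > 0)
  dt <- 1 / sampling_rate
  tmax <- decay_tau * 12
  tt <- seq(0, tmax, by = dt)
  k <- (1 - exp(-tt / rise_tau)) * exp(-tt / decay_tau)
  k <- k / max(k)
  peak_at <- which.max(k)
  below <- which(k < 1e-3 & seq_along(k) > peak_at)
  if (length(below)) k <- k[seq_len(below[1])]
  structure(list(variant = variant, rise_tau = rise_tau,
                 decay_tau = decay_tau, kernel_trace = k,
                 sampling_rate = sampling_rate),
            class = "calcium_kernel")
}

channel_indicator <- function(kind, onset, duration, tt) {
  ind <- numeric(length(tt))
  inwin <- tt >= onset - 1e-9 & tt < onset + duration - 1e-9
  if (!any(inwin)) return(ind)
  frac <- (tt[inwin] - onset) / duration
  ind[inwin] <- switch(kind,
    dark_ramp = frac, bright_ramp = frac,   # luminance ramps linearly
    looming = frac,                         # angular size grows linearly
    1)                                      # flashes, dots, gratings, blanks
  ind
}

#' Build the kernel-convolved regressor matrix for a protocol
#'
#' Each of the 15 channels gets a stimulus-indicator time series (box for
#' flashes, dots, gratings and sustained-dark; linear ramp for luminance
#' ramps and looming, whose drive grows with angular size), convolved with
#' the calcium kernel. Response windows span each event epoch plus one
#' kernel decay time constant; recurrent presentations of the same variant
#' yield a union of merged intervals. Columns are scaled to unit peak so a
#' regression slope reads directly in dF/F units.
#'
#' @param protocol A `stim_protocol`.
#' @param kernel A `calcium_kernel` with the same sampling rate.
#' @param normalize Scale each nonzero column to peak 1 (default `TRUE`).
#' @return A `regressor_matrix`: `values` (time x 15), `regressor_names`,
#'   `response_windows` (per channel, matrix of start/end frames),
#'   `sampling_rate`, and `zero_channels` flags.
#' @export
build_regressors <- function(protocol, kernel, normalize = TRUE) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(kernel, "calcium_kernel"))
  if (abs(protocol$sampling_rate - kernel$sampling_rate) > 1e-9)
    stop("protocol and kernel sampling rates differ")
  sr <- protocol$sampling_rate
  n_t <- max(1L, round(protocol$total_duration * sr))
  tt <- (seq_len(n_t) - 1) / sr
  ch <- stim_channel_names()
  k <- kernel$kernel_trace
  vals <- matrix(0, n_t, length(ch), dimnames = list(NULL, ch))
  windows <- stats::setNames(vector("list", length(ch)), ch)
  margin <- kernel$decay_tau
  for (j in seq_along(ch)) {
    evs <- protocol$events[protocol$events$channel == ch[j], , drop = FALSE]
    if (nrow(evs) == 0) {
      windows[[j]] <- matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("start", "end")))
      next
    }
    ind <- numeric(n_t)
    for (e in seq_len(nrow(evs)))
      ind <- ind + channel_indicator(evs$kind[e], evs$onset[e],
                                     evs$duration[e], tt)
    conv <- convolve_causal(ind, k)
    conv[conv < 1e-10] <- 0  # FFT round-off; true convolution is >= 0
    if (normalize && max(conv) > 0) conv <- conv / max(conv)
    vals[, j] <- conv
    iv <- cbind(start = pmax(1L, floor(evs$onset * sr) + 1L),
                end = pmin(n_t, ceiling((evs$onset + evs$duration + margin) *
                                          sr)))
    windows[[j]] <- merge_intervals(iv)
  }
  zero <- colSums(abs(vals)) == 0
  structure(list(values = vals, regressor_names = ch,
                 response_windows = windows, sampling_rate = sr,
                 zero_channels = zero),
            class = "regressor_matrix")
}

convolve_causal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")
  out[seq_len(n)]
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + 1L)
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Logical mask of a regressor's response window
#'
#' @param regressors A `regressor_matrix`.
#' @param j Channel index or name.
#' @return Logical vector over frames; union of the channel's merged
#'   response-window intervals.
#' @export
window_mask <- function(regressors, j) {
  iv <- regressors$response_windows[[j]]
  mask <- logical(nrow(regressors$values))
  for (i in seq_len(nrow(iv))) mask[iv[i, 1]:iv[i, 2]] <- TRUE
  mask
}
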