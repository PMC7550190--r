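#' Archetypal RGC response classes
#'
#' Ten fixed 15-dimensional score archetypes emulating the functional RGC
#' input classes seen in the tectal neuropil: small-dot direction-selective
#' (forward / backward), small-dot non-selective, large-dot, size-invariant
#' dot, fast- and slow-looming, OFF/dimming, ON/brightening, and
#' grating-responsive profiles. Rows are archetypes, columns the 15
#' regressor channels of [stim_channel_names()].
#'
#' The set is constructed to be mutually identifiable: no archetype is
#' close to a non-negative combination of the others (each class carries a
#' private signature, e.g. the non-selective small-dot class also responds
#' weakly to gratings, the size-invariant class to slow looming and dark
#' flashes). Without this property the generative weights of mixture units
#' would not be a well-defined recovery target.
#'
#' @return 10 x 15 numeric matrix.
#' @export
rgc_archetypes <- function() {
  ch <- stim_channel_names()
  a <- rbind(
    small_ds_fwd = c(0.9, 0.05,0.8, 0.05,0.15,0.05,0,   0,   0,   0,   0,   0,   0,   0,   0),
    small_ds_bwd = c(0.05,0.9, 0.05,0.8, 0.05,0.15,0,   0,   0,   0,   0,   0,   0,   0,   0),
    small_all    = c(0.6, 0.6, 0.55,0.55,0.1, 0.1, 0.35,0.35,0,   0,   0,   0,   0,   0,   0),
    large_dot    = c(0.1, 0.1, 0.05,0.05,0.9, 0.85,0,   0,   0.15,0.1, 0,   0,   0,   0,   0),
    size_invar   = c(0.5, 0.5, 0.45,0.45,0.55,0.55,0,   0,   0,   0.3, 0,   0,   0.25,0,   0.15),
    loom_fast    = c(0,   0,   0,   0,   0.1, 0.1, 0,   0,   0.9, 0.3, 0,   0,   0.2, 0,   0.3),
    loom_slow    = c(0,   0,   0,   0,   0,   0,   0,   0,   0.3, 0.9, 0,   0,   0.2, 0,   0.3),
    off_dimming  = c(0,   0,   0,   0,   0,   0,   0,   0,   0.1, 0.1, 0.8, 0,   0.9, 0,   0.6),
    on_brighten  = c(0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0,   0.8, 0,   0.9, 0),
    grating      = c(0.1, 0.1, 0.1, 0.1, 0,   0,   0.8, 0.8, 0,   0,   0,   0,   0,   0,   0.1))
  colnames(a) <- ch
  a
}

archetype_traces <- function(archetypes, regressors) {
  archetypes %*% t(regressors$values)
}

#' Simulate an RGC pixel population
#'
#' Each unit's dF/F trace is the archetype-weighted sum of the regressors
#' (`sum_k archetype_score_k x regressor_k`) plus Gaussian noise;
#' `n_trials` independent-noise trials per unit.
#'
#' @param regressors A `regressor_matrix`.
#' @param n_per_cluster Units generated per archetype.
#' @param noise_sigma Gaussian noise SD in dF/F units (default 0.1).
#' @param seed RNG seed.
#' @param archetypes Archetype score matrix (default [rgc_archetypes()]).
#' @param n_trials Trials per unit (default 2).
#' @return List with `trials` (list of units x time dF/F matrices),
#'   `labels` (generating archetype per unit), `archetypes`.
#' @export
simulate_rgc_population <- function(regressors, n_per_cluster = 30,
                                    noise_sigma = 0.1, seed = 1,
                                    archetypes = rgc_archetypes(),
                                    n_trials = 2) {
  stopifnot(noise_sigma >= 0, n_per_cluster >= 0)
  set.seed(seed)
  n_arch <- nrow(archetypes)
  n <- n_arch * n_per_cluster
  at <- archetype_traces(archetypes, regressors)
  n_t <- ncol(at)
  labels <- rep(seq_len(n_arch), each = n_per_cluster)
  trials <- lapply(seq_len(n_trials), function(tr) {
    m <- at[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * n_t, 0, noise_sigma), n, n_t)
    if (n == 0) m <- matrix(numeric(0), 0, n_t)
    m
  })
  list(trials = trials, labels = labels, archetypes = archetypes)
}

#' Simulate a tectal cell population as sparse mixtures of RGC archetypes
#'
#' Every tectal unit's dF/F is `b + sum_j w_j x archetype_trace_j + noise`,
#' with a sparse non-negative weight vector: support size 1 + Geometric
#' (median support 2), weights Exponential with mean 0.5. Two
#' independent-noise trials per unit. Anterior-posterior soma positions are
#' drawn from cluster-biased Beta distributions: units dominated by the
#' large-dot archetype sit anterior, small-dot-dominated units posterior
#' (position 0 = anterior).
#'
#' @param regressors A `regressor_matrix`.
#' @param n_units Number of tectal units.
#' @param noise_sigma Gaussian noise SD in dF/F units (default 0.1).
#' @param seed RNG seed.
#' @param archetypes Archetype score matrix.
#' @param support_prob Geometric parameter of the support-size draw
#'   (default 0.3, giving median support 2).
#' @param weight_mean Mean of the Exponential weight prior (default 0.5).
#' @param bias_max Per-unit bias drawn Uniform[0, bias_max].
#' @param n_trials Trials per unit (default 2).
#' @return List with `trials`, and `ground_truth` (a
#'   `synthetic_ground_truth`: `rgc_archetypes`, `tectal_weights`
#'   (units x 10), `tectal_bias`, `cluster_labels` (dominant archetype),
#'   `ap_positions`, `noise_sigma`, `seed`).
#' @export
simulate_tectal_population <- function(regressors, n_units = 200,
                                       noise_sigma = 0.1, seed = 1,
                                       archetypes = rgc_archetypes(),
                                       support_prob = 0.3,
                                       weight_mean = 0.5, bias_max = 0.1,
                                       n_trials = 2) {
  stopifnot(noise_sigma >= 0, n_units >= 0)
  set.seed(seed)
  n_arch <- nrow(archetypes)
  at <- archetype_traces(archetypes, regressors)
  n_t <- ncol(at)
  w <- matrix(0, n_units, n_arch)
  bias <- stats::runif(n_units, 0, bias_max)
  for (i in seq_len(n_units)) {
    k <- min(1L + stats::rgeom(1, support_prob), n_arch)
    sup <- sample.int(n_arch, k)
    w[i, sup] <- stats::rexp(k, rate = 1 / weight_mean)
  }
  dominant <- max.col(w, ties.method = "first")
  small_dot <- 1:3; large_dot <- 4L
  ap <- numeric(n_units)
  for (i in seq_len(n_units)) {
    ap[i] <- if (dominant[i] == large_dot) stats::rbeta(1, 2, 5)
             else if (dominant[i] %in% small_dot) stats::rbeta(1, 5, 2)
             else stats::runif(1)
  }
  clean <- w %*% at + bias
  trials <- lapply(seq_len(n_trials), function(tr) {
    m <- clean + matrix(stats::rnorm(n_units * n_t, 0, noise_sigma),
                        n_units, n_t)
    if (n_units == 0) m <- matrix(numeric(0), 0, n_t)
    m
  })
  gt <- structure(list(rgc_archetypes = archetypes, tectal_weights = w,
                       tectal_bias = bias, cluster_labels = dominant,
                       ap_positions = ap, noise_sigma = noise_sigma,
                       seed = seed),
                  class = "synthetic_ground_truth")
  list(trials = trials, ground_truth = gt)
}

#' Simulate a prey-capture tracking session
#'
#' Tail-tip angle built from signed half-sine bout waveforms plus small
#' noise; eye-convergence angle switching between an unconverged and a
#' converged mode. The first `length(j_turn_directions)` bouts are initial
#' J-turns: the convergence mode switches high mid-bout and a hunting
#' episode of `hunt_duration_s` follows, ending before the next bout, so
#' the eyes are unconverged before and converged after exactly those bouts.
#'
#' @param frame_rate Hz (default 500).
#' @param duration_s Session length, seconds.
#' @param n_bouts Number of bouts, evenly spaced.
#' @param bout_frames Bout duration, frames.
#' @param amp_range Bout amplitude range, degrees (Uniform draw).
#' @param j_turn_directions Character vector (`"right"`/`"left"`), one per
#'   initial J-turn; remaining bouts get random directions.
#' @param hunt_duration_s Hunting-episode length after each J-turn,
#'   seconds.
#' @param conv_modes Unconverged / converged eye-convergence mode angles,
#'   degrees (must be separated by more than 4 x `conv_sd`).
#' @param conv_sd Within-mode convergence noise SD, degrees.
#' @param tail_noise_sd Tail-angle tracking-noise SD, degrees. The noise is
#'   temporally smoothed (band-limited), as tracker output jitter is, so
#'   its frame-to-frame derivative stays far below bout velocities.
#' @param seed RNG seed.
#' @return List with `track` (`frame`, `tail_angle_deg`, `left_eye_deg`,
#'   `right_eye_deg`), `bouts` (ground truth: frames, amplitude, integral,
#'   direction, `is_j_turn`), `hunt_episodes` (start/end frames),
#'   `threshold_truth` (mode midpoint), `hunting_fraction_truth`,
#'   `frame_rate`.
#' @export
simulate_behavior <- function(frame_rate = 500, duration_s = 60,
                              n_bouts = 10, bout_frames = 50,
                              amp_range = c(20, 60),
                              j_turn_directions = character(0),
                              hunt_duration_s = 2, conv_modes = c(10, 50),
                              conv_sd = 5, tail_noise_sd = 0.2, seed = 1) {
  stopifnot(frame_rate > 0, diff(conv_modes) > 4 * conv_sd,
            length(j_turn_directions) <= n_bouts)
  set.seed(seed)
  n <- round(duration_s * frame_rate)
  tail <- gaussian_smooth(stats::rnorm(n, 0, tail_noise_sd), 2)
  conv_state <- logical(n)
  m <- length(j_turn_directions)
  bouts <- NULL
  episodes <- NULL
  if (n_bouts > 0) {
    spacing <- n / n_bouts
    if (spacing < bout_frames + 100)
      stop("bouts overlap: session too short for requested bout count")
    starts <- round((seq_len(n_bouts) - 0.5) * spacing - bout_frames / 2)
    amps <- stats::runif(n_bouts, amp_range[1], amp_range[2])
    dirs <- c(j_turn_directions,
              sample(c("right", "left"), n_bouts - m, replace = TRUE))
    sgn <- ifelse(dirs == "right", 1, -1)
    wave <- sin(pi * (seq_len(bout_frames) - 1) / (bout_frames - 1))
    rows <- vector("list", n_bouts)
    eps <- list()
    hunt_frames <- round(hunt_duration_s * frame_rate)
    for (k in seq_len(n_bouts)) {
      s <- starts[k]; e <- s + bout_frames - 1L
      tail[s:e] <- tail[s:e] + sgn[k] * amps[k] * wave
      is_j <- k <= m
      if (is_j) {
        ep_s <- s + bout_frames %/% 2
        next_guard <- if (k < n_bouts) starts[k + 1] - 50L else n
        ep_e <- min(ep_s + hunt_frames - 1L, next_guard)
        conv_state[ep_s:ep_e] <- TRUE
        eps[[length(eps) + 1L]] <- data.frame(start_frame = ep_s,
                                              end_frame = ep_e)
      }
      rows[[k]] <- data.frame(
        start_frame = s, end_frame = e, amplitude = amps[k],
        integral = sgn[k] * amps[k] * sum(wave), direction = dirs[k],
        is_j_turn = is_j)
    }
    bouts <- do.call(rbind, rows)
    episodes <- if (length(eps)) do.call(rbind, eps)
                else data.frame(start_frame = integer(0),
                                end_frame = integer(0))
  } else {
    bouts <- data.frame(start_frame = integer(0), end_frame = integer(0),
                        amplitude = numeric(0), integral = numeric(0),
                        direction = character(0), is_j_turn = logical(0))
    episodes <- data.frame(start_frame = integer(0), end_frame = integer(0))
  }
  conv <- ifelse(conv_state, conv_modes[2], conv_modes[1]) +
    stats::rnorm(n, 0, conv_sd)
  track <- data.frame(frame = seq_len(n), tail_angle_deg = tail,
                      left_eye_deg = conv / 2, right_eye_deg = conv / 2)
  list(track = track, bouts = bouts, hunt_episodes = episodes,
       threshold_truth = mean(conv_modes),
       hunting_fraction_truth = mean(conv_state), frame_rate = frame_rate)
}

#' Simulate an SWC tracing with a prescribed laminar profile
#'
#' Builds a tracing whose per-layer cable length matches `layer_profile`:
#' a vertical shaft connects the mid-depths of the shallowest and deepest
#' layers carrying mass, and horizontal neurite runs at each layer's
#' mid-depth supply the remaining cable, shrunk by exactly the shaft cable
#' already crossing that layer. Layers with zero target mass that the
#' shaft must pass through receive at most their thickness in cable, so
#' the round-trip error is bounded by (atlas depth span) / `total_length`.
#'
#' @param layer_profile Fractions per atlas layer (sums to 1).
#' @param atlas A `layer_atlas`.
#' @param total_length Target total cable length, micrometers (default
#'   4000; automatically increased if a layer's shaft share exceeds its
#'   target).
#' @param max_run Maximum horizontal node spacing, micrometers.
#' @return List with `tracing` (a `neuron_tracing`) and `total_length`.
#' @export
simulate_tracing <- function(layer_profile, atlas, total_length = 4000,
                             max_run = 20) {
  nl <- length(atlas$layers)
  stopifnot(length(layer_profile) == nl, all(layer_profile >= 0),
            abs(sum(layer_profile) - 1) < 1e-6)
  b <- atlas$boundaries
  mids <- (b[-1] + b[-length(b)]) / 2
  mass <- which(layer_profile > 0)
  stopifnot(length(mass) >= 1)
  lo <- min(mass); hi <- max(mass)
  # shaft cable per layer (vertical segment from mids[lo] to mids[hi])
  shaft <- numeric(nl)
  if (hi > lo) {
    for (i in seq_len(nl))
      shaft[i] <- max(0, min(mids[hi], b[i + 1]) - max(mids[lo], b[i]))
  }
  need <- shaft[mass] / layer_profile[mass]
  total_length <- max(total_length, max(need) * 1.01)
  horiz <- pmax(0, layer_profile * total_length - shaft)

  nodes <- list()
  nid <- 0L
  add_node <- function(x, y, z, parent, type = 3) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, type = type, x = x, y = y, z = z,
                                radius = 0.5, parent = parent)
    nid
  }
  shaft_node <- integer(nl)
  prev <- add_node(0, 0, mids[lo], -1L, type = 1)  # soma
  shaft_node[lo] <- prev
  if (hi > lo) {
    for (i in (lo + 1):hi) {
      prev <- add_node(0, 0, mids[i], prev)
      shaft_node[i] <- prev
    }
  }
  for (i in seq_len(nl)) {
    if (horiz[i] <= 0) next
    anchor <- shaft_node[i]
    if (anchor == 0L) next  # outside shaft span (cannot happen for mass layers)
    n_seg <- ceiling(horiz[i] / max_run)
    step <- horiz[i] / n_seg
    par <- anchor
    x <- 0
    for (s in seq_len(n_seg)) {
      x <- x + step
      par <- add_node(x, 0, mids[i], par)
    }
  }
  tracing <- as_neuron_tracing(do.call(rbind, nodes))
  list(tracing = tracing, total_length = total_length)
}
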