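test_that("bout segmentation recovers planted bouts and merges close ones", {
  # flat trace: nothing to segment
  expect_identical(nrow(segment_bouts(rep(0, 5000))), 0L)

  sim <- simulate_behavior(duration_s = 60, n_bouts = 10, conv_sd = 1,
                           seed = 28)
  seg <- segment_bouts(sim$track$tail_angle_deg)
  expect_identical(nrow(seg), 10L)
  expect_true(all(abs(seg$start_frame - sim$bouts$start_frame) <= 5))
  expect_true(all(abs(seg$end_frame - sim$bouts$end_frame) <= 5))

  # two waveforms closer than the minimum gap merge into one bout
  tail <- rep(0, 3000)
  wave <- 40 * sin(pi * (0:49) / 49)
  tail[1001:1050] <- wave
  tail[1056:1105] <- wave
  expect_identical(nrow(segment_bouts(tail)), 1L)
})

test_that("the convergence threshold sits at the bimodal density minimum", {
  set.seed(29)
  # equal mixture at 10 and 50 degrees, sd 5: minimum at the midpoint
  conv <- c(rnorm(15000, 10, 5), rnorm(15000, 50, 5))
  thr <- convergence_threshold(conv)
  mix <- function(x) 0.5 * dnorm(x, 10, 5) + 0.5 * dnorm(x, 50, 5)
  analytic <- optimize(mix, c(15, 45))$minimum
  expect_lt(abs(thr - analytic), 3)

  # unequal weights shift the minimum toward the lighter mode
  conv2 <- c(rnorm(24000, 10, 5), rnorm(6000, 50, 5))
  thr2 <- convergence_threshold(conv2)
  mix2 <- function(x) 0.8 * dnorm(x, 10, 5) + 0.2 * dnorm(x, 50, 5)
  analytic2 <- optimize(mix2, c(15, 45))$minimum
  expect_lt(abs(thr2 - analytic2), 3)
  expect_gt(thr2, analytic)

  expect_error(convergence_threshold(rnorm(5000, 20, 5)), "unimodal")
})

test_that("hunting fraction is the fraction of converged frames", {
  expect_identical(hunting_fraction(rep(10, 100), 30), 0)
  expect_identical(hunting_fraction(rep(50, 100), 30), 1)
  sim <- simulate_behavior(duration_s = 40, n_bouts = 8,
                           j_turn_directions = rep("right", 4),
                           hunt_duration_s = 3, conv_sd = 1, seed = 30)
  conv <- sim$track$left_eye_deg + sim$track$right_eye_deg
  hf <- hunting_fraction(conv, convergence_threshold(conv))
  expect_lt(abs(hf - sim$hunting_fraction_truth), 0.02)
})

test_that("bout integrals sum signed tail angles over the bout", {
  expect_identical(bout_integral(rep(2, 100), 1, 50), 100)
  anti <- sin(2 * pi * (0:99) / 99)
  expect_equal(bout_integral(anti, 1, 100), 0, tolerance = 1e-9)
  set.seed(31)
  x <- rnorm(500)
  expect_identical(bout_integral(x, 101, 200), sum(x[101:200]))
  expect_error(bout_integral(x, 200, 100))
})

test_that("J-turn flags follow the converged-before/after definition", {
  sim <- simulate_behavior(duration_s = 60, n_bouts = 10,
                           j_turn_directions = c("right", "left"),
                           conv_sd = 1, seed = 32)
  conv <- sim$track$left_eye_deg + sim$track$right_eye_deg
  thr <- convergence_threshold(conv)
  seg <- segment_bouts(sim$track$tail_angle_deg)
  bt <- bout_table(sim$track$tail_angle_deg, seg, conv, thr)
  expect_identical(bt$is_j_turn, !bt$converged_before & bt$converged_after)
  expect_identical(sum(bt$is_j_turn), 2L)
  expect_identical(bt$direction, ifelse(bt$integral > 0, "right", "left"))
  expect_identical(bt$direction[bt$is_j_turn], c("right", "left"))
})

test_that("the direction selectivity index takes its printed worked values", {
  mk <- function(signs, j) data.frame(
    start_frame = seq_along(signs) * 100,
    end_frame = seq_along(signs) * 100 + 50,
    integral = signs * 80, direction = ifelse(signs > 0, "right", "left"),
    converged_before = FALSE, converged_after = j, is_j_turn = j)

  expect_identical(direction_selectivity_index(mk(rep(1, 6), TRUE)), 1)
  expect_identical(direction_selectivity_index(mk(rep(-1, 6), TRUE)), -1)
  expect_identical(direction_selectivity_index(mk(rep(c(1, -1), 4), TRUE)),
                   0)
  # non-J-turn bouts do not count
  mixed <- rbind(mk(rep(1, 3), TRUE), mk(rep(-1, 5), FALSE))
  expect_identical(direction_selectivity_index(mixed), 1)
  expect_warning(out <- direction_selectivity_index(mk(1, FALSE)),
                 "no J-turns")
  expect_true(is.na(out))
})

test_that("mirroring the tail trace flips the selectivity index", {
  sim <- simulate_behavior(duration_s = 60, n_bouts = 10,
                           j_turn_directions = c("right", "right", "left"),
                           conv_sd = 1, seed = 33)
  conv <- sim$track$left_eye_deg + sim$track$right_eye_deg
  thr <- convergence_threshold(conv)
  dsi_of <- function(tail) {
    seg <- segment_bouts(tail)
    direction_selectivity_index(bout_table(tail, seg, conv, thr))
  }
  d1 <- dsi_of(sim$track$tail_angle_deg)
  d2 <- dsi_of(-sim$track$tail_angle_deg)
  expect_equal(d2, -d1)
  expect_true(abs(d1) <= 1)
})

test_that("group comparison uses a two-sided rank test", {
  vals <- c(1, 2, 3, 4, 10, 11, 12, 13)
  # identical groups: no evidence of a difference
  same <- compare_groups(rep(c(0.2, 0.3, 0.4, 0.5), 2),
                         rep(c("a", "b"), each = 4))
  expect_gt(same$p_value, 0.9)
  # complete separation at n = 8 per group
  set.seed(34)
  sep <- compare_groups(c(runif(8, 0, 0.1), runif(8, 0.9, 1)),
                        rep(c("sham", "ablated"), each = 8))
  expect_lt(sep$p_value, 0.01)
  expect_error(compare_groups(vals[1:3], c("a", "a", "b")), ">= 2 fish")
  expect_error(compare_groups(vals, rep("a", 8)), "two groups")
})

test_that("trajectory analysis ties the pieces together per fish", {
  sim <- simulate_behavior(duration_s = 60, n_bouts = 10,
                           j_turn_directions = rep("right", 4),
                           conv_sd = 1, seed = 35)
  out <- analyze_trajectory(sim$track)
  expect_identical(out$n_j_turns, 4L)
  expect_identical(out$dsi, 1)
  expect_lt(abs(out$hunting_fraction - sim$hunting_fraction_truth), 0.02)
  # with narrow modes the threshold need only separate them cleanly
  expect_gt(out$threshold, 15)
  expect_lt(out$threshold, 45)
})
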