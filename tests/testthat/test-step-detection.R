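test_that("constant traces yield no steps from either method", {
  flat <- fret_trace(rep(0.6, 80))
  fc <- find_steps_chisq(flat)
  expect_length(fc$change_points, 0)
  expect_equal(fc$plateau_levels, 0.6)

  fh <- find_steps_hmm(flat, seed = 1)
  expect_length(fh$change_points, 0)
  expect_identical(fh$n_states, 1L)
})

test_that("an ideal single step is recovered exactly", {
  y <- fret_trace(c(rep(0.8, 99), rep(0.6, 101)))
  fc <- find_steps_chisq(y)
  expect_identical(fc$change_points, 100L)
  expect_equal(fc$plateau_levels, c(0.8, 0.6))
  expect_equal(fc$step_sizes, -0.2)

  fh <- find_steps_hmm(y, seed = 2)
  expect_identical(fh$change_points, 100L)
  expect_equal(sort(fh$plateau_levels), c(0.6, 0.8), tolerance = 1e-6)
})

test_that("greedy chi-square placement equals exhaustive enumeration", {
  set.seed(21)
  for (r in 1:15) {
    one <- study_staircase(1)
    g1 <- find_steps_chisq(one$fret, n_steps = 1)$change_points
    expect_identical(as.integer(g1), exhaustive_one_step(one$fret$fret))

    two <- study_staircase(2)
    g2 <- find_steps_chisq(two$fret, n_steps = 2)$change_points
    expect_identical(sort(as.integer(g2)), sort(exhaustive_two_step(two$fret$fret)))
  }
})

test_that("both methods recover seeded staircase change points", {
  set.seed(31)
  hitc <- hith <- n_true <- 0
  for (r in 1:60) {
    st <- study_staircase(5)
    fc <- find_steps_chisq(st$fret)
    fh <- find_steps_hmm(st$fret, seed = r)
    n_true <- n_true + length(st$change_points)
    for (cp in st$change_points) {
      if (any(abs(fc$change_points - cp) <= 2)) hitc <- hitc + 1
      if (any(abs(fh$change_points - cp) <= 2)) hith <- hith + 1
    }
  }
  expect_gte(hitc / n_true, 0.9)
  expect_gte(hith / n_true, 0.9)
})

test_that("vanishing noise converges to the noiseless idealization", {
  st0 <- simulate_fret_staircase(4, -0.1, 0.8, noise_sd = 0,
                                 pause_range = c(20, 40), seed = 55)
  fc <- find_steps_chisq(st0$fret)
  expect_identical(as.integer(fc$change_points), st0$change_points)
  expect_equal(fc$plateau_levels, st0$levels, tolerance = 1e-12)
})

test_that("time reversal flips step signs but keeps placements", {
  st <- study_staircase(3, seed = 77)
  y <- st$fret$fret
  n <- length(y)
  fwd <- find_steps_chisq(y, n_steps = 3)
  rev_fit <- find_steps_chisq(rev(y), n_steps = 3)
  # a change point at frame c maps to n - c + 2 under reversal
  expect_identical(sort(as.integer(n - rev_fit$change_points + 2L)),
                   sort(as.integer(fwd$change_points)))
  expect_equal(sort(rev_fit$step_sizes), sort(-fwd$step_sizes),
               tolerance = 1e-9)
})

test_that("step acceptance applies the pause, range, and direction rules", {
  fit <- structure(
    list(
      change_points = c(21L, 25L, 60L, 95L),
      plateau_levels = c(0.80, 0.70, 0.60, 0.95, 0.50),
      step_sizes = c(-0.10, -0.10, 0.35, -0.45),
      pause_durations = c(20L, 4L, 35L, 35L, 26L),
      method = "chisq", fit_quality = 0, frame_rate = 1
    ),
    class = "step_fit"
  )
  calib <- calibration_curve(-0.053, 0.9, fret_range = c(0.1, 0.9))
  acc <- filter_steps(fit, calib, min_pause = 5, direction = "down")
  # steps 1 and 2 flank the 4-frame pause; steps 3 and 4 touch the 0.95 level
  expect_identical(acc$n_rejected_short, 2L)
  expect_identical(acc$n_rejected_range, 2L)
  expect_length(acc$steps, 0)

  # backward tally: one +0.1 step among nine -0.1 steps, all pauses long
  fit2 <- structure(
    list(
      change_points = cumsum(rep(10L, 10)),
      plateau_levels = c(0.80, 0.75, 0.70, 0.65, 0.60, 0.65,
                         0.60, 0.55, 0.50, 0.45, 0.40),
      step_sizes = c(rep(-0.05, 4), 0.05, rep(-0.05, 5)),
      pause_durations = rep(10L, 11),
      method = "chisq", fit_quality = 0, frame_rate = 1
    ),
    class = "step_fit"
  )
  acc2 <- filter_steps(fit2, NULL, min_pause = 5, direction = "down")
  expect_identical(acc2$n_backward, 1L)
  expect_equal(acc2$backward_fraction, 0.1)
  expect_length(acc2$steps, 9)
})

test_that("entry-side direction flips at the turning point", {
  fit <- structure(
    list(
      change_points = c(30L, 60L, 90L),
      plateau_levels = c(0.45, 0.65, 0.85, 0.60),
      step_sizes = c(0.20, 0.20, -0.25),
      pause_durations = c(30L, 30L, 30L, 30L),
      method = "chisq", fit_quality = 0, frame_rate = 1
    ),
    class = "step_fit"
  )
  acc <- filter_steps(fit, NULL, min_pause = 5, direction = "up_then_down")
  expect_identical(acc$n_backward, 0L)
  expect_length(acc$steps, 3)
})

test_that("interior pauses exclude the censored first and last plateaus", {
  fit <- structure(
    list(change_points = c(11L, 31L, 61L),
         plateau_levels = c(0.8, 0.7, 0.6, 0.5),
         step_sizes = rep(-0.1, 3),
         pause_durations = c(10L, 20L, 30L, 40L),
         method = "chisq", fit_quality = 0, frame_rate = 1),
    class = "step_fit"
  )
  expect_identical(interior_pauses(fit), c(20L, 30L))
})
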