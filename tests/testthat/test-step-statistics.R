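test_that("step histograms bin magnitudes on a fixed grid", {
  h <- build_step_histogram(c(0.1, -0.1, 0.3), bin_width = 0.02)
  expect_identical(h$counts[h$x > 0.10 - 1e-9 & h$x < 0.12][1], 2L)
  expect_identical(h$counts[h$x > 0.30 - 1e-9 & h$x < 0.32][1], 1L)
  expect_identical(sum(h$counts), 3L) # conservation
  expect_error(build_step_histogram(numeric(0)), "no accepted steps")

  set.seed(9)
  x <- simulate_step_observations(0.1, 0.3, 0.015, 1000, seed = 9)
  hh <- build_step_histogram(x, 0.02)
  # modes near c and 2c
  expect_lte(abs(hh$x[which.max(hh$counts)] - 0.11), 0.021)
  second <- hh$counts
  second[hh$x < 0.15] <- 0L
  expect_lte(abs(hh$x[which.max(second)] - 0.21), 0.021)
})

test_that("one-component histograms fit with f near zero", {
  set.seed(2)
  x <- rnorm(2000, 0.10, 0.02)
  fit <- fit_eq1(build_step_histogram(x, 0.02))[[1]]
  expect_lte(abs(fit$c - 0.10), 0.005)
  expect_lt(fit$f, 0.05)
})

test_that("the joint fit shares one width across histograms", {
  a <- build_step_histogram(
    simulate_step_observations(0.10, 0.30, 0.02, 1500, seed = 3), 0.02,
    movement_type = "exit")
  b <- build_step_histogram(
    simulate_step_observations(0.12, 0.40, 0.02, 1500, seed = 4), 0.02,
    movement_type = "exit")
  fits <- fit_eq1(list(a, b))
  expect_length(fits, 2)
  expect_identical(fits[[1]]$s, fits[[2]]$s)
  expect_true(fits[[1]]$shared_s)
  expect_lte(abs(fits[[1]]$c - 0.10), 0.01)
  expect_lte(abs(fits[[2]]$c - 0.12), 0.01)

  # peak-amplitude ratio between consecutive peaks approximates f
  f1 <- fits[[1]]
  y1 <- eq1_model(f1$c, f1$A, f1$f, f1$c, f1$s, f1$n_max)
  y2 <- eq1_model(2 * f1$c, f1$A, f1$f, f1$c, f1$s, f1$n_max)
  expect_lte(abs(y2 / y1 - f1$f), 0.05)
})

test_that("Gaussian population fits recover the mean and flag bad shapes", {
  set.seed(10)
  g <- fit_gaussian_fret(rnorm(5000, 0.6, 0.05))
  expect_lte(abs(g$mean - 0.6), 0.002)
  expect_false(g$poor_fit)
  expect_error(fit_gaussian_fret(rep(0.5, 100)), "degenerate")
  set.seed(11)
  bim <- fit_gaussian_fret(c(rnorm(500, 0.3, 0.03), rnorm(500, 0.7, 0.03)))
  expect_true(bim$poor_fit)
})

test_that("calibration regression matches exact and noisy lines", {
  exact <- data.frame(linker_bp = c(0, 6, 12), mean_fret = c(0.3, 0.6, 0.9))
  cal <- suppressWarnings(fit_calibration(exact))
  expect_equal(cal$slope, 0.05, tolerance = 1e-12)
  expect_equal(cal$slope_se, 0, tolerance = 1e-9)
  expect_error(fit_calibration(exact[1:2, ]), "3 distinct")

  ds <- simulate_calibration_dataset(0.053, 0.25, c(0, 2, 4, 6, 8, 10),
                                     0.03, 200, seed = 12)
  fit <- stats::lm(fret ~ linker_bp, ds)
  co <- summary(fit)$coefficients
  expect_lte(abs(co[2, 1] - 0.053), 2 * co[2, 2])
})

test_that("bp conversion reproduces the printed step-size estimates", {
  cases <- list(
    list(c = 0.104, se = 0.002, slope = 0.053, sse = 0.004, bp = 2.0),
    list(c = 0.113, se = 0.003, slope = 0.059, sse = 0.005, bp = 1.9),
    list(c = 0.092, se = 0.004, slope = 0.057, sse = 0.002, bp = 1.6),
    list(c = 0.088, se = 0.002, slope = 0.055, sse = 0.002, bp = 1.6)
  )
  for (cs in cases) {
    out <- convert_step_to_bp(cs$c, cs$se,
                              calibration_curve(cs$slope, 0, slope_se = cs$sse))
    expect_equal(round(out$bp, 1), cs$bp)
  }
  first <- cases[[1]]
  out1 <- convert_step_to_bp(first$c, first$se,
                             calibration_curve(first$slope, 0, slope_se = first$sse))
  expect_equal(round(out1$bp_se, 1), 0.2)

  expect_equal(convert_step_to_bp(0, 0, calibration_curve(0.05, 0))$bp, 0)
  expect_error(convert_step_to_bp(0.1, 0, calibration_curve(0, 0)), "zero")
  # linearity: doubling the slope halves the estimate
  half <- convert_step_to_bp(0.1, 0, calibration_curve(0.05, 0))$bp
  expect_equal(convert_step_to_bp(0.1, 0, calibration_curve(0.10, 0))$bp,
               half / 2)
})

test_that("missed-fraction analytics follow the exponential CDF", {
  expect_equal(missed_fraction(20, 5), 1 - exp(-0.25), tolerance = 1e-12)
  expect_equal(missed_fraction(20, 0), 0)
  expect_equal(missed_fraction(5 / log(2), 5), 0.5, tolerance = 1e-12)
  taus <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(missed_fraction(taus, 5)) < 0))
})

test_that("truncated exponential lifetimes recover tau", {
  x <- 5 + simulate_pause_lifetimes(20, 10000, seed = 13)
  fit <- fit_pause_lifetimes(x, frame_rate = 1, threshold = 5)
  expect_lte(abs(fit$tau_frames - 20), 0.5)
  expect_equal(fit$missed_fraction, 1 - exp(-5 / fit$tau_frames))
  expect_error(fit_pause_lifetimes(c(2, x), threshold = 5), "below the detection")
})

test_that("Forster conversion matches the sixth-root law", {
  expect_equal(fret_to_distance(0.5, 6), 6)
  expect_lte(abs(distance_change(0.6, 0.5, 6) - 0.392), 1e-3)
  # 0.1 FRET drops anywhere in 0.35-0.65 give 0.3-0.6 nm motions
  starts <- seq(0.45, 0.65, by = 0.05)
  dr <- vapply(starts, function(s) distance_change(s, s - 0.1, 6), numeric(1))
  expect_true(all(dr >= 0.3 & dr <= 0.6))
  # monotone decreasing and invertible
  r <- fret_to_distance(c(0.2, 0.4, 0.6, 0.8), 6)
  expect_true(all(diff(r) < 0))
  back <- 1 / (1 + (r / 6)^6)
  expect_equal(fret_to_distance(back, 6), r, tolerance = 1e-10)
  expect_error(fret_to_distance(1), "strictly inside")
})
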