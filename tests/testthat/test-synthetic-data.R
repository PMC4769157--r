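test_that("noiseless exit-side trace is an exact FRET staircase", {
  cons <- construct_spec("test/[end,+6]", "H2A", "end", 6L,
                         initial_linker_bp = 6L, final_fret = 0.5)
  params <- simulation_params(
    noise_sd = 0, bleach_rate = 0, donor_enhancement = 1,
    steps_per_emission_dist = c("2" = 1), trace_length = 400L, seed = 101
  )
  calib <- calibration_curve(0.05, 0.5) # start = 0.5 + 0.05*6 = 0.8
  sim <- simulate_remodeling_trace(cons, params, calib,
                                   movement_class = "exit")
  expect_equal(sim$truth$plateau_fret, c(0.8, 0.7, 0.6, 0.5))
  expect_equal(sim$truth$true_step_sizes_fret, rep(-0.1, 3))
  expect_equal(sim$truth$true_step_sizes_bp, rep(2, 3))

  ft <- compute_fret(sim$trace)
  cps <- sim$truth$true_change_points
  bounds <- c(1L, cps, length(sim$trace$frame) + 1L)
  for (i in seq_along(sim$truth$plateau_fret)) {
    seg <- ft$fret[bounds[i]:(bounds[i + 1L] - 1L)]
    expect_equal(seg, rep(sim$truth$plateau_fret[i], length(seg)),
                 tolerance = 1e-12)
  }
})

test_that("donor enhancement raises donor emission 1.10-fold, acceptor unchanged", {
  cons <- construct_registry()[["H2A/[end,+6]"]]
  params <- simulation_params(noise_sd = 0, bleach_rate = 0,
                              donor_enhancement = 1.1,
                              pause_mean_tau = 1e6, # no steps inside window
                              trace_length = 200L, seed = 11)
  calib <- study_calibration()
  sim <- simulate_remodeling_trace(cons, params, calib,
                                   movement_class = "exit")
  bf <- sim$truth$binding_frame
  skip_if(bf < 11 || bf > 190) # need both windows at constant FRET
  r <- intensity_ratio(sim$trace, bf, window = 10L)
  expect_equal(unname(r["donor_ratio"]), 1.10, tolerance = 1e-9)
  expect_equal(unname(r["acceptor_ratio"]), 1.00, tolerance = 1e-9)
})

test_that("pause draws follow the exponential dwell law", {
  x <- simulate_pause_lifetimes(20, 200, seed = 7)
  expect_true(abs(mean(x) - 20) <= 2 * 20 / sqrt(200))
  # exponential CDF fraction below 5 frames
  y <- simulate_pause_lifetimes(20, 10000, seed = 8)
  p <- mean(y < 5)
  p0 <- 1 - exp(-5 / 20)
  expect_true(abs(p - p0) <= 3 * sqrt(p0 * (1 - p0) / 10000))
  expect_length(simulate_pause_lifetimes(20, 1, seed = 1), 1)
  expect_gt(simulate_pause_lifetimes(20, 1, seed = 1), 0)
  expect_error(simulate_pause_lifetimes(-1, 10), "tau")
})

test_that("step observation mixture has geometric component weights", {
  # f = 0 collapses to one Gaussian component
  x0 <- simulate_step_observations(0.1, 0, 0.02, 2000, seed = 3)
  expect_true(abs(mean(x0) - 0.1) < 0.002)
  expect_identical(simulate_step_observations(0.1, 0.3, 0.02, 0), numeric(0))
  expect_error(simulate_step_observations(0.1, 1, 0.02, 10), "f must")

  # multiplicities recoverable by rounding when s << c
  x <- simulate_step_observations(0.1, 0.5, 0.005, 10000, n_max = 6, seed = 4)
  mult <- pmin(pmax(round(x / 0.1), 1), 6)
  obs <- tabulate(mult, 6)
  w <- 0.5^(0:5)
  gof <- suppressWarnings(stats::chisq.test(obs, p = w / sum(w)))
  expect_gt(gof$p.value, 0.01)
  # weights monotone non-increasing for f < 1
  expect_true(all(diff(obs) <= 0))
})

test_that("calibration dataset generator samples the stated line", {
  ds0 <- simulate_calibration_dataset(0.05, 0.3, c(0, 6, 12), 0, 5, seed = 1)
  m <- as.vector(tapply(ds0$fret, ds0$linker_bp, mean))
  expect_equal(m, c(0.3, 0.6, 0.9), tolerance = 1e-12)
  expect_error(
    simulate_calibration_dataset(0.1, 0.5, c(0, 6), 0.02, 5),
    "must lie in"
  )
})

test_that("identical seeds give identical synthetic outputs", {
  cons <- construct_registry()[["H2A/[end,+6]"]]
  params <- simulation_params(seed = 99)
  calib <- study_calibration()
  a <- simulate_remodeling_trace(cons, params, calib)
  b <- simulate_remodeling_trace(cons, params, calib)
  expect_identical(a$trace$donor, b$trace$donor)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_step_observations(0.1, 0.3, 0.02, 50, seed = 5),
                   simulate_step_observations(0.1, 0.3, 0.02, 50, seed = 5))
})

test_that("gap constructs force the translocation direction", {
  reg <- construct_registry()
  params <- simulation_params(bleach_rate = 0, seed = NULL)
  calib <- study_calibration()
  set.seed(12)
  cls_m2 <- replicate(20, simulate_remodeling_trace(
    reg[["H2A/[end,+6]/gapSHL-2"]], params, calib)$truth$movement_class)
  cls_p2 <- replicate(20, simulate_remodeling_trace(
    reg[["H2A/[end,+6]/gapSHL+2"]], params, calib)$truth$movement_class)
  expect_true(all(cls_m2 == "exit"))
  expect_true(all(cls_p2 == "entry"))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(noise_sd = -1), "noise_sd")
  expect_error(simulation_params(pause_mean_tau = 0), "pause_mean_tau")
  expect_error(simulation_params(bleach_rate = 1.5), "bleach_rate")
  expect_error(simulation_params(steps_per_emission_dist = c(0.5, 0.4)),
               "probability")
})
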