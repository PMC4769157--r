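make_fret <- function(values) fret_trace(values, frame_rate = 1)

test_that("monotone decreases map to exit and rise-then-fall to entry", {
  reg <- construct_registry()
  cons <- reg[["H2A/[end,+6]"]]

  down <- make_fret(rep(seq(0.8, 0, by = -0.1), each = 15))
  expect_identical(classify_trace(down, cons)$label, "exit")

  up <- make_fret(c(rep(0.45, 20), rep(0.65, 10), rep(0.85, 15),
                    rep(0.5, 10), rep(0.17, 20)))
  res <- classify_trace(up, cons)
  expect_identical(res$label, "entry")
  expect_true(res$rise_detected)

  # sub-threshold rise (only +0.05 above initial) stays exit
  sub <- make_fret(c(rep(0.6, 20), rep(0.65, 10), rep(0.4, 10), rep(0.1, 20)))
  expect_identical(classify_trace(sub, cons)$label, "exit")
})

test_that("the rise mapping inverts for the backbone,-15 geometry", {
  cons <- construct_registry()[["H2A/[backbone,-15]"]]
  expect_identical(cons$classification_threshold, 0.07)
  up <- make_fret(c(rep(0.5, 20), rep(0.75, 15), rep(0.0, 20)))
  expect_identical(classify_trace(up, cons)$label, "exit")
  down <- make_fret(c(rep(0.5, 20), rep(0.35, 10), rep(0.23, 20)))
  expect_identical(classify_trace(down, cons)$label, "entry")
})

test_that("traces without a remodeling transition are unclassified", {
  cons <- construct_registry()[["H2A/[end,+6]"]]
  flat <- make_fret(rep(0.6, 60))
  expect_identical(classify_trace(flat, cons)$label, "unclassified")
  small <- make_fret(c(rep(0.6, 30), rep(0.55, 30))) # change < 0.15
  expect_identical(classify_trace(small, cons)$label, "unclassified")
})

test_that("classification is invariant to trailing plateau frames", {
  cons <- construct_registry()[["H2A/[end,+6]"]]
  base <- c(rep(0.45, 20), rep(0.85, 15), rep(0.17, 20))
  lab1 <- classify_trace(make_fret(base), cons)$label
  lab2 <- classify_trace(make_fret(c(base, rep(0.17, 200))), cons)$label
  expect_identical(lab1, lab2)
  expect_identical(lab1, "entry")
})

test_that("movement fractions carry binomial standard errors", {
  all_entry <- movement_fractions(rep("entry", 30))
  expect_equal(all_entry$entry_fraction, 1)
  expect_equal(all_entry$entry_se, 0)

  half <- movement_fractions(rep(c("entry", "exit"), each = 50))
  expect_equal(half$entry_fraction, 0.5)
  expect_equal(half$entry_se, 0.05)
  expect_equal(half$entry_fraction + half$exit_fraction, 1)
  expect_error(movement_fractions(character(0)), "no classified")
})

test_that("simulated SHL+2 gap datasets classify overwhelmingly entry-side", {
  reg <- construct_registry()
  params <- simulation_params(bleach_rate = 0)
  calib <- study_calibration()
  set.seed(44)
  labs <- vapply(1:60, function(i) {
    sim <- simulate_remodeling_trace(reg[["H2A/[end,+6]/gapSHL+2"]],
                                     params, calib)
    classify_trace(compute_fret(sim$trace),
                   reg[["H2A/[end,+6]/gapSHL+2"]])$label
  }, character(1))
  expect_gt(movement_fractions(labs)$entry_fraction, 0.95)
})
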