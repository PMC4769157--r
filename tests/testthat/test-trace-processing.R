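test_that("trace files round-trip losslessly through the manifest", {
  dir <- withr::local_tempdir()
  tr <- intensity_trace(c(10.5, 20.25, 30), c(1, 2, 3.5), frame_rate = 2,
                        construct = "H2A/[end,+6]")
  write_traces(list(tr), dir, construct = "H2A/[end,+6]", seed = 1)
  back <- read_traces(dir)
  expect_equal(back$traces[[1]]$donor, tr$donor)
  expect_equal(back$traces[[1]]$acceptor, tr$acceptor)
  expect_equal(back$traces[[1]]$time_s, tr$time_s)
  expect_equal(back$construct$name, "H2A/[end,+6]")
})

test_that("missing and malformed trace files are reported by path", {
  dir <- withr::local_tempdir()
  tr <- intensity_trace(1:5, 1:5)
  write_traces(list(tr), dir)
  file.remove(file.path(dir, "trace_0001.tsv"))
  expect_error(read_traces(dir), "trace_0001.tsv")

  writeLines(c("frame\ttime_s\tdonor\tacceptor", "1\t0\t10"),
             file.path(dir, "trace_0001.tsv"))
  expect_error(read_traces(dir), "trace_0001.tsv")
})

test_that("one-step photobleach is detected and multi-step drops rejected", {
  clean <- intensity_trace(c(rep(70, 49), rep(5, 51)),
                           c(rep(30, 49), rep(5, 51)))
  call <- detect_photobleach(clean)
  expect_true(call$accepted)
  expect_identical(call$n_drops, 1L)
  expect_identical(call$bleach_frame, 50L)

  two <- intensity_trace(c(rep(70, 30), rep(40, 30), rep(5, 40)),
                         rep(5, 100))
  call2 <- detect_photobleach(two)
  expect_false(call2$accepted)
  expect_identical(call2$n_drops, 2L)

  set.seed(14)
  noisy <- intensity_trace(c(rep(100, 60), rep(10, 40)) + rnorm(100, 0, 5),
                           rep(0, 100))
  call3 <- detect_photobleach(noisy)
  expect_true(call3$accepted)
  expect_true(abs(call3$bleach_frame - 61L) <= 1L)

  expect_error(detect_photobleach(intensity_trace(1:5, 1:5)), "too short")
})

test_that("background subtraction removes the post-bleach level", {
  tr <- intensity_trace(c(rep(120, 50), rep(20, 50)),
                        c(rep(80, 50), rep(30, 50)))
  bl <- detect_photobleach(tr)
  corr <- subtract_background(tr, bl)
  expect_equal(corr$donor[1], 100)
  expect_equal(corr$acceptor[1], 50)
  expect_equal(mean(corr$donor[51:100]), 0, tolerance = 1e-12)

  # idempotence: a second pass subtracts ~0
  bl2 <- detect_photobleach(corr)
  corr2 <- subtract_background(corr, bl2)
  expect_equal(corr2$donor, corr$donor, tolerance = 1e-9)

  set.seed(5)
  noisy <- intensity_trace(c(rep(120, 60), rep(20, 60)) + rnorm(120, 0, 4),
                           c(rep(80, 60), rep(30, 60)) + rnorm(120, 0, 4))
  bln <- detect_photobleach(noisy)
  corrn <- subtract_background(noisy, bln)
  post <- corrn$donor[bln$bleach_frame:120]
  expect_true(abs(mean(post)) <= 2 * sd(post) / sqrt(length(post)))
})

test_that("proximity-ratio FRET follows the corrected channels", {
  expect_equal(compute_fret(intensity_trace(rep(100, 20), rep(0, 20)))$fret[1], 0)
  expect_equal(compute_fret(intensity_trace(rep(50, 20), rep(50, 20)))$fret[1], 0.5)

  # raw 120/80 with backgrounds 20/30 -> corrected 100/50 -> FRET 1/3
  tr <- intensity_trace(c(rep(120, 50), rep(20, 50)),
                        c(rep(80, 50), rep(30, 50)))
  ft <- compute_fret(subtract_background(tr, detect_photobleach(tr)),
                     detect_photobleach(tr))
  expect_equal(ft$fret[1], 1 / 3, tolerance = 1e-12)
  expect_false(any(ft$valid[51:100])) # masked from the bleach frame on
  expect_true(ft$valid[50])

  # scale invariance
  k <- 3.7
  scaled <- intensity_trace(k * c(rep(120, 50), rep(20, 50)) - k * 20,
                            k * c(rep(80, 50), rep(30, 50)) - k * 30)
  base <- intensity_trace(c(rep(120, 50), rep(20, 50)) - 20,
                          c(rep(80, 50), rep(30, 50)) - 30)
  expect_equal(compute_fret(scaled)$fret[1:49], compute_fret(base)$fret[1:49])
})

test_that("median filter matches the edge-shrinking contract", {
  expect_equal(median_filter(rep(2, 10), 3), rep(2, 10))
  expect_equal(median_filter(c(0, 0, 1, 0, 0), 3), rep(0, 5))
  expect_equal(median_filter(c(5, 1, 1, 1), 3)[1], 3) # median of {5, 1}
  expect_error(median_filter(1:5, 4), "odd")
  # monotone input stays monotone
  set.seed(3)
  mono <- sort(runif(50))
  expect_true(all(diff(median_filter(mono, 5)) >= 0))
})

test_that("population gates follow the construct rules", {
  reg <- construct_registry()
  expect_true(select_population(0.6, reg[["H2A/H2A"]]))
  expect_false(select_population(0.15, reg[["H2A/H2A"]]))
  expect_true(select_population(0.12, reg[["H2B/H2B"]]))
  expect_true(select_population(0.45, reg[["H2A/[end,+6]"]]))
})

test_that("intensity ratios isolate per-channel changes", {
  tr <- intensity_trace(rep(100, 40), rep(60, 40))
  r <- intensity_ratio(tr, 20, window = 10)
  expect_equal(unname(r), c(1, 1))
  expect_error(intensity_ratio(tr, 1, window = 10), "each side")
})

test_that("ensemble normalization is affine and rejects flat curves", {
  curve <- seq(100, 40, length.out = 50)
  norm <- normalize_ensemble(curve, window = 1)
  expect_equal(norm[1], 1)
  expect_equal(norm[50], 0)
  expect_equal(norm, seq(1, 0, length.out = 50), tolerance = 1e-12)
  expect_error(normalize_ensemble(rep(5, 50), window = 1), "degenerate")
})

test_that("summed single-molecule decays match the analytic ensemble", {
  set.seed(6)
  n_frames <- 120
  rate <- 1 / 30
  traces <- lapply(1:400, function(i) {
    off <- 1 + rgeom(1, rate) # single-molecule acceptor loss
    acc <- ifelse(seq_len(n_frames) < off, 100, 0) + rnorm(n_frames, 0, 5)
    intensity_trace(rep(0, n_frames), acc)
  })
  ens <- normalize_ensemble(sum_singles(traces), window = 1)
  expected <- (1 - rate)^(seq_len(n_frames) - 1)
  expected <- (expected - expected[n_frames]) / (1 - expected[n_frames])
  expect_lt(max(abs(ens - expected)), 0.08) # Monte-Carlo error bound
})
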