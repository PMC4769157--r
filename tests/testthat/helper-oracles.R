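# Brute-force change-point oracles, independent of the package's greedy
# fitter: enumerate every placement and minimize the residual sum of
# squares directly.

segment_rss <- function(y, a, b) {
  s <- y[a:b]
  sum((s - mean(s))^2)
}

exhaustive_one_step <- function(y) {
  n <- length(y)
  rss <- vapply(1:(n - 1), function(i) {
    segment_rss(y, 1, i) + segment_rss(y, i + 1, n)
  }, numeric(1))
  which.min(rss) + 1L # first frame of the new plateau
}

exhaustive_two_step <- function(y) {
  n <- length(y)
  best <- Inf
  bi <- c(NA_integer_, NA_integer_)
  for (i in 1:(n - 2)) {
    left <- segment_rss(y, 1, i)
    for (j in (i + 1):(n - 1)) {
      v <- left + segment_rss(y, i + 1, j) + segment_rss(y, j + 1, n)
      if (v < best) {
        best <- v
        bi <- c(i, j)
      }
    }
  }
  bi + 1L
}

# standard study conditions used across the step-detection tests
study_staircase <- function(n_steps = 5, seed = NULL) {
  simulate_fret_staircase(n_steps, step_fret = -0.1, start_fret = 0.8,
                          noise_sd = 0.03, pause_range = c(10L, 60L),
                          seed = seed)
}
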