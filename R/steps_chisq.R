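# Piecewise-constant (step) fitting by greedy chi-square minimization with
# counter-fit model selection, after the step-finder style used for
# molecular-motor staircase data.

# residual sum of squares of segment a..b around its mean, from cumsums
.seg_rss <- function(S1, S2, a, b) {
  n <- b - a + 1
  s1 <- S1[b + 1L] - S1[a]
  s2 <- S2[b + 1L] - S2[a]
  max(s2 - s1 * s1 / n, 0)
}

# best single split of segment a..b: returns split position j (left ends at
# j) and the RSS reduction; NULL if the segment cannot be split
.best_split <- function(S1, S2, a, b) {
  if (b <= a) return(NULL)
  j <- a:(b - 1L)
  nl <- j - a + 1L
  nr <- b - j
  sl <- S1[j + 1L] - S1[a]
  sr <- (S1[b + 1L] - S1[a]) - sl
  s2l <- S2[j + 1L] - S2[a]
  s2r <- (S2[b + 1L] - S2[a]) - s2l
  rss <- (s2l - sl^2 / nl) + (s2r - sr^2 / nr)
  i <- which.min(rss)
  list(j = j[i], reduction = .seg_rss(S1, S2, a, b) - rss[i])
}

.rss_for_cps <- function(S1, S2, n, cps) {
  bounds <- c(0L, sort(cps), n)
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    total <- total + .seg_rss(S1, S2, bounds[i] + 1L, bounds[i + 1L])
  }
  total
}

# coordinate-descent refinement: re-optimize each change point within the
# segment bounded by its neighbors until the set is stable
.refine_cps <- function(S1, S2, n, cps, max_sweeps = 10L) {
  cps <- sort(cps)
  if (!length(cps)) return(cps)
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_along(cps)) {
      a <- if (i == 1L) 1L else cps[i - 1L] + 1L
      b <- if (i == length(cps)) n else cps[i + 1L]
      bs <- .best_split(S1, S2, a, b)
      if (!is.null(bs) && bs$j != cps[i]) {
        cps[i] <- bs$j
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  sort(cps)
}

# counter-fit change points: midpoints of every plateau of the fit
.counter_cps <- function(cps, n) {
  bounds <- c(0L, sort(cps), n)
  mids <- integer(0)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i] + 1L
    b <- bounds[i + 1L]
    if (b - a >= 1L) mids <- c(mids, (a + b - 1L) %/% 2L)
  }
  mids
}

#' Piecewise-constant step fit of a numeric series
#'
#' Greedy chi-square minimization: at each round the single change point
#' that maximally reduces the residual chi-square (over all current
#' segments) is inserted, and the placed change points are then refined by
#' coordinate descent (each point re-optimized within the segment bounded
#' by its neighbors) so that the final placements are jointly, not just
#' sequentially, optimal. The number of steps is selected by the
#' counter-fit quality criterion: for each candidate step count `k`, a
#' counter fit places change points at the midpoints of the fitted plateaus,
#' and the quality ratio `S_k = RSS(counter) / RSS(fit)` peaks at the
#' best-supported step count. Fits with `max(S_k)` below `threshold` are
#' declared step-free.
#'
#' @param y Numeric vector (no NAs).
#' @param max_steps Cap on the number of change points considered.
#' @param threshold Minimum counter-fit quality ratio for accepting steps.
#' @param n_steps Optional fixed number of change points; skips model
#'   selection (used for oracle comparisons).
#' @return A list with `change_points` (first frame of each new plateau),
#'   `plateau_levels`, `step_sizes`, `pause_durations`, `fit_quality`
#'   (residual sum of squares), and `quality_ratio` (the selected `S_k`).
#' @export
pwc_fit <- function(y, max_steps = 30L, threshold = 1.3, n_steps = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must not contain NAs")
  if (n < 2L) stop("series too short to fit")
  S1 <- c(0, cumsum(y))
  S2 <- c(0, cumsum(y * y))
  eps <- 1e-10 * max(S2[n + 1L], n * 1e-20) # relative to the signal power
  # noise-level screen on greedy insertions: a split must reduce the
  # chi-square by more than a mean-shift significance penalty (robust noise
  # estimate from first differences, SIC-style 2 log n factor)
  sigma_hat <- stats::mad(diff(y)) / sqrt(2)
  penalty <- max(sigma_hat^2 * 2 * log(n), eps)

  # greedy split sequence
  segs <- list(list(a = 1L, b = n, split = .best_split(S1, S2, 1L, n)))
  splits <- integer(0)
  K <- if (is.null(n_steps)) max_steps else n_steps
  K <- min(K, n - 1L)
  while (length(splits) < K) {
    reds <- vapply(segs, function(s) {
      if (is.null(s$split)) -Inf else s$split$reduction
    }, numeric(1))
    i <- which.max(reds)
    if (!is.finite(reds[i]) ||
        (is.null(n_steps) && reds[i] <= penalty)) break
    s <- segs[[i]]
    j <- s$split$j
    splits <- c(splits, j)
    segs[[i]] <- list(a = s$a, b = j, split = .best_split(S1, S2, s$a, j))
    segs[[length(segs) + 1L]] <-
      list(a = j + 1L, b = s$b, split = .best_split(S1, S2, j + 1L, s$b))
  }

  if (is.null(n_steps)) {
    k_sel <- 0L
    q_sel <- NA_real_
    if (length(splits)) {
      S_k <- vapply(seq_along(splits), function(k) {
        cps <- splits[seq_len(k)]
        rf <- .rss_for_cps(S1, S2, n, cps)
        rc <- .rss_for_cps(S1, S2, n, .counter_cps(cps, n))
        if (rf <= eps && rc <= eps) return(1)
        if (rf <= eps) return(Inf)
        rc / rf
      }, numeric(1))
      k_best <- which.max(S_k)
      if (S_k[k_best] >= threshold) {
        k_sel <- k_best
        q_sel <- S_k[k_best]
      }
    }
    cps <- if (k_sel > 0L) sort(splits[seq_len(k_sel)]) else integer(0)
  } else {
    if (length(splits) < n_steps) {
      stop("series supports only ", length(splits), " change points")
    }
    cps <- sort(splits)
    q_sel <- NA_real_
  }
  cps <- .refine_cps(S1, S2, n, cps)

  bounds <- c(0L, cps, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(y[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  list(
    change_points = cps + 1L,
    plateau_levels = levels,
    step_sizes = diff(levels),
    pause_durations = diff(bounds),
    fit_quality = .rss_for_cps(S1, S2, n, cps),
    quality_ratio = q_sel
  )
}

# extract the contiguous valid span of a fret_trace (or accept a bare vector)
.fret_values <- function(fret) {
  if (inherits(fret, "fret_trace")) {
    vi <- which(fret$valid & !is.na(fret$fret))
    if (!length(vi)) stop("trace has no valid frames")
    a <- vi[1]
    b <- vi[length(vi)]
    y <- fret$fret[a:b]
    if (anyNA(y)) { # interior invalid frames: carry the last valid value
      y <- stats::approx(seq_along(y)[!is.na(y)], y[!is.na(y)],
                         xout = seq_along(y), method = "constant",
                         rule = 2)$y
    }
    list(y = y, offset = a - 1L, frame_rate = fret$frame_rate)
  } else {
    list(y = as.numeric(fret), offset = 0L, frame_rate = 1)
  }
}

.step_fit_result <- function(fit, offset, method, frame_rate,
                             extra = list()) {
  structure(
    c(list(
      change_points = fit$change_points + offset,
      plateau_levels = fit$plateau_levels,
      step_sizes = fit$step_sizes,
      pause_durations = fit$pause_durations,
      method = method,
      fit_quality = fit$fit_quality,
      frame_rate = frame_rate
    ), extra),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit:%s> %d change points, %d plateaus\n",
              x$method, length(x$change_points), length(x$plateau_levels)))
  invisible(x)
}

#' Chi-square-minimization step finder
#'
#' Idealizes a FRET trace into plateaus and steps by greedy chi-square
#' minimization with counter-fit model selection (see [pwc_fit()]). Plateau
#' levels are segment means. Runs on unfiltered FRET values.
#'
#' @param fret A [fret_trace()] or numeric vector (>= 10 valid frames).
#' @param max_steps Cap on the number of steps per trace.
#' @param threshold Counter-fit quality threshold for accepting steps.
#' @param n_steps Optional fixed number of steps (skips model selection).
#' @return A `step_fit` object (`method = "chisq"`): change points (first
#'   frame of each new plateau, in original frame indices), plateau levels,
#'   signed step sizes, pause durations in frames, and the fit's residual
#'   chi-square.
#' @export
find_steps_chisq <- function(fret, max_steps = 30L, threshold = 1.3,
                             n_steps = NULL) {
  v <- .fret_values(fret)
  if (length(v$y) < 10L) stop("need >= 10 valid frames for step fitting")
  fit <- pwc_fit(v$y, max_steps = max_steps, threshold = threshold,
                 n_steps = n_steps)
  .step_fit_result(fit, v$offset, "chisq", v$frame_rate,
                   extra = list(quality_ratio = fit$quality_ratio))
}
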