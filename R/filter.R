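#' Apply the step-acceptance criteria to an idealized trace
#'
#' Keeps only steps whose flanking pauses both last at least `min_pause`
#' frames and whose flanking plateau FRET levels lie inside the linear range
#' of the calibration curve. Backward steps (sign opposite to the
#' construct's expected translocation direction) are excluded from the
#' accepted set but tallied, since such events are rare and left out of the
#' step-size histograms.
#'
#' @param fit A `step_fit` from [find_steps_chisq()] or [find_steps_hmm()].
#' @param calibration A [calibration_curve()] whose `fret_range` defines the
#'   trusted FRET interval; `NULL` skips the range filter.
#' @param min_pause Minimum flanking pause duration, frames (default 5).
#' @param direction Expected translocation direction: `"down"` for
#'   exit-side traces (FRET monotonically decreasing), `"up_then_down"` for
#'   entry-side traces (FRET rising to the turning point, then falling), or
#'   `"both"` to disable the backward-step exclusion.
#' @return An object of class `accepted_steps`: `steps` (signed ΔFRET),
#'   `n_rejected_short`, `n_rejected_range`, `n_backward`, and
#'   `backward_fraction` (backward / steps surviving the pause and range
#'   filters).
#' @export
filter_steps <- function(fit, calibration = NULL, min_pause = 5L,
                         direction = c("down", "up_then_down", "both")) {
  stopifnot(inherits(fit, "step_fit"))
  direction <- match.arg(direction)
  steps <- fit$step_sizes
  n_steps <- length(steps)
  if (n_steps == 0L) {
    return(structure(
      list(steps = numeric(0), n_rejected_short = 0L, n_rejected_range = 0L,
           n_backward = 0L, backward_fraction = NA_real_),
      class = "accepted_steps"
    ))
  }
  pauses <- fit$pause_durations
  levels <- fit$plateau_levels
  pause_ok <- pauses[seq_len(n_steps)] >= min_pause &
    pauses[seq_len(n_steps) + 1L] >= min_pause
  if (!is.null(calibration)) {
    rng <- calibration$fret_range
    lev_ok <- levels >= rng[1] - 1e-9 & levels <= rng[2] + 1e-9
    range_ok <- lev_ok[seq_len(n_steps)] & lev_ok[seq_len(n_steps) + 1L]
  } else {
    range_ok <- rep(TRUE, n_steps)
  }
  n_rejected_short <- sum(!pause_ok)
  n_rejected_range <- sum(pause_ok & !range_ok)
  pass <- pause_ok & range_ok

  expected_sign <- switch(
    direction,
    down = rep(-1, n_steps),
    both = rep(0, n_steps),
    up_then_down = {
      turn <- which.max(levels) # plateau index of the turning point
      ifelse(seq_len(n_steps) < turn, +1, -1)
    }
  )
  backward <- pass & expected_sign != 0 & sign(steps) != expected_sign
  n_backward <- sum(backward)
  accepted <- steps[pass & !backward]
  structure(
    list(
      steps = accepted,
      n_rejected_short = as.integer(n_rejected_short),
      n_rejected_range = as.integer(n_rejected_range),
      n_backward = as.integer(n_backward),
      backward_fraction = if (sum(pass)) n_backward / sum(pass) else NA_real_
    ),
    class = "accepted_steps"
  )
}

#' @export
print.accepted_steps <- function(x, ...) {
  cat(sprintf(
    "<accepted_steps> %d accepted; rejected: %d short-pause, %d out-of-range; %d backward (fraction %.3f)\n",
    length(x$steps), x$n_rejected_short, x$n_rejected_range, x$n_backward,
    x$backward_fraction
  ))
  invisible(x)
}

#' Pause durations accepted for lifetime analysis
#'
#' Interior pauses (bounded by detected steps on both sides) at least
#' `min_pause` frames long; the leading and trailing plateaus are excluded
#' because their durations are censored by the observation window.
#'
#' @param fit A `step_fit`.
#' @param min_pause Detection threshold, frames.
#' @return Integer vector of pause durations in frames.
#' @export
interior_pauses <- function(fit, min_pause = 5L) {
  stopifnot(inherits(fit, "step_fit"))
  p <- fit$pause_durations
  if (length(p) <= 2L) return(integer(0))
  p <- p[-c(1L, length(p))]
  as.integer(p[p >= min_pause])
}
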