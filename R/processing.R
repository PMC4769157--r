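#' FRET efficiency trace
#'
#' Holds a per-frame FRET efficiency series with a validity mask (frames
#' after photobleaching, or with non-positive total intensity, are invalid)
#' and plateau summaries of the initial and final FRET levels.
#'
#' @param fret Numeric vector of FRET values (clipped to \[0, 1\]).
#' @param valid Logical mask, same length as `fret`.
#' @param frame_rate Frame rate, Hz.
#' @param construct Optional construct name.
#' @param window Number of valid frames averaged for the initial and final
#'   plateau summaries (default 10).
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(fret, valid = rep(TRUE, length(fret)), frame_rate = 1,
                       construct = NULL, window = 10L) {
  stopifnot(length(fret) == length(valid))
  fret <- pmin(pmax(as.numeric(fret), 0), 1)
  fret[!valid] <- NA_real_
  vi <- which(valid)
  initial_fret <- if (length(vi)) {
    mean(fret[utils::head(vi, window)])
  } else {
    NA_real_
  }
  final_fret <- if (length(vi)) mean(fret[utils::tail(vi, window)]) else NA_real_
  structure(
    list(fret = fret, valid = valid, frame_rate = frame_rate,
         construct = construct, initial_fret = initial_fret,
         final_fret = final_fret),
    class = "fret_trace"
  )
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf(
    "<fret_trace> %d frames (%d valid), initial FRET %.3f, final FRET %.3f\n",
    length(x$fret), sum(x$valid), x$initial_fret, x$final_fret
  ))
  invisible(x)
}

#' @export
length.fret_trace <- function(x) length(x$fret)

#' Detect single-step photobleaching
#'
#' Scans the total (donor + acceptor) intensity for discrete drops using a
#' piecewise-constant step fit. A trace is accepted as a single molecule
#' only when exactly one discrete drop to the post-drop baseline is present,
#' mirroring the one-step photobleaching selection rule. The drop threshold
#' is `min_drop_sd` times the noise SD estimated from the final segment.
#'
#' @param trace An [intensity_trace()] of at least 10 frames.
#' @param min_drop_sd Minimum drop size in units of post-drop noise SD.
#' @param max_steps Cap on fitted intensity levels.
#' @return An object of class `bleach_call` with `bleach_frame` (first
#'   post-drop frame, `NA` if none), `channel` (`"donor"` or `"acceptor"`,
#'   whichever lost more intensity), `n_drops`, and `accepted`.
#' @export
detect_photobleach <- function(trace, min_drop_sd = 3, max_steps = 10L) {
  stopifnot(inherits(trace, "intensity_trace"))
  total <- trace$donor + trace$acceptor
  n <- length(total)
  if (n < 10L) stop("trace too short for bleach detection (< 10 frames)")

  fit <- pwc_fit(total, max_steps = max_steps)
  levels <- fit$plateau_levels
  cps <- fit$change_points
  # noise level from residuals in the final fitted segment
  seg_start <- if (length(cps)) cps[length(cps)] else 1L
  post_sd <- stats::sd(total[seg_start:n])
  if (!is.finite(post_sd)) post_sd <- 0
  min_drop <- max(min_drop_sd * post_sd, 1e-9 * max(abs(total), 1))

  dlev <- diff(levels)
  is_drop <- dlev < -min_drop
  n_drops <- sum(is_drop)
  baseline <- levels[length(levels)]
  accepted <- FALSE
  bleach_frame <- NA_integer_
  channel <- NA_character_
  if (n_drops == 1L) {
    i <- which(is_drop)
    # the single drop must land at the final baseline level
    accepted <- abs(levels[i + 1L] - baseline) <= max(min_drop, 1e-9)
    if (accepted) {
      bleach_frame <- cps[i]
      pre <- max(1L, bleach_frame - 20L):(bleach_frame - 1L)
      post <- bleach_frame:min(n, bleach_frame + 19L)
      d_drop <- mean(trace$donor[pre]) - mean(trace$donor[post])
      a_drop <- mean(trace$acceptor[pre]) - mean(trace$acceptor[post])
      channel <- if (d_drop >= a_drop) "donor" else "acceptor"
    }
  }
  structure(
    list(bleach_frame = bleach_frame, channel = channel,
         n_drops = as.integer(n_drops), accepted = accepted),
    class = "bleach_call"
  )
}

#' @export
print.bleach_call <- function(x, ...) {
  cat(sprintf("<bleach_call> %s: %d drop(s)%s\n",
              if (x$accepted) "accepted" else "rejected", x$n_drops,
              if (is.na(x$bleach_frame)) "" else
                sprintf(", %s bleach at frame %d", x$channel, x$bleach_frame)))
  invisible(x)
}

#' Subtract post-bleach background from both channels
#'
#' The fluorescence intensity after photobleaching measures the background;
#' its per-channel mean is subtracted from the whole trace. Negative
#' corrected intensities are permitted (noise).
#'
#' @param trace An [intensity_trace()].
#' @param bleach An accepted [detect_photobleach()] call with at least
#'   `min_post` post-bleach frames.
#' @param min_post Minimum number of post-bleach frames required.
#' @return The background-corrected [intensity_trace()].
#' @export
subtract_background <- function(trace, bleach, min_post = 10L) {
  stopifnot(inherits(trace, "intensity_trace"), inherits(bleach, "bleach_call"))
  if (!bleach$accepted) stop("trace lacks an accepted one-step photobleach")
  n <- length(trace$frame)
  post <- bleach$bleach_frame:n
  if (length(post) < min_post) {
    stop("fewer than ", min_post, " post-bleach frames for background estimation")
  }
  out <- trace
  out$donor <- trace$donor - mean(trace$donor[post])
  out$acceptor <- trace$acceptor - mean(trace$acceptor[post])
  out
}

#' Compute the FRET trace from a background-corrected intensity trace
#'
#' FRET is the uncorrected proximity ratio `acceptor / (acceptor + donor)`,
#' clipped to \[0, 1\]. Frames at or after the photobleach, and frames with
#' non-positive total intensity, are masked invalid.
#'
#' @param trace A background-corrected [intensity_trace()].
#' @param bleach Optional [detect_photobleach()] call; frames from
#'   `bleach_frame` onward are masked.
#' @param window Valid frames averaged for the initial/final FRET summaries.
#' @return A [fret_trace()].
#' @export
compute_fret <- function(trace, bleach = NULL, window = 10L) {
  stopifnot(inherits(trace, "intensity_trace"))
  total <- trace$donor + trace$acceptor
  valid <- total > 0
  if (!is.null(bleach) && !is.na(bleach$bleach_frame)) {
    valid[trace$frame >= bleach$bleach_frame] <- FALSE
  }
  fret <- ifelse(valid, trace$acceptor / total, NA_real_)
  fret_trace(fret, valid, trace$frame_rate, trace$construct, window = window)
}

#' Running median filter with edge shrinking
#'
#' Applies a running median of odd window `window`; at the edges the window
#' is truncated to the available frames, and the median of an even-sized set
#' is the mean of its two central values (the behavior of [stats::median()]).
#'
#' @param x Numeric vector (NAs are passed through and ignored within
#'   windows).
#' @param window Odd positive integer window width.
#' @return Filtered vector, same length as `x`.
#' @export
median_filter <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd positive integer")
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else stats::median(w, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Population gate on the initial FRET value
#'
#' Applies the construct-specific selection used to pick analyzable
#' molecules: octamer-octamer constructs keep traces above a FRET bound
#' (H2A/H2A: > 0.2, H2B/H2B: > 0.1, so that molecules lacking an acceptor
#' are excluded), while octamer-DNA constructs keep traces inside a
#' configured proximal-population FRET window.
#'
#' @param initial_fret Initial FRET value of the trace.
#' @param construct A [construct_spec()]; its `fret_gate` is either a lower
#'   bound or a `c(lo, hi)` window. Octamer-DNA constructs without an
#'   explicit gate default to the window \[0.3, 0.95\] selecting the
#'   proximal-donor population.
#' @return Logical: keep the trace?
#' @export
select_population <- function(initial_fret, construct) {
  stopifnot(inherits(construct, "construct_spec"))
  if (is.na(initial_fret)) return(FALSE)
  gate <- construct$fret_gate
  if (is.null(gate)) {
    if (construct$donor_site %in% c("H2A", "H2B", "H3") &&
        construct$name %in% c("H2A/H2A", "H2B/H2B")) {
      stop("construct ", construct$name, " has no configured FRET gate")
    }
    gate <- c(0.3, 0.95) # proximal-donor population window
  }
  if (length(gate) == 1L) {
    initial_fret > gate
  } else {
    initial_fret >= gate[1] && initial_fret <= gate[2]
  }
}

#' Channel intensity ratios across a remodeling or binding event
#'
#' Mean after/before ratio of each channel around `event_frame`, used to
#' distinguish photophysical donor brightness changes (donor ratio != 1 with
#' acceptor ratio ~ 1) from genuine FRET changes.
#'
#' @param trace An [intensity_trace()].
#' @param event_frame Frame index of the event.
#' @param window Frames averaged on each side.
#' @return Named numeric vector `c(donor_ratio, acceptor_ratio)`.
#' @export
intensity_ratio <- function(trace, event_frame, window = 10L) {
  stopifnot(inherits(trace, "intensity_trace"))
  n <- length(trace$frame)
  if (event_frame - window < 1L || event_frame + window - 1L > n) {
    stop("need at least ", window, " frames on each side of the event")
  }
  before <- (event_frame - window):(event_frame - 1L)
  after <- event_frame:(event_frame + window - 1L)
  c(donor_ratio = mean(trace$donor[after]) / mean(trace$donor[before]),
    acceptor_ratio = mean(trace$acceptor[after]) / mean(trace$acceptor[before]))
}

#' Sum single-molecule acceptor signals into an ensemble curve
#'
#' @param traces List of [intensity_trace()] objects of equal length.
#' @return Numeric vector: per-frame sum of the acceptor channels.
#' @export
sum_singles <- function(traces) {
  lens <- vapply(traces, function(t) length(t$frame), integer(1))
  if (length(unique(lens)) != 1L) stop("traces must have equal length to be summed")
  Reduce(`+`, lapply(traces, `[[`, "acceptor"))
}

#' Normalize an ensemble acceptor curve
#'
#' Affine rescale so that the mean of the initial window is 1 and the mean
#' of the final window is 0, matching the normalization of ensemble
#' remodeling kinetics.
#'
#' @param curve Numeric time series.
#' @param window Frames averaged at each end.
#' @return Normalized curve.
#' @export
normalize_ensemble <- function(curve, window = 10L) {
  n <- length(curve)
  if (n < 2L * window) stop("curve too short for the normalization windows")
  i0 <- mean(curve[seq_len(window)])
  i1 <- mean(curve[(n - window + 1L):n])
  if (abs(i0 - i1) < 1e-12 * max(abs(i0), 1)) {
    stop("initial and final levels coincide; normalization is degenerate")
  }
  (curve - i1) / (i0 - i1)
}
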