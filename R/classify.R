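#' Classify a remodeling trace as entry- or exit-side movement
#'
#' Implements the threshold rule used to separate the two remodeling
#' outcomes: a trace showing 3 consecutive points greater than the initial
#' FRET by the construct's threshold (0.1 for end-labeled constructs, 0.07
#' for H2A/\[backbone,-15\]) before first reaching its final FRET plateau
#' has a FRET rise and maps to entry-side movement for end-labeled
#' constructs (the mapping inverts for H2A/\[backbone,-15\], whose geometry
#' puts the rise on the exit side). A trace reaching the final plateau
#' without such a rise is monotone and maps to the other class.
#'
#' "Reaching the final FRET value" is operationalized as the first frame at
#' which the median-filtered trace enters within `plateau_tol` of the final
#' plateau level and stays there. Traces whose total FRET change is below
#' `min_change` are flagged unclassified (no remodeling transition).
#'
#' @param fret A [fret_trace()] (3-pt median filtering is applied here
#'   unless `prefiltered = TRUE`).
#' @param construct A [construct_spec()] supplying the threshold and the
#'   rise-to-class mapping.
#' @param threshold FRET rise threshold; defaults to the construct's.
#' @param n_consecutive Number of consecutive qualifying points (default 3).
#' @param plateau_tol Half-width of the final-plateau band (default 0.05).
#' @param min_change Minimum |initial - final| FRET change for a trace to
#'   count as remodeled (default 0.15).
#' @param prefiltered Set `TRUE` if `fret` is already median filtered.
#' @return An object of class `classification_result` with `label`
#'   (`"entry"`, `"exit"`, or `"unclassified"`), `rise_detected`,
#'   `rise_frames` (the first qualifying run), `threshold_used`, and
#'   `final_fret`.
#' @export
classify_trace <- function(fret, construct, threshold = NULL,
                           n_consecutive = 3L, plateau_tol = 0.05,
                           min_change = 0.15, prefiltered = FALSE) {
  stopifnot(inherits(fret, "fret_trace"), inherits(construct, "construct_spec"))
  if (is.null(threshold)) threshold <- construct$classification_threshold

  y <- if (prefiltered) fret$fret else median_filter(fret$fret, 3L)
  vi <- which(fret$valid & !is.na(y))
  res <- function(label, rise, frames) {
    structure(
      list(label = label, rise_detected = rise, rise_frames = frames,
           threshold_used = threshold, final_fret = fret$final_fret),
      class = "classification_result"
    )
  }
  if (length(vi) < n_consecutive + 1L ||
      is.na(fret$initial_fret) || is.na(fret$final_fret)) {
    return(res("unclassified", FALSE, integer(0)))
  }
  if (abs(fret$initial_fret - fret$final_fret) < min_change) {
    return(res("unclassified", FALSE, integer(0)))
  }

  yv <- y[vi]
  # first frame after which the trace stays inside the final-plateau band
  inband <- abs(yv - fret$final_fret) <= plateau_tol
  out <- which(!inband)
  plateau_start <- if (length(out)) {
    if (out[length(out)] == length(yv)) length(yv) + 1L else out[length(out)] + 1L
  } else {
    1L
  }

  pre <- seq_len(min(plateau_start - 1L, length(yv)))
  above <- yv[pre] > fret$initial_fret + threshold
  rise_at <- NA_integer_
  if (length(above) >= n_consecutive) {
    run <- 0L
    for (i in seq_along(above)) {
      run <- if (isTRUE(above[i])) run + 1L else 0L
      if (run >= n_consecutive) {
        rise_at <- i - n_consecutive + 1L
        break
      }
    }
  }
  rise <- !is.na(rise_at)
  frames <- if (rise) vi[rise_at + seq_len(n_consecutive) - 1L] else integer(0)

  label <- if (construct$invert_classification) {
    if (rise) "exit" else "entry"
  } else {
    if (rise) "entry" else "exit"
  }
  res(label, rise, frames)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s (rise %s, threshold %.2f)\n",
              x$label, if (x$rise_detected) "detected" else "absent",
              x$threshold_used))
  invisible(x)
}

#' Entry/exit movement fractions with binomial standard errors
#'
#' @param labels Character vector of `"entry"`/`"exit"`/`"unclassified"`
#'   labels (unclassified traces are dropped before computing fractions).
#' @return A list with `entry_fraction`, `exit_fraction`, their standard
#'   errors (`sqrt(p(1-p)/n)`), and counts `n_entry`, `n_exit`, `n`.
#' @export
movement_fractions <- function(labels) {
  labels <- labels[labels %in% c("entry", "exit")]
  n <- length(labels)
  if (n == 0L) stop("no classified traces")
  p_entry <- mean(labels == "entry")
  se <- sqrt(p_entry * (1 - p_entry) / n)
  list(
    entry_fraction = p_entry, entry_se = se,
    exit_fraction = 1 - p_entry, exit_se = se,
    n_entry = sum(labels == "entry"), n_exit = sum(labels == "exit"), n = n
  )
}
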