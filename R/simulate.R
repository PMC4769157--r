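#' Simulation parameters for synthetic remodeling traces
#'
#' Bundles the kinetic and photophysical parameters of the synthetic smFRET
#' trace generator. Defaults emulate the study conditions: 1 Hz imaging,
#' exponentially distributed pauses, a 1-bp fundamental translocation unit
#' emitted as 1-2 bp observable steps, additive Gaussian camera noise giving
#' raw FRET noise of roughly 0.05, a 1.10-fold donor brightness enhancement
#' upon enzyme binding, and memoryless single-step photobleaching.
#'
#' @param frame_rate Camera frame rate, Hz.
#' @param trace_length Number of frames to simulate.
#' @param pause_mean_tau Mean pause duration between translocation steps,
#'   frames (exponential dwell parameter).
#' @param fundamental_step_bp Fundamental translocation unit, bp.
#' @param steps_per_emission_dist Named numeric vector of probabilities over
#'   the number of fundamental units per observable translocation event
#'   (names "1", "2", ...). Must sum to 1.
#' @param noise_sd Additive Gaussian noise SD per channel, intensity a.u.
#' @param donor_enhancement Multiplicative factor applied to donor emission
#'   from the enzyme binding frame onward (photophysical, not a distance
#'   change).
#' @param bleach_rate Per-frame photobleaching probability for each dye.
#' @param total_intensity Noiseless donor+acceptor sum before enhancement,
#'   a.u.
#' @param binding_delay_mean Mean number of frames before enzyme binding,
#'   frames (exponential).
#' @param start_fret Optional FRET level of the unremodeled nucleosome;
#'   `NULL` derives it from the calibration curve and the construct's
#'   initial linker length.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#'
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(frame_rate = 1,
                              trace_length = 600L,
                              pause_mean_tau = 20,
                              fundamental_step_bp = 1,
                              steps_per_emission_dist = c("1" = 0.3, "2" = 0.7),
                              noise_sd = 35,
                              donor_enhancement = 1.1,
                              bleach_rate = 0.0015,
                              total_intensity = 1000,
                              binding_delay_mean = 30,
                              start_fret = NULL,
                              seed = NULL) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (trace_length < 1) stop("trace_length must be >= 1")
  if (pause_mean_tau <= 0) stop("pause_mean_tau must be positive")
  if (fundamental_step_bp <= 0) stop("fundamental_step_bp must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (bleach_rate < 0 || bleach_rate >= 1) stop("bleach_rate must be in [0, 1)")
  if (donor_enhancement <= 0) stop("donor_enhancement must be positive")
  if (total_intensity <= 0) stop("total_intensity must be positive")
  p <- as.numeric(steps_per_emission_dist)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("steps_per_emission_dist must be a probability distribution")
  }
  if (is.null(names(steps_per_emission_dist))) {
    names(steps_per_emission_dist) <- seq_along(steps_per_emission_dist)
  }
  structure(
    list(
      frame_rate = frame_rate, trace_length = as.integer(trace_length),
      pause_mean_tau = pause_mean_tau,
      fundamental_step_bp = fundamental_step_bp,
      steps_per_emission_dist = steps_per_emission_dist,
      noise_sd = noise_sd, donor_enhancement = donor_enhancement,
      bleach_rate = bleach_rate, total_intensity = total_intensity,
      binding_delay_mean = binding_delay_mean, start_fret = start_fret,
      seed = seed
    ),
    class = "simulation_params"
  )
}

#' Two-channel intensity trace container
#'
#' @param donor,acceptor Numeric vectors of per-frame channel intensities
#'   (a.u.), equal length.
#' @param frame_rate Frame rate, Hz.
#' @param construct Construct name or [construct_spec()] (optional).
#' @return An object of class `intensity_trace` with elements `frame`,
#'   `time_s`, `donor`, `acceptor`, `frame_rate`, `construct`.
#' @export
intensity_trace <- function(donor, acceptor, frame_rate = 1, construct = NULL) {
  if (length(donor) != length(acceptor)) {
    stop("donor and acceptor channels must have equal length")
  }
  if (frame_rate <= 0) stop("frame_rate must be positive")
  frame <- seq_along(donor)
  structure(
    list(
      frame = frame, time_s = (frame - 1) / frame_rate,
      donor = as.numeric(donor), acceptor = as.numeric(acceptor),
      frame_rate = frame_rate,
      construct = if (inherits(construct, "construct_spec")) construct$name else construct
    ),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "<intensity_trace> %d frames at %g Hz%s\n", length(x$frame),
    x$frame_rate, if (is.null(x$construct)) "" else paste0(" [", x$construct, "]")
  ))
  invisible(x)
}

#' @export
length.intensity_trace <- function(x) length(x$frame)

# draw the piecewise-constant FRET staircase of one remodeling event;
# returns plateau levels, per-step bp, and signed per-step dFRET
.draw_staircase <- function(movement_class, start_fret, final_fret,
                            peak_fret, slope_mag, params) {
  n_units <- as.integer(names(params$steps_per_emission_dist))
  p_units <- as.numeric(params$steps_per_emission_dist)
  draw_bp <- function() {
    params$fundamental_step_bp *
      n_units[sample.int(length(n_units), 1L, prob = p_units)]
  }
  levels <- start_fret
  step_bp <- numeric(0)
  step_fret <- numeric(0)
  truncated <- FALSE
  phase_up <- movement_class == "entry" # entry rises first, then falls
  repeat {
    cur <- levels[length(levels)]
    bp <- draw_bp()
    dfret <- if (phase_up) bp * slope_mag else -bp * slope_mag
    nxt <- cur + dfret
    if (phase_up && nxt >= peak_fret - 1e-12) {
      nxt <- peak_fret
      dfret <- nxt - cur
      phase_up <- FALSE
    } else if (!phase_up && nxt <= final_fret + 1e-12) {
      nxt <- final_fret
      dfret <- nxt - cur
    }
    if (nxt < -1e-12 || nxt > 1 + 1e-12) {
      truncated <- TRUE
      break
    }
    if (abs(dfret) < 1e-12) break
    levels <- c(levels, nxt)
    step_bp <- c(step_bp, bp)
    step_fret <- c(step_fret, dfret)
    if (!phase_up && abs(nxt - final_fret) < 1e-12) break
    if (length(step_bp) > 500L) break # safety cap
  }
  list(levels = levels, step_bp = step_bp, step_fret = step_fret,
       truncated = truncated)
}

#' Simulate a single remodeling trace with ground truth
#'
#' Generates one two-channel intensity trace of a nucleosome being remodeled:
#' the enzyme binds after an exponential delay (switching on a donor
#' brightness enhancement), then translocates DNA in discrete 1-2 bp steps
#' separated by exponential pauses. Each step moves the FRET level along the
#' linear FRET-versus-linker-length calibration: exit-side trajectories fall
#' monotonically toward the final product level, entry-side trajectories
#' rise to the top of the calibration range and then fall. A single
#' photobleaching event per dye may truncate the usable signal.
#'
#' @param construct A [construct_spec()]. A gap at SHL-2 forces exit-side
#'   movement; a gap at SHL+2 forces entry-side movement.
#' @param params A [simulation_params()].
#' @param calibration A [calibration_curve()]; its slope magnitude sets the
#'   FRET change per bp and its prediction at the construct's initial linker
#'   length sets the starting FRET (unless `params$start_fret` overrides).
#' @param movement_class Optional `"entry"`/`"exit"` override of the
#'   stochastic engagement-side draw.
#'
#' @return A list with elements `trace` (an [intensity_trace()]) and `truth`
#'   (ground truth: `movement_class`, `true_change_points`,
#'   `true_step_sizes_bp`, `true_step_sizes_fret`, `plateau_fret`,
#'   `binding_frame`, `bleach_frame`, `bleach_channel`, `truncated`).
#' @export
simulate_remodeling_trace <- function(construct, params, calibration,
                                      movement_class = NULL) {
  stopifnot(inherits(construct, "construct_spec"),
            inherits(params, "simulation_params"),
            inherits(calibration, "calibration_curve"))
  if (!is.null(params$seed)) set.seed(params$seed)

  if (is.null(movement_class)) {
    movement_class <- if (construct$gap == "SHL-2") {
      "exit"
    } else if (construct$gap == "SHL+2") {
      "entry"
    } else if (stats::runif(1) < construct$movement_bias) "entry" else "exit"
  }
  movement_class <- match.arg(movement_class, c("entry", "exit"))

  slope_mag <- abs(calibration$slope)
  if (slope_mag == 0) stop("calibration slope must be nonzero")
  start_fret <- if (!is.null(params$start_fret)) {
    params$start_fret
  } else {
    calibration_predict(calibration, construct$initial_linker_bp)
  }
  if (start_fret < 0 || start_fret > 1) {
    stop("starting FRET outside [0, 1]; calibration does not cover this construct")
  }
  peak_fret <- max(calibration$fret_range)
  final_fret <- construct$final_fret
  if (movement_class == "exit") final_fret <- min(final_fret, start_fret)

  st <- .draw_staircase(movement_class, start_fret, final_fret, peak_fret,
                        slope_mag, params)

  n <- params$trace_length
  binding_frame <- min(n, 1L + stats::rgeom(1, 1 / max(params$binding_delay_mean, 1)))
  n_steps <- length(st$step_bp)
  pauses <- pmax(1L, as.integer(ceiling(stats::rexp(n_steps, 1 / params$pause_mean_tau))))
  change_points <- binding_frame + cumsum(pauses)
  keep <- change_points <= n
  change_points <- change_points[keep]
  step_bp <- st$step_bp[keep]
  step_fret <- st$step_fret[keep]

  fret <- rep(st$levels[1], n)
  for (i in seq_along(change_points)) {
    fret[change_points[i]:n] <- st$levels[i + 1L]
  }

  # one bleach event per trace: the earlier of two geometric draws
  bleach_frame <- NA_integer_
  bleach_channel <- NA_character_
  if (params$bleach_rate > 0) {
    bd <- 1L + stats::rgeom(1, params$bleach_rate)
    ba <- 1L + stats::rgeom(1, params$bleach_rate)
    first <- min(bd, ba)
    if (first <= n) {
      bleach_frame <- as.integer(first)
      bleach_channel <- if (bd <= ba) "donor" else "acceptor"
    }
  }

  enh <- ifelse(seq_len(n) >= binding_frame, params$donor_enhancement, 1)
  donor <- (1 - fret) * params$total_intensity * enh
  acceptor <- fret * params$total_intensity
  if (!is.na(bleach_frame)) {
    post <- seq_len(n) >= bleach_frame
    if (bleach_channel == "donor") {
      donor[post] <- 0
      acceptor[post] <- 0 # no excitation transfer once the donor is dark
    } else {
      acceptor[post] <- 0
      donor[post] <- params$total_intensity * enh[post] # quenching lost
    }
  }
  if (params$noise_sd > 0) {
    donor <- donor + stats::rnorm(n, 0, params$noise_sd)
    acceptor <- acceptor + stats::rnorm(n, 0, params$noise_sd)
  }

  truth <- list(
    movement_class = movement_class,
    true_change_points = as.integer(change_points),
    true_step_sizes_bp = step_bp,
    true_step_sizes_fret = step_fret,
    plateau_fret = st$levels[seq_len(length(change_points) + 1L)],
    binding_frame = as.integer(binding_frame),
    bleach_frame = bleach_frame,
    bleach_channel = bleach_channel,
    truncated = st$truncated
  )
  list(
    trace = intensity_trace(donor, acceptor, params$frame_rate, construct),
    truth = truth
  )
}

#' Simulate an idealized FRET staircase for step-finder validation
#'
#' Produces a piecewise-constant FRET series with known change points plus
#' i.i.d. Gaussian noise, bypassing the intensity-channel emission model.
#' Used to benchmark the step-detection algorithms against ground truth.
#'
#' @param n_steps Number of translocation steps.
#' @param step_fret Signed FRET change per step (scalar or length `n_steps`).
#' @param start_fret Initial FRET level.
#' @param noise_sd Gaussian noise SD on the FRET values.
#' @param pause_range Integer range (min, max) of uniform pause durations,
#'   frames; also sets the leading and trailing plateau lengths.
#' @param seed Optional integer seed.
#' @return List with `fret` (a [fret_trace()]), `change_points`, and
#'   `levels`.
#' @export
simulate_fret_staircase <- function(n_steps, step_fret = -0.1,
                                    start_fret = 0.8, noise_sd = 0.03,
                                    pause_range = c(20L, 60L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_steps < 0) stop("n_steps must be >= 0")
  step_fret <- rep_len(step_fret, n_steps)
  pauses <- sample(seq(pause_range[1], pause_range[2]), n_steps + 1L,
                   replace = TRUE)
  levels <- start_fret + c(0, cumsum(step_fret))
  fret <- rep(levels, times = pauses)
  change_points <- utils::head(cumsum(pauses), n_steps)
  if (noise_sd > 0) fret <- fret + stats::rnorm(length(fret), 0, noise_sd)
  list(
    fret = fret_trace(fret, frame_rate = 1),
    change_points = as.integer(change_points + 1L), # first frame of new plateau
    levels = levels
  )
}

#' Draw observed step sizes from the missed-step mixture
#'
#' Each observed step is the sum of `n` fundamental steps, where the
#' multiplicity `n` is drawn with probability proportional to `f^(n-1)`
#' (a pause between fundamental steps is missed with probability `f`), and
#' the observed size is Normal(n*c, s).
#'
#' @param c Fundamental step size (ΔFRET), > 0.
#' @param f Probability that a pause is missed, in \[0, 1).
#' @param s Standard deviation of the observed step size.
#' @param n_obs Number of observations to draw.
#' @param n_max Maximum multiplicity (mixture components), default 6.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_obs` observed step sizes.
#' @export
simulate_step_observations <- function(c, f, s, n_obs, n_max = 6L,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (f < 0 || f >= 1) stop("f must lie in [0, 1)")
  if (c <= 0) stop("c must be positive")
  if (s <= 0) stop("s must be positive")
  if (n_obs < 0) stop("n_obs must be >= 0")
  if (n_obs == 0) return(numeric(0))
  w <- f^(seq_len(n_max) - 1)
  mult <- sample.int(n_max, n_obs, replace = TRUE, prob = w / sum(w))
  stats::rnorm(n_obs, mean = mult * c, sd = s)
}

#' Draw exponential pause lifetimes
#'
#' @param tau Mean pause lifetime, frames (> 0).
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` i.i.d. Exponential(mean = tau) durations.
#' @export
simulate_pause_lifetimes <- function(tau, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (tau <= 0) stop("tau must be positive")
  if (n < 0) stop("n must be >= 0")
  stats::rexp(n, rate = 1 / tau)
}

#' Simulate a FRET-versus-linker-length calibration dataset
#'
#' Draws per-molecule FRET samples at each linker length from
#' Normal(intercept + slope * L, sd), emulating the population measurements
#' from which calibration curves are regressed.
#'
#' @param slope FRET change per bp.
#' @param intercept FRET at zero linker length.
#' @param linker_lengths Integer vector of linker lengths, bp.
#' @param sd Per-sample FRET standard deviation.
#' @param n_per_length Samples per linker length.
#' @param seed Optional integer seed.
#' @return Data frame with columns `linker_bp` and `fret`.
#' @export
simulate_calibration_dataset <- function(slope, intercept, linker_lengths,
                                         sd, n_per_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- intercept + slope * linker_lengths
  if (any(means < 0 | means > 1)) {
    stop("calibration means must lie in [0, 1]; got ",
         paste(signif(means, 3), collapse = ", "))
  }
  if (sd < 0) stop("sd must be >= 0")
  if (n_per_length < 1) stop("n_per_length must be >= 1")
  data.frame(
    linker_bp = rep(linker_lengths, each = n_per_length),
    fret = stats::rnorm(length(linker_lengths) * n_per_length,
                        mean = rep(means, each = n_per_length), sd = sd)
  )
}

#' Simulate a dataset of remodeling traces
#'
#' Convenience wrapper drawing `n_traces` independent remodeling traces for
#' one construct, optionally writing them to disk as tab-separated trace
#' files with a JSON manifest and per-trace ground-truth JSON.
#'
#' @param construct A [construct_spec()].
#' @param n_traces Number of traces.
#' @param params A [simulation_params()] (its `seed` element is ignored).
#' @param calibration A [calibration_curve()].
#' @param seed Integer seed for the whole dataset.
#' @param dir Optional output directory; created if missing.
#' @return A list with `traces` (list of [intensity_trace()]), `truths`
#'   (list of ground-truth lists), and, when written, `manifest_path`.
#' @export
simulate_dataset <- function(construct, n_traces, params, calibration,
                             seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$seed <- NULL
  sims <- lapply(seq_len(n_traces), function(i) {
    simulate_remodeling_trace(construct, params, calibration)
  })
  out <- list(
    traces = lapply(sims, `[[`, "trace"),
    truths = lapply(sims, `[[`, "truth")
  )
  if (!is.null(dir)) {
    out$manifest_path <- write_traces(
      out$traces, dir,
      construct = construct, frame_rate = params$frame_rate,
      seed = seed, truths = out$truths
    )
  }
  out
}
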