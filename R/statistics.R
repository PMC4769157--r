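#' Histogram of accepted step sizes
#'
#' Bins step-size magnitudes on a fixed grid starting at zero, the abscissa
#' on which the missed-step mixture model is fitted.
#'
#' @param steps An `accepted_steps` object from [filter_steps()] or a
#'   numeric vector of step sizes (signs are dropped).
#' @param bin_width Bin width in ΔFRET (default 0.02).
#' @param movement_type Optional `"entry"`/`"exit"` tag.
#' @param construct Optional construct name tag.
#' @return An object of class `step_histogram` with `bin_edges`, `counts`,
#'   `x` (bin centers), `movement_type`, `construct`, and `n_steps`.
#' @export
build_step_histogram <- function(steps, bin_width = 0.02,
                                 movement_type = NULL, construct = NULL) {
  if (inherits(steps, "accepted_steps")) steps <- steps$steps
  steps <- abs(as.numeric(steps))
  if (length(steps) == 0L) stop("no accepted steps to histogram")
  if (bin_width <= 0) stop("bin_width must be positive")
  upper <- bin_width * ceiling(max(steps) / bin_width + 1e-9)
  edges <- seq(0, max(upper, bin_width), by = bin_width)
  counts <- as.integer(table(cut(steps, edges, include.lowest = TRUE,
                                 right = FALSE)))
  structure(
    list(bin_edges = edges, counts = counts,
         x = edges[-length(edges)] + bin_width / 2,
         movement_type = movement_type, construct = construct,
         n_steps = length(steps)),
    class = "step_histogram"
  )
}

#' Missed-step mixture model curve
#'
#' Evaluates the step-size distribution model: a series of evenly spaced
#' Gaussian peaks at multiples of the fundamental step size `c`, each peak's
#' amplitude reduced by the missed-step probability `f` from the previous
#' one: `y(x) = sum_{n=1..n_max} A f^(n-1) exp(-(x - n c)^2 / (2 s^2))`.
#'
#' @param x Abscissa (ΔFRET).
#' @param A Amplitude of the first peak (counts).
#' @param f Probability that a pause is missed, in \[0, 1).
#' @param c Fundamental step size (ΔFRET).
#' @param s Standard deviation of the observed step size.
#' @param n_max Number of mixture components (default 6).
#' @return Model values at `x`.
#' @export
eq1_model <- function(x, A, f, c, s, n_max = 6L) {
  y <- 0
  for (n in seq_len(n_max)) {
    y <- y + A * f^(n - 1) * exp(-(x - n * c)^2 / (2 * s^2))
  }
  y
}

.eq1_residuals <- function(par, hists, n_max) {
  m <- length(hists)
  s <- par[3 * m + 1]
  unlist(lapply(seq_len(m), function(i) {
    A <- par[3 * i - 2]
    f <- par[3 * i - 1]
    cc <- par[3 * i]
    hists[[i]]$counts - eq1_model(hists[[i]]$x, A, f, cc, s, n_max)
  }))
}

#' Fit the missed-step mixture model to step-size histograms
#'
#' Nonlinear least squares of [eq1_model()] to histogram bin counts. When
#' several histograms of the same movement type are supplied, the peak
#' width `s` is shared globally across them while `A`, `f`, and `c` are
#' fitted per histogram; with a single histogram the joint fit degenerates
#' to an independent fit. Initialization is multi-start over a grid of `c`
#' values around each histogram's modal bin; the best-residual start wins.
#'
#' @param histograms A `step_histogram` or list of them (same movement
#'   type).
#' @param n_max Number of mixture components (default 6).
#' @param c_grid Multiplicative grid of starting `c` values relative to the
#'   modal bin center.
#' @param f_start Starting missed-step probability.
#' @return A list of class `eq1_fit_set`: one `eq1_fit` per histogram with
#'   elements `A`, `f`, `c`, their standard errors, the shared `s` and
#'   `s_se`, `n_max`, `shared_s`, `f_pinned`, and `ssr`.
#' @export
fit_eq1 <- function(histograms, n_max = 6L,
                    c_grid = c(0.5, 0.75, 1, 1.25, 1.5), f_start = 0.3) {
  if (inherits(histograms, "step_histogram")) histograms <- list(histograms)
  stopifnot(all(vapply(histograms, inherits, logical(1), "step_histogram")))
  m <- length(histograms)
  for (h in histograms) {
    if (sum(h$counts > 0) < 10L && h$n_steps < 100L) {
      stop("histogram too sparse for the mixture fit ",
           "(need >= 10 nonzero bins or >= 100 steps)")
    }
  }

  modal_c <- vapply(histograms, function(h) h$x[which.max(h$counts)], numeric(1))
  bw <- vapply(histograms, function(h) diff(h$bin_edges[1:2]), numeric(1))
  lower <- c(rep(c(0, 0, 1e-4), m), 1e-4)
  upper <- c(rep(c(Inf, 0.999, Inf), m), Inf)

  best <- NULL
  for (g in c_grid) {
    par0 <- numeric(3 * m + 1)
    for (i in seq_len(m)) {
      par0[3 * i - 2] <- max(histograms[[i]]$counts)
      par0[3 * i - 1] <- f_start
      par0[3 * i] <- max(modal_c[i] * g, bw[i] / 2)
    }
    par0[3 * m + 1] <- mean(bw)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper,
        fn = .eq1_residuals, hists = histograms, n_max = n_max,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15
        )
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best_ssr) {
      best <- fit
      best_ssr <- ssr
    }
  }
  if (is.null(best)) stop("missed-step mixture fit failed to converge from every start")

  par <- best$par
  # parameter covariance from the Jacobian at the optimum
  se <- rep(NA_real_, length(par))
  dof <- length(best$fvec) - length(par)
  if (dof > 0) {
    sigma2 <- best_ssr / dof
    cov <- tryCatch(sigma2 * solve(best$hessian), error = function(e) NULL)
    if (!is.null(cov)) {
      d <- diag(cov)
      se <- ifelse(d > 0, sqrt(d), 0)
    }
  }
  s <- par[3 * m + 1]
  out <- lapply(seq_len(m), function(i) {
    f_i <- par[3 * i - 1]
    structure(
      list(
        A = par[3 * i - 2], f = f_i, c = par[3 * i],
        A_se = se[3 * i - 2], f_se = se[3 * i - 1], c_se = se[3 * i],
        s = s, s_se = se[3 * m + 1], n_max = n_max, shared_s = m > 1,
        f_pinned = f_i <= 1e-6 || f_i >= 0.999 - 1e-6,
        movement_type = histograms[[i]]$movement_type,
        construct = histograms[[i]]$construct, ssr = best_ssr
      ),
      class = "eq1_fit"
    )
  })
  structure(out, class = "eq1_fit_set")
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat(sprintf(
    "<eq1_fit> c = %.4f +/- %.4f, f = %.3f, s = %.4f%s%s\n",
    x$c, x$c_se, x$f, x$s,
    if (x$shared_s) " (shared)" else "",
    if (x$f_pinned) " [f at bound]" else ""
  ))
  invisible(x)
}

#' @export
print.eq1_fit_set <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' Gaussian fit to a FRET population
#'
#' Fits a Gaussian curve to the histogram of per-molecule FRET values, as
#' used to summarize calibration populations.
#'
#' @param samples Numeric FRET values (>= 20).
#' @param bin_width Histogram bin width (default 0.02).
#' @param r2_threshold Minimum R-squared of the Gaussian fit before the
#'   `poor_fit` flag is raised (e.g. for bimodal populations).
#' @return A list with `mean`, `sd`, `mean_se`, `r_squared`, `poor_fit`.
#' @export
fit_gaussian_fret <- function(samples, bin_width = 0.02, r2_threshold = 0.8) {
  samples <- as.numeric(samples)
  if (length(samples) < 20L) stop("need >= 20 samples for a Gaussian fit")
  if (stats::sd(samples) < 1e-12) {
    stop("zero-variance sample; Gaussian fit is degenerate")
  }
  edges <- seq(floor(min(samples) / bin_width) * bin_width,
               ceiling(max(samples) / bin_width) * bin_width + bin_width / 2,
               by = bin_width)
  counts <- as.integer(table(cut(samples, edges, include.lowest = TRUE,
                                 right = FALSE)))
  x <- edges[-length(edges)] + bin_width / 2
  par0 <- c(A = max(counts), m = mean(samples), s = stats::sd(samples))
  fit <- minpack.lm::nls.lm(
    par = par0, lower = c(0, -Inf, 1e-6), upper = c(Inf, Inf, Inf),
    fn = function(p) counts - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  ssr <- sum(fit$fvec^2)
  r2 <- 1 - ssr / sum((counts - mean(counts))^2)
  dof <- length(counts) - 3L
  se <- rep(NA_real_, 3)
  if (dof > 0) {
    cov <- tryCatch((ssr / dof) * solve(fit$hessian), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  list(mean = unname(fit$par[2]), sd = unname(abs(fit$par[3])),
       mean_se = unname(se[2]), r_squared = r2, poor_fit = r2 < r2_threshold)
}

#' Fit a linear FRET-versus-linker-length calibration curve
#'
#' Ordinary least-squares regression of mean FRET on linker length. The
#' slope's standard error comes from the regression; the valid FRET range is
#' the span of the fitted means.
#'
#' @param points Data frame with columns `linker_bp` and `mean_fret`
#'   (optionally `sd_fret`), one row per linker length; at least 3 distinct
#'   lengths.
#' @param enzyme_bound Logical tag stored on the curve.
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(points, enzyme_bound = FALSE) {
  stopifnot(is.data.frame(points),
            all(c("linker_bp", "mean_fret") %in% names(points)))
  if (length(unique(points$linker_bp)) < 3L) {
    stop("need >= 3 distinct linker lengths for calibration")
  }
  fit <- stats::lm(mean_fret ~ linker_bp, data = points)
  co <- summary(fit)$coefficients
  fitted_range <- range(stats::fitted(fit))
  calibration_curve(
    slope = co["linker_bp", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    fret_range = pmin(pmax(fitted_range, 0), 1),
    slope_se = co["linker_bp", "Std. Error"],
    intercept_se = co["(Intercept)", "Std. Error"],
    points = points, enzyme_bound = enzyme_bound
  )
}

#' Convert a FRET step size to base pairs
#'
#' Divides the fitted fundamental FRET step size by the magnitude of the
#' calibration slope; standard errors combine in quadrature on the relative
#' scale.
#'
#' @param c Fundamental step size, ΔFRET.
#' @param c_se Its standard error.
#' @param calibration A [calibration_curve()] (or a numeric slope).
#' @param slope_se Slope standard error when `calibration` is numeric.
#' @return A list with `bp` and `bp_se`.
#' @export
convert_step_to_bp <- function(c, c_se = 0, calibration, slope_se = 0) {
  if (inherits(calibration, "calibration_curve")) {
    slope <- calibration$slope
    slope_se <- calibration$slope_se
  } else {
    slope <- calibration
  }
  if (slope == 0) stop("calibration slope is zero; conversion undefined")
  bp <- c / abs(slope)
  rel2 <- (slope_se / slope)^2 + if (c > 0) (c_se / c)^2 else 0
  list(bp = bp, bp_se = abs(bp) * sqrt(rel2))
}

#' Expected fraction of pauses missed below a detection threshold
#'
#' For exponentially distributed pause lifetimes with mean `tau`, the
#' fraction shorter than the detection threshold is
#' `1 - exp(-threshold / tau)`.
#'
#' @param tau Mean pause lifetime, frames.
#' @param threshold Detection threshold, frames (default 5).
#' @return The missed fraction.
#' @export
missed_fraction <- function(tau, threshold = 5) {
  if (any(tau <= 0)) stop("tau must be positive")
  1 - exp(-threshold / tau)
}

#' Exponential pause-lifetime fit with detection censoring
#'
#' Observed pauses are left-truncated at the detection threshold (pauses
#' shorter than `threshold` frames are never scored). By the memoryless
#' property the maximum-likelihood mean is `mean(durations) - threshold`;
#' the expected missed-event fraction follows from the exponential CDF.
#'
#' @param durations Pause durations, frames; all must be >= `threshold`.
#' @param frame_rate Frame rate, Hz, to report `tau_s` in seconds.
#' @param threshold Detection threshold, frames (default 5).
#' @return An object of class `pause_lifetime_fit` with `tau_frames`,
#'   `tau_se_frames`, `tau_s`, `detection_threshold`, `missed_fraction`,
#'   and `n`.
#' @export
fit_pause_lifetimes <- function(durations, frame_rate = 1, threshold = 5) {
  durations <- as.numeric(durations)
  n <- length(durations)
  if (n < 20L) stop("need >= 20 pause durations")
  if (any(durations < threshold)) {
    stop("durations below the detection threshold present; filter upstream")
  }
  tau <- mean(durations) - threshold
  if (tau <= 0) stop("degenerate lifetime estimate (tau <= 0)")
  structure(
    list(
      tau_frames = tau, tau_se_frames = tau / sqrt(n),
      tau_s = tau / frame_rate, detection_threshold = threshold,
      missed_fraction = missed_fraction(tau, threshold), n = n
    ),
    class = "pause_lifetime_fit"
  )
}

#' @export
print.pause_lifetime_fit <- function(x, ...) {
  cat(sprintf(
    "<pause_lifetime_fit> tau = %.2f +/- %.2f frames (%.2f s), missed fraction %.3f (n = %d)\n",
    x$tau_frames, x$tau_se_frames, x$tau_s, x$missed_fraction, x$n
  ))
  invisible(x)
}

#' Convert FRET efficiency to dye separation
#'
#' `r = R0 * (1/E - 1)^(1/6)` for a Förster radius `R0`.
#'
#' @param fret FRET efficiency, strictly inside (0, 1).
#' @param R0 Förster radius, nm (default 6 nm for the Cy3-Cy5 pair).
#' @return Distance in nm.
#' @export
fret_to_distance <- function(fret, R0 = 6) {
  if (any(fret <= 0 | fret >= 1)) {
    stop("FRET must lie strictly inside (0, 1) for distance conversion")
  }
  R0 * (1 / fret - 1)^(1 / 6)
}

#' Dye-separation change between two FRET values
#'
#' @param fret1,fret2 FRET efficiencies, strictly inside (0, 1).
#' @param R0 Förster radius, nm.
#' @return `fret_to_distance(fret2) - fret_to_distance(fret1)` in nm.
#' @export
distance_change <- function(fret1, fret2, R0 = 6) {
  fret_to_distance(fret2, R0) - fret_to_distance(fret1, R0)
}
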