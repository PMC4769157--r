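#' Hidden-Markov-model step finder
#'
#' Fits Gaussian-emission HMMs with 1 to `max_states` states (state-specific
#' means, shared emission SD, sticky transitions) by Baum-Welch EM with
#' several random restarts per state count, selects the state count by BIC,
#' decodes the most probable state path by Viterbi, and merges consecutive
#' identical states into plateaus. Plateau levels are the fitted state
#' means.
#'
#' State counts are scanned in increasing order and the scan stops early
#' once the BIC has worsened for two consecutive counts; the BIC counts one
#' mean per state, the shared emission SD, and one escape probability per
#' state (sticky transitions), the effective complexity of stepping data.
#'
#' @param fret A [fret_trace()] or numeric vector (>= 10 valid frames).
#' @param max_states Largest state count considered (default 10).
#' @param restarts Random restarts per state count (default 5).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param seed Optional seed for the restart initializations.
#' @return A `step_fit` object (`method = "hmm"`) with the same fields as
#'   [find_steps_chisq()]; `fit_quality` is the selected model's
#'   log-likelihood and `n_states` the selected state count.
#' @export
find_steps_hmm <- function(fret, max_states = 10L, restarts = 5L,
                           max_iter = 100L, tol = 1e-6, seed = NULL) {
  v <- .fret_values(fret)
  y <- v$y
  n <- length(y)
  if (n < 10L) stop("need >= 10 valid frames for step fitting")
  if (!is.null(seed)) set.seed(seed)

  sd0 <- max(stats::sd(y), 1e-4)
  best <- NULL
  best_bic <- Inf
  n_worse <- 0L
  failures <- character(0)
  for (K in seq_len(max_states)) {
    if (K == 1L) {
      mu <- mean(y)
      sig <- max(stats::sd(y), 1e-6)
      ll <- sum(stats::dnorm(y, mu, sig, log = TRUE))
      fitK <- list(loglik = ll, mu = mu, sigma = sig,
                   A = matrix(1, 1, 1), pi = 1)
    } else {
      fitK <- NULL
      for (r in seq_len(restarts)) {
        # spread initial means over the data range with jitter
        mu0 <- as.numeric(stats::quantile(y, probs = (seq_len(K) - 0.5) / K)) +
          stats::rnorm(K, 0, sd0 / 4)
        f <- tryCatch(
          .hmm_em_cpp(y, sort(mu0), sd0, 0.95, as.integer(max_iter), tol),
          error = function(e) NULL
        )
        if (is.null(f) || !is.finite(f$loglik)) next
        if (is.null(fitK) || f$loglik > fitK$loglik) fitK <- f
      }
      if (is.null(fitK)) {
        failures <- c(failures, sprintf("K=%d: all %d restarts failed", K, restarts))
        next
      }
    }
    # model complexity for stepping data: K state means, one shared sd,
    # and one escape probability per state (sticky transitions)
    p <- 2 * K + 1
    bic <- -2 * fitK$loglik + p * log(n)
    if (bic < best_bic) {
      best_bic <- bic
      best <- c(fitK, list(K = K))
      n_worse <- 0L
    } else {
      n_worse <- n_worse + 1L
      if (n_worse >= 2L) break
    }
  }
  if (is.null(best)) {
    stop("HMM fitting failed to converge for every state count: ",
         paste(failures, collapse = "; "))
  }

  if (best$K == 1L) {
    path <- rep(1L, n)
  } else {
    path <- .hmm_viterbi_cpp(y, best$mu, best$sigma,
                             best$A, best$pi)
  }
  change <- which(diff(path) != 0L) # last frame of old plateau
  bounds <- c(0L, change, n)
  levels <- best$mu[path[bounds[-1]]] # state mean of each plateau
  fit <- list(
    change_points = change + 1L,
    plateau_levels = as.numeric(levels),
    step_sizes = diff(as.numeric(levels)),
    pause_durations = diff(bounds),
    fit_quality = best$loglik
  )
  .step_fit_result(fit, v$offset, "hmm", v$frame_rate,
                   extra = list(n_states = best$K, sigma = best$sigma))
}
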