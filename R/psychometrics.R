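logistic2 <- function(snr, alpha, beta) 1 / (1 + exp(-(snr - alpha) / beta))

#' Fit a two-parameter logistic psychometric function
#'
#' Least-squares fit of `P(SNR) = 1 / (1 + exp(-(SNR - alpha)/beta))` to the
#' observed proportions correct, by Levenberg-Marquardt. `alpha` is the SNR
#' at 50% correct (the speech reception threshold) and `beta > 0` the slope
#' scale in dB. Guess and lapse rates are fixed at 0. Initialization uses
#' the SNR level whose proportion is nearest 0.5 and `beta0 = 1` dB.
#'
#' @param snr SNR levels in dB (>= 3 distinct values).
#' @param n_trials,n_correct Trial and correct counts per level.
#' @param init Optional `c(alpha, beta)` start values.
#' @param max_iter Maximum iterations (default 200).
#' @return A list of class `hemilat_psyfit`: `alpha`, `beta`, `rss`,
#'   `converged`, `n_iter`, `message`.
#' @export
fit_logistic <- function(snr, n_trials, n_correct, init = NULL, max_iter = 200L) {
  if (length(unique(snr)) < 3L) {
    hemi_stop("hemilat_value_error", "need at least 3 distinct SNR levels")
  }
  if (length(n_trials) != length(snr) || length(n_correct) != length(snr)) {
    hemi_stop("hemilat_shape_error", "snr, n_trials, n_correct lengths differ")
  }
  if (any(n_correct < 0) || any(n_correct > n_trials) || any(n_trials < 1)) {
    hemi_stop("hemilat_value_error", "need 0 <= n_correct <= n_trials")
  }
  p_obs <- n_correct / n_trials
  if (all(p_obs == p_obs[1L])) {
    hemi_stop("hemilat_degenerate_error",
              "constant proportions: psychometric slope unidentifiable")
  }
  if (is.null(init)) {
    init <- c(alpha = snr[which.min(abs(p_obs - 0.5))], beta = 1)
  }
  fit <- minpack.lm::nls.lm(
    par = init,
    fn = function(par) p_obs - logistic2(snr, par[1L], par[2L]),
    lower = c(-Inf, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                         ptol = 1e-10)
  )
  structure(list(alpha = unname(fit$par[1L]), beta = unname(fit$par[2L]),
                 rss = fit$deviance,
                 # info 5 = iteration limit, 0 = improper input; the gradient
                 # and machine-tolerance codes all indicate a stationary fit
                 converged = fit$info %in% c(1L, 2L, 3L, 4L, 6L, 7L, 8L),
                 n_iter = fit$niter, message = fit$message),
            class = "hemilat_psyfit")
}

#' Speech reception threshold across spatial conditions
#'
#' The threshold for a masker type is the arithmetic mean of the 50% points
#' fitted separately under the colocated and separated spatial conditions.
#'
#' @param ... Two or more `hemilat_psyfit` objects (or a single list of them).
#' @return Mean `alpha` in dB.
#' @export
threshold_across_conditions <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "hemilat_psyfit")) {
    fits <- fits[[1L]]
  }
  if (!length(fits)) hemi_stop("hemilat_value_error", "no fits supplied")
  for (f in fits) {
    if (!inherits(f, "hemilat_psyfit")) {
      hemi_stop("hemilat_value_error", "inputs must be hemilat_psyfit objects")
    }
    if (!isTRUE(f$converged)) {
      hemi_stop("hemilat_convergence_error",
                "cannot average thresholds: a psychometric fit did not converge")
    }
  }
  mean(vapply(fits, `[[`, numeric(1), "alpha"))
}

#' Score a digit span run
#'
#' Two trials per length, lengths consecutive from the starting length; the
#' run stops at the first length where both trials fail. The score is the
#' longest length with at least one correct trial before that stop (starting
#' length minus one if the very first length fails both trials). The total
#' auditory working-memory score is the sum of the forward and backward runs.
#'
#' @param trials data.frame with columns `length` and logical `correct`
#'   (two rows per length).
#' @param direction `"forward"` or `"backward"` (documentation only; scoring
#'   is identical).
#' @return Integer span score.
#' @export
score_digit_span <- function(trials, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (!all(c("length", "correct") %in% names(trials))) {
    hemi_stop("hemilat_format_error", "trials need columns 'length' and 'correct'")
  }
  lens <- sort(unique(trials$length))
  if (length(lens) > 1L && any(diff(lens) != 1L)) {
    hemi_stop("hemilat_value_error", "lengths must be consecutive")
  }
  n_correct <- vapply(lens, function(l) sum(trials$correct[trials$length == l]),
                      numeric(1))
  stop_at <- which(n_correct == 0)
  considered <- if (length(stop_at)) seq_len(stop_at[1L] - 1L) else seq_along(lens)
  passed <- lens[considered][n_correct[considered] >= 1]
  if (length(passed)) max(passed) else lens[1L] - 1L
}

#' Score the auditory Stroop task
#'
#' Interference cost: response time in the asynchronous (incongruent)
#' condition minus the synchronous (congruent) condition, in seconds. Larger
#' values indicate poorer inhibitory control.
#'
#' @param sync_time,async_time Positive response times in seconds.
#' @return `async_time - sync_time`.
#' @export
score_stroop <- function(sync_time, async_time) {
  if (any(c(sync_time, async_time) <= 0) || any(!is.finite(c(sync_time, async_time)))) {
    hemi_stop("hemilat_value_error", "Stroop times must be positive")
  }
  async_time - sync_time
}
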