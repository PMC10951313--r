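#' Classify trial outcomes from lick times
#'
#' Stimulus trials are hits when the first in-window lick falls strictly
#' after the early-lick cutoff (150 ms) and within the response window
#' (1.5 s); a first lick at or before the cutoff marks the trial excluded
#' (`early_lick`); no in-window lick is a miss. Catch trials are false alarms
#' or correct rejections by the same window.
#'
#' @param trials trial table with `lick_times_s` list column.
#' @param response_window_s,early_lick_s window parameters in seconds.
#' @return the trial table with `outcome` and `exclusion_reason` set.
#' @export
classify_outcomes <- function(trials, response_window_s = 1.5,
                              early_lick_s = 0.15) {
  n <- nrow(trials)
  outcome <- character(n)
  reason <- rep("none", n)
  for (i in seq_len(n)) {
    licks <- trials$lick_times_s[[i]]
    go <- trials$contrast[i] > 0
    early <- length(licks) > 0 && licks[1L] <= early_lick_s
    in_window <- any(licks > early_lick_s & licks <= response_window_s)
    if (early) {
      outcome[i] <- "excluded"
      reason[i] <- "early_lick"
    } else if (go) {
      outcome[i] <- if (in_window) "hit" else "miss"
    } else {
      outcome[i] <- if (in_window) "false_alarm" else "correct_rejection"
    }
  }
  trials$outcome <- outcome
  trials$exclusion_reason <- reason
  trials
}

#' Truncate a session when easy-trial performance collapses
#'
#' Computes the trailing rolling hit rate (default 20-trial window) over the
#' highest-contrast ("easy") trials; the starting performance is the first
#' full window's value. The session is truncated at the first easy trial
#' where the rolling value drops below `frac` of the starting performance;
#' every trial of any type after that point is marked `truncated`.
#'
#' @param trials trial table with outcomes.
#' @param window rolling window length in easy trials.
#' @param frac fraction of starting performance.
#' @return the trial table with truncated trials marked
#'   (`outcome = "excluded"`, `exclusion_reason = "truncated"`); attribute
#'   `truncated_at` gives the cut trial_id (or NA).
#' @export
truncate_session <- function(trials, window = 20L, frac = 0.8) {
  easy <- which(trials$contrast == max(trials$contrast) &
                  trials$outcome %in% c("hit", "miss"))
  attr(trials, "truncated_at") <- NA_integer_
  if (length(easy) < window) {
    warning("fewer easy trials than the rolling window; session not truncated")
    return(trials)
  }
  hits <- as.numeric(trials$outcome[easy] == "hit")
  roll <- stats::filter(hits, rep(1 / window, window), sides = 1)
  roll <- as.numeric(roll)
  start <- roll[window]
  bad <- which(!is.na(roll) & roll < frac * start)
  if (length(bad) == 0L) return(trials)
  cut_idx <- easy[bad[1L]]
  after <- trials$trial_id > trials$trial_id[cut_idx]
  trials$outcome[after] <- "excluded"
  trials$exclusion_reason[after] <- "truncated"
  attr(trials, "truncated_at") <- trials$trial_id[cut_idx]
  trials
}

#' Exclude photostimulation trials with failed targets
#'
#' A target "responds" on a trial when its windowed delta-F/F exceeds the
#' mapping responsivity criterion (default 0.3). Photostimulation trials on
#' which more than `fail_frac` of targets fail are excluded
#' (`target_failure`), and the session is flagged invalid when any of the 12
#' trial types retains fewer than 10 trials.
#'
#' @param trials trial table with outcomes.
#' @param target_responses trials x targets delta-F/F matrix.
#' @param thresh response criterion (delta-F/F).
#' @param fail_frac maximum tolerated failure fraction.
#' @return trial table with exclusions applied; attribute `session_valid`.
#' @export
apply_trial_exclusions <- function(trials, target_responses, thresh = 0.3,
                                   fail_frac = 0.5) {
  stim <- which(trials$photostim)
  if (length(stim) > 0L) {
    fail <- rowMeans(target_responses[stim, , drop = FALSE] <= thresh,
                     na.rm = TRUE)
    bad <- stim[fail > fail_frac]
    trials$outcome[bad] <- "excluded"
    trials$exclusion_reason[bad] <- "target_failure"
  }
  kept <- trials$outcome != "excluded"
  counts <- tapply(kept, paste(trials$contrast, trials$photostim), sum)
  attr(trials, "session_valid") <- all(counts >= 10L)
  trials
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(HR) - qnorm(FAR)` with rates clipped to
#' `[1/(2n), 1 - 1/(2n)]` for the respective trial counts, so the value is
#' always finite. Antisymmetric under swapping hits and false alarms.
#'
#' @param n_hit,n_go hits and go-trial count.
#' @param n_fa,n_catch false alarms and catch-trial count.
#' @return scalar d-prime.
#' @export
dprime <- function(n_hit, n_go, n_fa, n_catch) {
  stopifnot(n_go >= 1L, n_catch >= 1L)
  hr <- min(max(n_hit / n_go, 1 / (2 * n_go)), 1 - 1 / (2 * n_go))
  fa <- min(max(n_fa / n_catch, 1 / (2 * n_catch)), 1 - 1 / (2 * n_catch))
  stats::qnorm(hr) - stats::qnorm(fa)
}

#' Fixed-asymptote Weibull psychometric function
#'
#' `W(c) = gamma + (1 - gamma - lambda) * (1 - exp(-(c/alpha)^beta))`.
#'
#' @param contrast stimulus contrasts.
#' @param alpha scale (contrast units).
#' @param beta shape.
#' @param gamma guess rate.
#' @param lambda lapse rate.
#' @return performance probabilities.
#' @export
weibull_performance <- function(contrast, alpha, beta, gamma, lambda) {
  gamma + (1 - gamma - lambda) * (1 - exp(-(contrast / alpha)^beta))
}

#' Threshold and width of a fitted Weibull curve
#'
#' Threshold is the contrast at 50% normalized performance (between the fixed
#' asymptotes), `alpha * log(2)^(1/beta)`. Width is the contrast difference
#' between 95% and 5% normalized performance,
#' `alpha * ((-log(0.05))^(1/beta) - (-log(0.95))^(1/beta))`.
#'
#' @param alpha,beta Weibull parameters.
#' @return named vector `c(threshold, width)`.
#' @export
weibull_threshold_width <- function(alpha, beta) {
  c(threshold = alpha * log(2)^(1 / beta),
    width = alpha * ((-log(0.05))^(1 / beta) - (-log(0.95))^(1 / beta)))
}

#' Maximum-likelihood Weibull psychometric fit
#'
#' Fits `(alpha, beta)` by maximizing the binomial log-likelihood with the
#' guess and lapse rates held fixed, over `log(alpha)`, `log(beta)` from a
#' deterministic grid of starting values followed by BFGS polishing.
#'
#' @param contrast per-level contrasts (>= 3 levels with trials).
#' @param n_go,n_hit per-level go-trial and hit counts (fractional counts are
#'   allowed, e.g. for rate-based fits).
#' @param gamma fixed guess rate.
#' @param lambda fixed lapse rate.
#' @return an object of class `oc_weibull_fit`: list with `alpha`, `beta`,
#'   `gamma`, `lambda`, `threshold`, `width`, `converged`, `loglik`, and the
#'   per-level data.
#' @export
fit_weibull <- function(contrast, n_go, n_hit, gamma = 0, lambda = 0) {
  keep <- is.finite(contrast) & is.finite(n_go) & n_go > 0 & contrast > 0
  contrast <- contrast[keep]; n_go <- n_go[keep]; n_hit <- n_hit[keep]
  if (length(contrast) < 3L)
    stop("need at least 3 contrast levels with trials", call. = FALSE)
  if (gamma < 0 || lambda < 0 || gamma + lambda >= 1)
    stop("need 0 <= gamma + lambda < 1", call. = FALSE)
  negll <- function(par) {
    p <- weibull_performance(contrast, exp(par[1L]), exp(par[2L]), gamma, lambda)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(n_hit * log(p) + (n_go - n_hit) * log1p(-p))
  }
  starts <- expand.grid(a = log(stats::quantile(contrast, c(0.25, 0.5, 0.75))),
                        b = log(c(0.5, 1, 2, 4)))
  vals <- apply(starts, 1L, negll)
  best <- NULL
  for (k in order(vals)[1:3]) {
    fit <- try(stats::optim(as.numeric(starts[k, ]), negll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    fit <- stats::optim(fit$par, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  converged <- !is.null(best) && best$convergence == 0
  if (is.null(best))
    return(structure(list(alpha = NA_real_, beta = NA_real_, gamma = gamma,
                          lambda = lambda, threshold = NA_real_,
                          width = NA_real_, converged = FALSE,
                          loglik = NA_real_,
                          data = data.frame(contrast, n_go, n_hit)),
                     class = "oc_weibull_fit"))
  alpha <- exp(best$par[1L]); beta <- exp(best$par[2L])
  tw <- weibull_threshold_width(alpha, beta)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
                 threshold = unname(tw["threshold"]), width = unname(tw["width"]),
                 converged = converged, loglik = -best$value,
                 data = data.frame(contrast, n_go, n_hit)),
            class = "oc_weibull_fit")
}

#' @export
print.oc_weibull_fit <- function(x, ...) {
  cat(sprintf(
    "<Weibull fit> alpha = %.4g, beta = %.4g (gamma = %.3g, lambda = %.3g)\n  threshold = %.4g, width = %.4g, converged = %s\n",
    x$alpha, x$beta, x$gamma, x$lambda, x$threshold, x$width, x$converged))
  invisible(x)
}

#' Behavioral summary by state, photostimulation and contrast
#'
#' Hit rates, d-prime (false-alarm rate from the same state's catch trials
#' without photostimulation by default, with a config switch to use
#' photostimulation catch trials) and fixed-asymptote Weibull fits per
#' (state x photostimulation) condition. The guess rate is fixed to the
#' condition's catch false-alarm rate; the lapse rate to `acfg$lapse_rate`.
#' Conditions with no trials yield missing values, never zeros.
#'
#' @param trials trial table with outcomes and exclusions applied.
#' @param states per-trial state labels (from [state_index()]), or NULL to
#'   pool states.
#' @param acfg an [analysis_config()].
#' @param fa_from_stim_catch use photostimulation catch trials for the
#'   false-alarm rate.
#' @param fa_per_state estimate the false-alarm rate from each state's own
#'   catch trials instead of the whole session's (the default pools states:
#'   the false-alarm rate is a session-level quantity, and per-state catch
#'   subsets are small enough that their sampling noise would dominate
#'   between-state d-prime comparisons).
#' @return list with `table` (per state x photostim x contrast rows) and
#'   `fits` (named list of `oc_weibull_fit` per state x photostim).
#' @export
summarize_behavior <- function(trials, states = NULL,
                               acfg = analysis_config(),
                               fa_from_stim_catch = FALSE,
                               fa_per_state = FALSE) {
  keep <- trials$outcome != "excluded"
  tr <- trials[keep, , drop = FALSE]
  st <- if (is.null(states)) rep("pooled", nrow(tr)) else states[keep]
  state_levels <- unique(st[!is.na(st)])
  contrasts <- sort(unique(tr$contrast[tr$contrast > 0]))
  rows <- list()
  fits <- list()
  for (s in state_levels) {
    in_s <- !is.na(st) & st == s
    for (ps in c(FALSE, TRUE)) {
      catch <- tr$contrast == 0 & tr$photostim == fa_from_stim_catch
      if (fa_per_state) catch <- catch & in_s
      n_catch <- sum(catch)
      n_fa <- sum(tr$outcome[catch] == "false_alarm")
      fa_rate <- if (n_catch > 0) n_fa / n_catch else NA_real_
      cond_rows <- lapply(contrasts, function(cc) {
        sel <- in_s & tr$photostim == ps & tr$contrast == cc
        n_go <- sum(sel)
        n_hit <- sum(tr$outcome[sel] == "hit")
        data.frame(state = s, photostim = ps, contrast = cc,
                   n_go = n_go, n_hit = n_hit,
                   hit_rate = if (n_go > 0) n_hit / n_go else NA_real_,
                   dprime = if (n_go > 0 && n_catch > 0)
                     dprime(n_hit, n_go, n_fa, n_catch) else NA_real_,
                   stringsAsFactors = FALSE)
      })
      cond <- do.call(rbind, cond_rows)
      key <- paste0(s, if (ps) ".stim" else ".vis")
      gamma <- if (is.finite(fa_rate)) min(fa_rate, 0.95) else 0
      fit <- if (sum(cond$n_go > 0) >= 3L)
        try(fit_weibull(cond$contrast, cond$n_go, cond$n_hit,
                        gamma = gamma, lambda = acfg$lapse_rate), silent = TRUE)
      else NULL
      if (inherits(fit, "try-error")) fit <- NULL
      fits[[key]] <- fit
      cond$fa_rate <- fa_rate
      cond$alpha <- if (!is.null(fit)) fit$alpha else NA_real_
      cond$beta <- if (!is.null(fit)) fit$beta else NA_real_
      cond$threshold <- if (!is.null(fit)) fit$threshold else NA_real_
      cond$width <- if (!is.null(fit)) fit$width else NA_real_
      rows[[key]] <- cond
    }
  }
  list(table = do.call(rbind, rows), fits = fits)
}
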