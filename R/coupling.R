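#' Photostimulation-induced change in d-prime
#'
#' For each session, state, and intermediate contrast (default 2, 5, 10%),
#' the change in d-prime caused by photostimulation:
#' `dd' = d'(visual+stim) - d'(visual only)`. Only the intermediate contrasts
#' enter the coupling analysis (the lowest contrast is far below the
#' detection limit, the highest saturated).
#'
#' @param summary_tables list of per-session behavior tables (the `table`
#'   element of [summarize_behavior()]).
#' @param contrasts contrasts to report.
#' @return data.frame with `session`, `state`, `contrast`, `ddprime`.
#' @export
behavior_delta <- function(summary_tables, contrasts = c(2, 5, 10)) {
  rows <- lapply(seq_along(summary_tables), function(i) {
    tab <- summary_tables[[i]]
    tab <- tab[tab$contrast %in% contrasts, ]
    keys <- unique(tab[, c("state", "contrast")])
    keys$session <- i
    keys$ddprime <- mapply(function(s, cc) {
      d1 <- tab$dprime[tab$state == s & tab$contrast == cc & tab$photostim]
      d0 <- tab$dprime[tab$state == s & tab$contrast == cc & !tab$photostim]
      if (length(d1) == 1L && length(d0) == 1L) d1 - d0 else NA_real_
    }, keys$state, keys$contrast)
    keys
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("session", "state", "contrast", "ddprime")]
}

## Lean per-state ddprime at the given contrasts (used inside the shuffle
## loop; no psychometric fitting).
ddprime_lean <- function(contrast, photostim, outcome, states, contrasts) {
  out <- matrix(NA_real_, 2L, length(contrasts),
                dimnames = list(c("more_engaged", "less_engaged"), contrasts))
  kept <- outcome != "excluded"
  catch <- kept & contrast == 0 & !photostim
  n_catch <- sum(catch)
  if (n_catch < 1L) return(out)
  n_fa <- sum(outcome[catch] == "false_alarm")
  for (s in rownames(out)) {
    in_s <- kept & !is.na(states) & states == s
    for (k in seq_along(contrasts)) {
      d <- numeric(2L)
      okk <- TRUE
      for (p in 1:2) {
        sel <- in_s & contrast == contrasts[k] & photostim == (p == 2L)
        n_go <- sum(sel)
        if (n_go < 1L) { okk <- FALSE; break }
        d[p] <- dprime(sum(outcome[sel] == "hit"), n_go, n_fa, n_catch)
      }
      if (okk) out[s, k] <- d[2L] - d[1L]
    }
  }
  out
}

#' Per-bin neural-behavioral coupling
#'
#' For each similarity bin, the Pearson correlation between the
#' photostimulation-induced change in activity and the change in d-prime,
#' pooled across sessions and the intermediate contrasts (each bin of each
#' complete session contributes 3 points). Computed separately per state;
#' bins with fewer than 3 points or zero variance are NA.
#'
#' @param deltas list of per-session `oc_delta` objects.
#' @param beh data.frame from [behavior_delta()].
#' @param state state to analyse.
#' @param contrasts intermediate contrasts.
#' @param sessions session indices to use (for bootstrapping).
#' @return numeric vector of correlations, one per bin plus a final
#'   `targets` element.
#' @export
coupling_by_bin <- function(deltas, beh, state, contrasts = c(2, 5, 10),
                            sessions = seq_along(deltas)) {
  nb <- deltas[[1L]]$n_bins
  all_c <- deltas[[1L]]$contrasts
  ci <- match(contrasts, all_c)
  r <- rep(NA_real_, nb + 1L)
  y_of <- function(i) vapply(contrasts, function(cc) {
    v <- beh$ddprime[beh$session == i & beh$state == state & beh$contrast == cc]
    if (length(v) == 1L) v else NA_real_
  }, numeric(1L))
  ys <- lapply(sessions, y_of)
  for (b in seq_len(nb + 1L)) {
    x <- unlist(lapply(seq_along(sessions), function(j)
      deltas[[sessions[j]]]$delta[b, ci, state]))
    y <- unlist(ys)
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      r[b] <- stats::cor(x[ok], y[ok])
  }
  names(r) <- c(paste0("bin", seq_len(nb)), "targets")
  r
}

#' Across-bin coupling slope
#'
#' Ordinary least squares of the per-bin coupling coefficients on normalized
#' similarity (bin centers mapped to `[0, 1]`), background bins only — the
#' target point is excluded from the fit.
#'
#' @param coupling_r vector from [coupling_by_bin()] (targets last).
#' @param n_bins number of similarity bins.
#' @param min_bins minimum non-missing bins required.
#' @return named vector `c(intercept, slope)` (NA when too few bins).
#' @export
coupling_slope <- function(coupling_r, n_bins = length(coupling_r) - 1L,
                           min_bins = 5L) {
  r_bg <- coupling_r[seq_len(n_bins)]
  if (sum(is.finite(r_bg)) < min_bins)
    return(c(intercept = NA_real_, slope = NA_real_))
  normsim <- (seq_len(n_bins) - 0.5) / n_bins
  fit <- ols_fit(normsim, r_bg)
  c(intercept = fit[1L], slope = fit[2L])
}

#' Session bootstrap of the coupling fit
#'
#' Resamples sessions with replacement, recomputing the per-bin couplings
#' and the across-bin slope each time; reports the mean slope, its standard
#' error (SD of resampled slopes), and per-bin standard errors.
#'
#' @param deltas list of per-session `oc_delta`.
#' @param beh data.frame from [behavior_delta()].
#' @param state state to analyse.
#' @param contrasts intermediate contrasts.
#' @param n_boot resample count.
#' @param seed integer seed.
#' @return list with `mean_slope`, `se_slope`, `slopes`, `bin_se`.
#' @export
bootstrap_coupling <- function(deltas, beh, state, contrasts = c(2, 5, 10),
                               n_boot = 5000L, seed = 1L) {
  stopifnot(length(deltas) >= 1L)
  set.seed(seed)
  n <- length(deltas)
  nb <- deltas[[1L]]$n_bins
  slopes <- numeric(n_boot)
  bins <- matrix(NA_real_, n_boot, nb + 1L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- coupling_by_bin(deltas, beh, state, contrasts, sessions = idx)
    bins[b, ] <- r
    slopes[b] <- coupling_slope(r, nb)[["slope"]]
  }
  list(mean_slope = mean(slopes, na.rm = TRUE),
       se_slope = stats::sd(slopes, na.rm = TRUE),
       slopes = slopes,
       bin_se = apply(bins, 2L, stats::sd, na.rm = TRUE))
}

## Per-session coupling tables: X[[state]] is (bins+1) x 3 x sessions
## (cross-validated delta at the intermediate contrasts), Y[[state]] is
## 3 x sessions (ddprime). Reuses precomputed deltas when available.
coupling_tables <- function(sessions, acfg, seed, contrasts_cc) {
  nses <- length(sessions)
  deltas <- vector("list", nses)
  dds <- vector("list", nses)
  for (i in seq_len(nses)) {
    ss <- sessions[[i]]
    deltas[[i]] <- ss$delta %||% crossval_similarity_delta(
      ss$responses, ss$trials, ss$states, ss$rois, acfg,
      n_splits = acfg$n_splits, seed = derive_seed(seed, "tables", i))
    dds[[i]] <- ddprime_lean(ss$trials$contrast, ss$trials$photostim,
                             ss$trials$outcome, ss$states, contrasts_cc)
  }
  nb <- deltas[[1L]]$n_bins
  ci <- match(contrasts_cc, deltas[[1L]]$contrasts)
  states <- c("more_engaged", "less_engaged")
  X <- lapply(states, function(s)
    vapply(deltas, function(d) d$delta[, ci, s],
           matrix(0, nb + 1L, length(ci))))
  Y <- lapply(states, function(s)
    vapply(dds, function(m) m[s, ], numeric(length(ci))))
  names(X) <- names(Y) <- states
  list(X = X, Y = Y, n_bins = nb)
}

## Across-bin coupling slope from tables, with optional per-session
## permutations of the contrast axis (columns) of X and Y.
slope_from_tables <- function(X, Y, nb, perm_x = NULL, perm_y = NULL) {
  nses <- dim(X)[3L]
  if (!is.null(perm_x))
    for (i in seq_len(nses)) X[, , i] <- X[, perm_x[[i]], i]
  if (!is.null(perm_y))
    for (i in seq_len(nses)) Y[, i] <- Y[perm_y[[i]], i]
  y <- as.vector(Y)
  r <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    xb <- as.vector(X[b, , ])
    ok <- is.finite(xb) & is.finite(y)
    if (sum(ok) >= 3L) {
      xs <- xb[ok]; ys <- y[ok]
      if (stats::var(xs) > 0 && stats::var(ys) > 0)
        r[b] <- stats::cor(xs, ys)
    }
  }
  coupling_slope(c(r, NA_real_), nb)[["slope"]]
}

#' Contrast-label shuffle null for the coupling slope
#'
#' Builds the chance distribution of the across-bin coupling slope by
#' shuffling trial contrast identity among the intermediate contrasts within
#' each session and recomputing the slope for every shuffle. The shuffle is
#' a session-level permutation of the three intermediate contrast labels,
#' drawn independently for the behavioral (d-prime) and neural
#' (cross-validated delta) coordinates: groups keep their trials and all
#' within-session statistics, only the contrast alignment between network
#' change and behavioral change — the quantity under test — is destroyed.
#' The observed slope is the identity permutation of the same tables, so
#' this is an exact conditional permutation test; the two-sided percentile
#' p-value has resolution floor `1/(n_shuffle + 1)`.
#'
#' (Permuting labels at the single-trial level instead would mix trials of
#' different true contrasts into each relabeled group; the resulting
#' composition noise loads on all similarity bins with a sign that follows
#' each bin's contrast tuning, which over-disperses the null slopes and
#' makes the test strongly conservative.)
#'
#' @param sessions list of per-session lists with elements `responses`,
#'   `trials`, `states`, `rois`, and optionally a precomputed `delta`
#'   (`oc_delta`; otherwise computed at `acfg$n_splits`).
#' @param acfg an [analysis_config()].
#' @param n_shuffle number of shuffles.
#' @param seed integer seed.
#' @return list per state with `observed`, `null` (vector of slopes), and
#'   `p_value`.
#' @export
shuffle_null <- function(sessions, acfg = analysis_config(),
                         n_shuffle = acfg$n_shuffle, seed = 1L) {
  stopifnot(length(sessions) >= 2L)
  cc <- acfg$coupling_contrasts
  tabs <- coupling_tables(sessions, acfg, seed, cc)
  nses <- length(sessions)
  k3 <- length(cc)
  perms <- function() lapply(seq_len(nses), function(i) sample.int(k3))
  obs <- vapply(names(tabs$X), function(s)
    slope_from_tables(tabs$X[[s]], tabs$Y[[s]], tabs$n_bins), numeric(1L))
  null <- matrix(NA_real_, n_shuffle, 2L,
                 dimnames = list(NULL, names(obs)))
  set.seed(derive_seed(seed, "shuffle"))
  for (k in seq_len(n_shuffle)) {
    px <- perms()
    py <- perms()
    null[k, ] <- vapply(names(tabs$X), function(s)
      slope_from_tables(tabs$X[[s]], tabs$Y[[s]], tabs$n_bins, px, py),
      numeric(1L))
  }
  out <- lapply(names(obs), function(s) {
    nn <- null[, s]
    nn_ok <- nn[is.finite(nn)]
    p <- if (is.finite(obs[[s]]) && length(nn_ok) > 0L) {
      lo <- (1 + sum(nn_ok <= obs[[s]])) / (length(nn_ok) + 1)
      hi <- (1 + sum(nn_ok >= obs[[s]])) / (length(nn_ok) + 1)
      min(1, 2 * min(lo, hi))
    } else NA_real_
    list(observed = obs[[s]], null = nn, p_value = p)
  })
  names(out) <- names(obs)
  out
}

#' Full neural-behavioral coupling analysis
#'
#' Computes, per state: the per-bin coupling coefficients (at the full
#' cross-validation split count), the across-bin slope, its session
#' bootstrap (mean slope and SE), and the contrast-label shuffle null with
#' p-value.
#'
#' @param sessions list of per-session lists with `responses`, `trials`,
#'   `states`, `rois`, and optionally a precomputed `delta` (`oc_delta`) and
#'   `summary` ([summarize_behavior()] output).
#' @param acfg an [analysis_config()].
#' @param seed integer seed.
#' @return object of class `oc_coupling`: per-state list with `coupling_r`,
#'   `slope`, `intercept`, `boot` (mean/SE), `null`, `p_value`; plus
#'   `beh_delta` and settings.
#' @export
coupling_analysis <- function(sessions, acfg = analysis_config(), seed = 1L) {
  cc <- acfg$coupling_contrasts
  deltas <- vector("list", length(sessions))
  tabs <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    ss <- sessions[[i]]
    deltas[[i]] <- ss$delta %||% crossval_similarity_delta(
      ss$responses, ss$trials, ss$states, ss$rois, acfg,
      n_splits = acfg$n_splits, seed = derive_seed(seed, "delta", i))
    tabs[[i]] <- if (!is.null(ss$summary)) ss$summary$table else
      summarize_behavior(ss$trials, ss$states, acfg)$table
  }
  beh <- behavior_delta(tabs, cc)
  for (i in seq_along(sessions)) sessions[[i]]$delta <- deltas[[i]]
  shuf <- shuffle_null(sessions, acfg, acfg$n_shuffle,
                       derive_seed(seed, "null"))
  states <- c("more_engaged", "less_engaged")
  per_state <- lapply(states, function(s) {
    r <- coupling_by_bin(deltas, beh, s, cc)
    sl <- coupling_slope(r, deltas[[1L]]$n_bins)
    boot <- bootstrap_coupling(deltas, beh, s, cc, n_boot = acfg$n_boot,
                               seed = derive_seed(seed, "boot"))
    list(coupling_r = r, slope = sl[["slope"]], intercept = sl[["intercept"]],
         boot = boot[c("mean_slope", "se_slope", "bin_se")],
         null = shuf[[s]]$null, null_observed = shuf[[s]]$observed,
         p_value = shuf[[s]]$p_value)
  })
  names(per_state) <- states
  structure(list(states = per_state, beh_delta = beh, deltas = deltas,
                 contrasts = cc, n_shuffle = acfg$n_shuffle,
                 n_boot = acfg$n_boot, seed = seed),
            class = "oc_coupling")
}

#' @export
print.oc_coupling <- function(x, ...) {
  cat("<neural-behavioral coupling>\n")
  for (s in names(x$states)) {
    st <- x$states[[s]]
    cat(sprintf("  %s: slope = %.4g (boot mean %.4g +/- %.4g), p = %.4g\n",
                s, st$slope, st$boot$mean_slope, st$boot$se_slope, st$p_value))
  }
  invisible(x)
}
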