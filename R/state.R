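#' Pre-trial pupil size
#'
#' Mean pupil area in the window (default 4 s) before trial onset, normalized
#' by the median pupil area of the whole session.
#'
#' @param pupil_trace per-frame pupil area.
#' @param onset_frame 0-based trial onset frame.
#' @param frame_rate_hz frame rate.
#' @param window_s window length in seconds.
#' @param session_median precomputed session median (avoids recomputation
#'   when normalizing many trials of one session).
#' @return normalized pupil size; `NA` when the window extends before the
#'   first frame (trial flagged, not imputed).
#' @export
pretrial_pupil <- function(pupil_trace, onset_frame, frame_rate_hz = 7,
                           window_s = 4,
                           session_median = stats::median(pupil_trace)) {
  win <- as.integer(round(window_s * frame_rate_hz))
  idx <- pretrial_idx(onset_frame, win)
  if (min(idx) < 1L) return(NA_real_)
  mean(pupil_trace[idx]) / session_median
}

#' Pre-trial population synchrony
#'
#' Mean of all unordered pairwise Pearson correlations between cells'
#' activity proxies in the window before trial onset. Cells with a constant
#' proxy in the window contribute no pairs.
#'
#' @param proxies cells x frames activity-proxy matrix.
#' @param onset_frame 0-based trial onset frame.
#' @param frame_rate_hz frame rate.
#' @param window_s window length in seconds.
#' @return mean pairwise correlation; `NA` when fewer than two cells vary.
#' @export
pretrial_synchrony <- function(proxies, onset_frame, frame_rate_hz = 7,
                               window_s = 4) {
  win <- as.integer(round(window_s * frame_rate_hz))
  idx <- pretrial_idx(onset_frame, win)
  if (min(idx) < 1L) return(NA_real_)
  mean_pairwise_cor(proxies[, idx, drop = FALSE])
}

#' Combined engagement score
#'
#' Z-scores pre-trial synchrony and normalized pupil (over trials with both
#' values present) and combines them as `score = z(synchrony) - z(pupil)`,
#' so that lower scores mean a larger pupil and lower synchrony — the more
#' engaged direction. By default both variables are z-scored within the
#' session; supplying `group` (e.g. an animal id per trial, with trials of
#' several sessions concatenated) z-scores within each group instead, for
#' across-animal comparability.
#'
#' @param pupil_norms,sync_raws per-trial values (NA allowed).
#' @param group optional grouping factor for the z-scores (default: one
#'   group).
#' @return per-trial score (NA where either input is missing).
#' @export
state_scores <- function(pupil_norms, sync_raws, group = NULL) {
  ok <- is.finite(pupil_norms) & is.finite(sync_raws)
  if (sum(ok) < 2L) stop("need at least 2 trials with pupil and synchrony",
                         call. = FALSE)
  group <- if (is.null(group)) rep(1L, length(pupil_norms))
           else as.integer(factor(group))
  zp <- zs <- rep(NA_real_, length(pupil_norms))
  for (g in unique(group)) {
    sel <- ok & group == g
    if (sum(sel) < 2L) next
    if (stats::sd(pupil_norms[sel]) == 0 || stats::sd(sync_raws[sel]) == 0)
      stop("zero variance in pupil or synchrony; state score degenerate",
           call. = FALSE)
    zp[sel] <- as.numeric(scale(pupil_norms[sel]))
    zs[sel] <- as.numeric(scale(sync_raws[sel]))
  }
  zs - zp
}

#' Median-split engagement states
#'
#' Labels trials below the median score `more_engaged` and above it
#' `less_engaged`; ties at the median are broken by alternation in trial
#' order so group sizes differ by at most one. Invariant to any strictly
#' monotone transform of the score.
#'
#' @param scores per-trial combined scores (NA trials stay unlabeled).
#' @return character vector of labels (`more_engaged` / `less_engaged` /
#'   `NA`).
#' @export
split_states <- function(scores) {
  lab <- rep(NA_character_, length(scores))
  ok <- which(is.finite(scores))
  if (length(ok) < 4L) stop("need at least 4 scored trials", call. = FALSE)
  s <- scores[ok]
  med <- stats::median(s)
  lab[ok[s < med]] <- "more_engaged"
  lab[ok[s > med]] <- "less_engaged"
  ties <- ok[s == med]
  if (length(ties) > 0L) {
    n_more <- sum(lab[ok] == "more_engaged", na.rm = TRUE)
    n_less <- sum(lab[ok] == "less_engaged", na.rm = TRUE)
    for (i in ties) {
      if (n_more <= n_less) {
        lab[i] <- "more_engaged"; n_more <- n_more + 1L
      } else {
        lab[i] <- "less_engaged"; n_less <- n_less + 1L
      }
    }
  }
  lab
}

#' Per-trial engagement state index for a session
#'
#' Computes pre-trial pupil (normalized to the session median) and pre-trial
#' synchrony for every trial, combines them into the engagement score, and
#' median-splits the session into two states.
#'
#' @param bundle an `oc_session`.
#' @param proxies cells x frames activity-proxy matrix (from
#'   [activity_proxy()] on the corrected traces).
#' @param acfg an [analysis_config()].
#' @return data.frame with `trial_id`, `pupil_norm`, `sync_raw`, `pupil_z`,
#'   `sync_z`, `score`, `state`.
#' @export
state_index <- function(bundle, proxies, acfg = analysis_config()) {
  rate <- bundle$frame_rate_hz
  med <- stats::median(bundle$pupil_area)
  pupil_norm <- vapply(bundle$trials$onset_frame, function(f)
    pretrial_pupil(bundle$pupil_area, f, rate, acfg$pretrial_window_s,
                   session_median = med),
    numeric(1L))
  sync_raw <- vapply(bundle$trials$onset_frame, function(f)
    pretrial_synchrony(proxies, f, rate, acfg$pretrial_window_s),
    numeric(1L))
  score <- state_scores(pupil_norm, sync_raw)
  ok <- is.finite(pupil_norm) & is.finite(sync_raw)
  zp <- zs <- rep(NA_real_, length(score))
  zp[ok] <- as.numeric(scale(pupil_norm[ok]))
  zs[ok] <- as.numeric(scale(sync_raw[ok]))
  data.frame(trial_id = bundle$trials$trial_id,
             pupil_norm = pupil_norm, sync_raw = sync_raw,
             pupil_z = zp, sync_z = zs, score = score,
             state = split_states(score),
             stringsAsFactors = FALSE)
}
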