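## Shared fixtures: a compact synthetic session reused across test files.
## Sessions use shortened trial timing so traces stay small; all seeds fixed.

oc_test_cache <- new.env(parent = emptyenv())

small_cfg <- function(...) {
  generator_config(n_cells = 60L, n_targets = 6L, n_trials = 240L,
                   iti_s = 3, withhold_mean_s = 2, withhold_jitter_s = 1, ...)
}

test_acfg <- function(...) {
  defaults <- list(n_splits = 40L, match_resamples = Inf, n_boot = 100L,
                   n_shuffle = 50L,
                   neuropil_stride = 4L, sync_max_cells = 40)
  do.call(analysis_config, utils::modifyList(defaults, list(...)))
}

cached <- function(key, expr) {
  if (is.null(oc_test_cache[[key]])) oc_test_cache[[key]] <- force(expr)
  oc_test_cache[[key]]
}

cached_session <- function() cached("session", generate_session(small_cfg(), seed = 42L))

cached_analysis <- function() cached("analysis", {
  suppressWarnings(analyze_session(cached_session(), test_acfg(),
                                   psychometrics = FALSE))
})

## Minimal trial-table builder for behavior/network unit tests.
mk_trials <- function(contrast, licks, photostim = FALSE) {
  n <- length(contrast)
  data.frame(trial_id = seq_len(n), onset_frame = seq_len(n) * 100L,
             contrast = contrast,
             photostim = rep_len(photostim, n),
             withhold_s = 3, lick_times_s = I(licks),
             outcome = NA_character_, exclusion_reason = "none",
             stringsAsFactors = FALSE)
}

## A tiny hand-built bundle for I/O and validation tests (3 cells, 4 trials).
tiny_bundle <- function(mutate = identity) {
  n_frames <- 200L
  set.seed(7)
  trials <- data.frame(
    trial_id = 1:4,
    onset_frame = c(40L, 80L, 120L, 160L),
    contrast = c(0, 2, 100, 0),
    photostim = c(FALSE, TRUE, FALSE, TRUE),
    withhold_s = c(2.5, 3.0, 2.0, 2.2),
    outcome = c("correct_rejection", "hit", "hit", "false_alarm"),
    exclusion_reason = "none",
    stringsAsFactors = FALSE)
  trials$lick_times_s <- I(list(numeric(), c(0.4, 0.52), 0.3, 0.8))
  rois <- data.frame(roi_id = 1:3, x_um = c(100, 300, 500),
                     y_um = c(200, 300, 400), plane = c(0L, 1L, 2L),
                     z_um = c(0, 33.3, 66.6),
                     is_target = c(TRUE, FALSE, FALSE), included = TRUE)
  f_roi <- matrix(stats::runif(3 * n_frames, 0.5, 1.5), nrow = 3)
  f_neu <- matrix(stats::runif(3 * n_frames, 0.2, 0.8), nrow = 3)
  args <- list(trials = trials, rois = rois, f_roi = f_roi,
               f_neuropil = f_neu,
               pupil_area = stats::runif(n_frames, 900, 1100),
               frame_rate_hz = 7,
               photostim_frames = c(80:86, 160:166),
               meta = list(session_id = "tiny", animal_id = "m0",
                           stim_orientation_deg = 90,
                           contrasts_used = c(1, 2, 5, 10, 100)))
  args <- mutate(args)
  do.call(session_bundle, c(args, list(check = FALSE)))
}
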