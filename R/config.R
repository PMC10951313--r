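#' Generator configuration
#'
#' Builds the configuration object for the synthetic-session generator. The
#' defaults describe one behavioral session of the all-optical detection
#' experiment the pipeline analyses: ~300 cells over 4 planes in a
#' 710 x 710 um field of view imaged at a 7 Hz volume rate, 360 trials of 12
#' types (five contrasts with and without photostimulation plus the two catch
#' types, in 40/40/20 proportions), a slowly drifting engagement latent that
#' couples a large pupil to low population synchrony, state-dependent Weibull
#' psychometric behavior, direct photostimulation drive to the targeted
#' ensemble, and similarity- plus distance-dependent background suppression.
#'
#' The per-state Weibull parameters default to values whose closed-form
#' threshold/width match typical engaged (3.9 / 7.4) and less-engaged
#' (4.6 / 15.0) sessions. `photostim_dp_engaged` is the additive change in
#' hit probability injected on photostimulation trials in the engaged state
#' only (positive at 2% contrast, negative at 10% by default); the
#' less-engaged state gets no injected behavioral effect.
#'
#' @param n_cells number of ROIs.
#' @param n_targets number of photostimulation targets (6-73).
#' @param n_trials number of trials; must allow >= 10 trials per trial type.
#' @param contrasts visual contrasts in percent (catch = 0 is implicit).
#' @param proportions trial-type proportions: visual-only, visual+photostim,
#'   catch (must sum to 1).
#' @param frame_rate_hz imaging volume rate.
#' @param fov_um lateral field-of-view size.
#' @param n_planes,plane_spacing_um axial sampling.
#' @param engagement_timescale_s autocorrelation time of the engagement latent.
#' @param pupil_gain,pupil_noise_sd pupil coupling to engagement and
#'   measurement noise (fraction of baseline area).
#' @param sync_gain scale of the shared (common-input) rate fluctuation; its
#'   amplitude is multiplied by (1 - engagement) so low engagement yields high
#'   synchrony.
#' @param common_timescale_s autocorrelation time of the common input.
#' @param contrast_surround_max upper bound of the per-cell surround
#'   suppression strength (relative to the driven amplitude); gives the
#'   population a continuum of contrast-response shapes, from monotone to
#'   band-pass, so functional similarity spans `[-1, 1]`.
#' @param weibull_engaged,weibull_disengaged `c(alpha, beta)` per state.
#' @param guess_rate,lapse_rate fixed psychometric asymptotes (lapse for the
#'   engaged state).
#' @param lapse_rate_disengaged lapse rate in the less-engaged state; set
#'   higher than `lapse_rate` so less-engaged performance is worse at every
#'   contrast (with fixed asymptotes, threshold/width differences alone make
#'   the two state curves cross at low contrast).
#' @param photostim_dp_engaged named vector (by contrast) of additive hit
#'   probability changes on engaged photostimulation trials.
#' @param direct_drive `c(less_engaged=, more_engaged=)` delta-F/F drive to
#'   targets, as recovered by the windowed response metric.
#' @param suppression_slope change in background delta-F/F per log10-contrast
#'   unit for a cell perfectly similar to the target average (b_true).
#' @param frac_negative_r fraction of cells with negative contrast response.
#' @param spatial_excitation_radius_um,spatial_suppression_radius_um
#'   center-surround influence kernel radii (excitation disk, suppression
#'   annulus outer edge).
#' @param spatial_excitation_amp,spatial_suppression_amp kernel amplitudes in
#'   recovered delta-F/F units.
#' @param neuropil_coeff_range range of per-cell neuropil contamination.
#' @param calcium_tau_s indicator decay time constant.
#' @param noise_sd white fluorescence noise, as a fraction of baseline F0.
#' @param visual_state_gain multiplicative gain of visual drive with
#'   engagement (drive scaled by `1 + gain * (e - 0.5)`).
#' @param early_lick_rate probability a trial is spoiled by a lick in the
#'   first 150 ms.
#' @param stim_duration_s,response_window_s,early_lick_s,iti_s,withhold_mean_s,withhold_jitter_s
#'   trial timing parameters (withhold is uniform mean +/- jitter).
#' @return an object of class `oc_generator_config` (a validated list).
#' @export
generator_config <- function(n_cells = 300L,
                             n_targets = 20L,
                             n_trials = 360L,
                             contrasts = c(1, 2, 5, 10, 100),
                             proportions = c(visual = 0.4, visual_stim = 0.4, catch = 0.2),
                             frame_rate_hz = 7,
                             fov_um = 710,
                             n_planes = 4L,
                             plane_spacing_um = 33.3,
                             engagement_timescale_s = 60,
                             pupil_gain = 0.4,
                             pupil_noise_sd = 0.02,
                             sync_gain = 0.12,
                             common_timescale_s = 0.15,
                             contrast_surround_max = 1.3,
                             weibull_engaged = c(alpha = 4.70, beta = 1.90),
                             weibull_disengaged = c(alpha = 6.23, beta = 1.20),
                             guess_rate = 0.12,
                             lapse_rate = 0.02,
                             lapse_rate_disengaged = 0.08,
                             photostim_dp_engaged = c(`1` = 0, `2` = 0.15, `5` = 0,
                                                      `10` = -0.15, `100` = 0),
                             direct_drive = c(less_engaged = 0.68, more_engaged = 0.81),
                             suppression_slope = -0.01,
                             frac_negative_r = 0.3,
                             spatial_excitation_radius_um = 15,
                             spatial_suppression_radius_um = 100,
                             spatial_excitation_amp = 0.10,
                             spatial_suppression_amp = -0.01,
                             neuropil_coeff_range = c(0.5, 0.9),
                             calcium_tau_s = 1.5,
                             noise_sd = 0.03,
                             visual_state_gain = 0.3,
                             early_lick_rate = 0.02,
                             stim_duration_s = 1,
                             response_window_s = 1.5,
                             early_lick_s = 0.15,
                             iti_s = 7,
                             withhold_mean_s = 4,
                             withhold_jitter_s = 3) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_targets = as.integer(n_targets),
    n_trials = as.integer(n_trials), contrasts = as.numeric(contrasts),
    proportions = proportions, frame_rate_hz = frame_rate_hz, fov_um = fov_um,
    n_planes = as.integer(n_planes), plane_spacing_um = plane_spacing_um,
    engagement_timescale_s = engagement_timescale_s, pupil_gain = pupil_gain,
    pupil_noise_sd = pupil_noise_sd, sync_gain = sync_gain,
    common_timescale_s = common_timescale_s,
    contrast_surround_max = contrast_surround_max,
    weibull_engaged = weibull_engaged, weibull_disengaged = weibull_disengaged,
    guess_rate = guess_rate, lapse_rate = lapse_rate,
    lapse_rate_disengaged = lapse_rate_disengaged,
    photostim_dp_engaged = photostim_dp_engaged, direct_drive = direct_drive,
    suppression_slope = suppression_slope, frac_negative_r = frac_negative_r,
    spatial_excitation_radius_um = spatial_excitation_radius_um,
    spatial_suppression_radius_um = spatial_suppression_radius_um,
    spatial_excitation_amp = spatial_excitation_amp,
    spatial_suppression_amp = spatial_suppression_amp,
    neuropil_coeff_range = neuropil_coeff_range, calcium_tau_s = calcium_tau_s,
    noise_sd = noise_sd, visual_state_gain = visual_state_gain,
    early_lick_rate = early_lick_rate, stim_duration_s = stim_duration_s,
    response_window_s = response_window_s, early_lick_s = early_lick_s,
    iti_s = iti_s, withhold_mean_s = withhold_mean_s,
    withhold_jitter_s = withhold_jitter_s)
  class(cfg) <- "oc_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_targets <= cfg$n_cells, cfg$n_targets >= 1L,
            cfg$frame_rate_hz > 0, cfg$engagement_timescale_s > 0,
            all(cfg$contrasts > 0), cfg$calcium_tau_s > 0,
            cfg$spatial_excitation_radius_um < cfg$spatial_suppression_radius_um)
  if (abs(sum(cfg$proportions) - 1) > 1e-8)
    stop("trial-type proportions must sum to 1", call. = FALSE)
  if (any(c(cfg$weibull_engaged, cfg$weibull_disengaged) <= 0))
    stop("Weibull alpha and beta must be positive", call. = FALSE)
  gl <- cfg$guess_rate + max(cfg$lapse_rate, cfg$lapse_rate_disengaged)
  if (cfg$guess_rate < 0 || cfg$lapse_rate < 0 ||
      cfg$lapse_rate_disengaged < 0 || gl >= 1)
    stop("need 0 <= guess_rate + lapse_rate < 1", call. = FALSE)
  counts <- trial_type_counts(cfg)
  if (min(counts$n) < 10L)
    stop(sprintf("n_trials = %d leaves a trial type with %d < 10 trials",
                 cfg$n_trials, min(counts$n)), call. = FALSE)
  invisible(cfg)
}

#' Analysis configuration
#'
#' Parameters of the analysis stages, separate from the generator so real and
#' synthetic sessions are analysed identically. Resample counts default to the
#' full analysis profile (10000 matching resamples, 5000 cross-validation
#' splits, 5000 bootstrap and shuffle iterations); tests and examples scale
#' them down.
#'
#' @param baseline_frames,response_frames response-metric windows (frames).
#' @param sigma_s Gaussian smoothing of the activity proxy (seconds).
#' @param pretrial_window_s state-indexing window before trial onset.
#' @param exclusion_radius_um lateral target exclusion radius (30 um diameter
#'   cylinder through all planes).
#' @param edge_rows,image_px top-of-frame exclusion band (pixel rows) and
#'   frame resolution used to convert rows to microns.
#' @param robust_estimator `"irls"` (bisquare, tuning constant 4.685) or
#'   `"theil_sen"`.
#' @param response_threshold delta-F/F above which a target counts as having
#'   responded on a trial (also the mapping responsivity criterion).
#' @param fail_frac photostimulation trials with more than this fraction of
#'   failed targets are excluded.
#' @param truncation_window,truncation_frac session truncation: rolling window
#'   (easy-contrast trials) and fraction of starting performance.
#' @param lapse_rate fixed psychometric lapse rate.
#' @param n_bins number of similarity bins on `[-1, 1]`.
#' @param n_splits cross-validation splits.
#' @param match_resamples hit:miss matching resamples (`Inf` for the exact
#'   infinite-resample limit, used inside the cross-validation loop).
#' @param n_boot session bootstrap resamples.
#' @param n_shuffle contrast-label shuffles for the coupling null.
#' @param coupling_contrasts contrasts entering the coupling analysis.
#' @param neuropil_stride frame subsampling stride for the contamination
#'   slope estimate (the correction itself always uses all frames).
#' @param sync_max_cells cap on the number of cells entering the pairwise
#'   synchrony estimate (an evenly spaced subset is used above the cap).
#' @return an object of class `oc_analysis_config`.
#' @export
analysis_config <- function(baseline_frames = 7L,
                            response_frames = 4L,
                            sigma_s = 0.5,
                            pretrial_window_s = 4,
                            exclusion_radius_um = 15,
                            edge_rows = 100L,
                            image_px = 512L,
                            robust_estimator = c("irls", "theil_sen"),
                            response_threshold = 0.3,
                            fail_frac = 0.5,
                            truncation_window = 20L,
                            truncation_frac = 0.8,
                            lapse_rate = 0.01,
                            n_bins = 20L,
                            n_splits = 5000L,
                            match_resamples = Inf,
                            n_boot = 5000L,
                            n_shuffle = 5000L,
                            coupling_contrasts = c(2, 5, 10),
                            neuropil_stride = 1L,
                            sync_max_cells = Inf) {
  cfg <- list(
    baseline_frames = as.integer(baseline_frames),
    response_frames = as.integer(response_frames),
    sigma_s = sigma_s, pretrial_window_s = pretrial_window_s,
    exclusion_radius_um = exclusion_radius_um,
    edge_rows = as.integer(edge_rows), image_px = as.integer(image_px),
    robust_estimator = match.arg(robust_estimator),
    response_threshold = response_threshold, fail_frac = fail_frac,
    truncation_window = as.integer(truncation_window),
    truncation_frac = truncation_frac, lapse_rate = lapse_rate,
    n_bins = as.integer(n_bins), n_splits = as.integer(n_splits),
    match_resamples = match_resamples, n_boot = as.integer(n_boot),
    n_shuffle = as.integer(n_shuffle),
    coupling_contrasts = coupling_contrasts,
    neuropil_stride = as.integer(neuropil_stride),
    sync_max_cells = sync_max_cells)
  stopifnot(cfg$baseline_frames > 0, cfg$response_frames > 0,
            cfg$n_bins >= 2L, cfg$n_splits >= 1L, cfg$n_boot >= 1L,
            cfg$n_shuffle >= 1L)
  class(cfg) <- "oc_analysis_config"
  cfg
}

## The 12 trial types and their target counts for a configuration.
## Types: each contrast x {no-stim, stim} plus catch x {no-stim, stim}.
trial_type_counts <- function(cfg) {
  nc <- length(cfg$contrasts)
  types <- data.frame(
    contrast = c(rep(cfg$contrasts, 2L), 0, 0),
    photostim = c(rep(FALSE, nc), rep(TRUE, nc), FALSE, TRUE))
  p <- c(rep(cfg$proportions[["visual"]] / nc, nc),
         rep(cfg$proportions[["visual_stim"]] / nc, nc),
         rep(cfg$proportions[["catch"]] / 2, 2L))
  types$n <- apportion(cfg$n_trials, p)
  types
}
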