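#' Naka-Rushton contrast response
#'
#' Standard V1 contrast-response form `r(c) = R * c^n / (c^n + c50^n)`. The
#' sign of `rmax` sets whether a cell is driven or suppressed by contrast.
#'
#' @param contrast contrast in percent.
#' @param rmax signed response amplitude (delta-F/F at saturation).
#' @param c50 semi-saturation contrast.
#' @param n exponent.
#' @return numeric response values.
#' @export
naka_rushton <- function(contrast, rmax, c50, n) {
  cn <- contrast^n
  rmax * cn / (cn + c50^n)
}

#' Calcium-kernel attenuation of the windowed response metric
#'
#' The trial response metric averages 4 frames starting immediately after a
#' 1 s (7-frame) stimulus, on traces convolved with an exponential indicator
#' kernel. For a unit-amplitude rate pulse this returns the exact factor by
#' which the windowed delta-F/F underestimates the pulse amplitude; the
#' generator divides injected amplitudes by it so configured effect sizes are
#' what the metric recovers.
#'
#' @param tau_s indicator decay constant (seconds).
#' @param rate_hz frame rate.
#' @param pulse_frames stimulus duration in frames.
#' @param response_frames response-window length in frames.
#' @return scalar attenuation factor in (0, 1).
#' @export
pulse_response_factor <- function(tau_s, rate_hz, pulse_frames = 7L,
                                  response_frames = 4L) {
  a <- exp(-1 / (rate_hz * tau_s))
  (1 - a^pulse_frames) * mean(a^seq_len(response_frames))
}

#' Generate the engagement latent and its observable correlates
#'
#' The engagement state is a bounded, slowly drifting latent: a logistic
#' squash of an Ornstein-Uhlenbeck process with autocorrelation time
#' `engagement_timescale_s`. Pupil area follows engagement positively
#' (`p0 * (1 + pupil_gain * (e - 1/2))` plus noise) while the variance of the
#' shared "common input" to all cells scales with `(1 - e)`, so periods of low
#' engagement show a small pupil and high population synchrony — the
#' anticorrelation the state index relies on.
#'
#' @param n_frames trace length in frames.
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @return list with `engagement` (in `[0, 1]`), `pupil_area`, and
#'   `common_input` (unit-variance AR(1)) traces of length `n_frames`.
#' @export
generate_engagement <- function(n_frames, cfg, seed) {
  stopifnot(n_frames > 0, cfg$engagement_timescale_s > 0)
  set.seed(seed)
  a_e <- exp(-1 / (cfg$frame_rate_hz * cfg$engagement_timescale_s))
  x <- ar1_noise(n_frames, a_e)
  e <- stats::plogis(1.2 * x)
  p0 <- 1000
  pupil <- p0 * (1 + cfg$pupil_gain * (e - 0.5)) +
    p0 * cfg$pupil_noise_sd * stats::rnorm(n_frames)
  a_c <- exp(-1 / (cfg$frame_rate_hz * cfg$common_timescale_s))
  common <- ar1_noise(n_frames, a_c)
  list(engagement = e, pupil_area = pupil, common_input = common)
}

#' Generate the simulated cell population
#'
#' Positions cells uniformly over the field of view and four imaging planes,
#' draws per-cell Naka-Rushton contrast-response parameters (a configured
#' fraction with negative amplitude, i.e. suppressed by contrast), assigns
#' preferred orientations, and selects the photostimulation ensemble as the
#' largest group of photostimulation-responsive cells co-tuned to the session
#' orientation (re-tuning the strongest remaining cells when the group would
#' otherwise be smaller than `n_targets`, so every configuration is
#' satisfiable by construction).
#'
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @return list with `rois` (ROI table), `params` (per-cell ground-truth
#'   parameter table), `curves` (cells x contrasts true response curves),
#'   `stim_orientation_deg`, and `sim` (true contrast-curve correlation of
#'   each cell with the target-average curve).
#' @export
generate_population <- function(cfg, seed) {
  if (cfg$n_targets > cfg$n_cells)
    stop("n_targets exceeds n_cells", call. = FALSE)
  set.seed(seed)
  nc <- cfg$n_cells
  orientations <- seq(0, 315, by = 45)
  x <- stats::runif(nc, 0, cfg$fov_um)
  y <- stats::runif(nc, 0, cfg$fov_um)
  plane <- sample(0:(cfg$n_planes - 1L), nc, replace = TRUE)
  negative <- stats::runif(nc) < cfg$frac_negative_r
  rmax <- ifelse(negative,
                 -stats::rlnorm(nc, log(0.15), 0.4),
                 stats::rlnorm(nc, log(0.30), 0.5))
  c50 <- stats::runif(nc, 3, 30)
  nexp <- stats::runif(nc, 1.2, 2.5)
  ## surround suppression: a second, opposing high-contrast component of
  ## variable strength gives curve shapes from monotone to band-pass
  surround <- stats::runif(nc, 0, cfg$contrast_surround_max)
  rmax2 <- -surround * rmax
  c50_2 <- stats::runif(nc, 20, 90)
  n_2 <- stats::runif(nc, 1, 2)
  theta <- sample(orientations, nc, replace = TRUE)
  photo_resp <- stats::runif(nc) < 0.6

  ## session orientation = modal preference among driven, opsin-positive,
  ## monotonically contrast-driven cells
  pool <- rmax > 0 & photo_resp & surround < 0.25
  orient <- if (any(pool)) as.numeric(names(which.max(table(theta[pool]))))
            else as.numeric(names(which.max(table(theta))))
  eligible <- which(pool & theta == orient)
  short <- cfg$n_targets - length(eligible)
  if (short > 0) {
    extra <- setdiff(order(-abs(rmax)), eligible)[seq_len(short)]
    theta[extra] <- orient
    rmax[extra] <- abs(rmax[extra])
    rmax2[extra] <- -0.1 * rmax[extra]
    surround[extra] <- 0.1
    photo_resp[extra] <- TRUE
    eligible <- c(eligible, extra)
  }
  targets <- eligible[order(-rmax[eligible])][seq_len(cfg$n_targets)]
  is_target <- rep(FALSE, nc)
  is_target[targets] <- TRUE

  photo_amp <- ifelse(photo_resp, stats::runif(nc, 0.4, 1.0),
                      stats::runif(nc, 0, 0.15))
  photo_amp[is_target] <- stats::runif(sum(is_target), 0.5, 1.0)

  curves <- t(vapply(seq_len(nc), function(i)
    naka_rushton(cfg$contrasts, rmax[i], c50[i], nexp[i]) +
      naka_rushton(cfg$contrasts, rmax2[i], c50_2[i], n_2[i]),
    numeric(length(cfg$contrasts))))
  target_curve <- colMeans(curves[targets, , drop = FALSE])
  sim <- row_cor(curves, target_curve)

  rois <- data.frame(
    roi_id = seq_len(nc), x_um = x, y_um = y, plane = plane,
    z_um = plane * cfg$plane_spacing_um, is_target = is_target,
    included = TRUE)
  params <- data.frame(
    roi_id = seq_len(nc), r_max = rmax, c50 = c50, n_exp = nexp,
    r_max2 = rmax2, c50_2 = c50_2, n_2 = n_2,
    theta_deg = theta, photo_responsive = photo_resp, photo_amp = photo_amp,
    neuropil_coeff = stats::runif(nc, cfg$neuropil_coeff_range[1],
                                  cfg$neuropil_coeff_range[2]),
    baseline_f0 = stats::runif(nc, 0.5, 2),
    common_loading = stats::runif(nc, 0.5, 1.5))
  list(rois = rois, params = params, curves = curves,
       stim_orientation_deg = orient, sim = sim)
}

#' Generate the trial sequence
#'
#' Draws the 12 trial types (five contrasts with and without
#' photostimulation, plus the two catch types) in the configured 40/40/20
#' proportions using largest-remainder apportionment, in a pseudorandom order
#' with no immediate repeats of the same type, and lays out onset frames using
#' the task timing (withhold uniform `mean +/- jitter`, 1 s stimulus, 1.5 s
#' response window, fixed inter-trial period).
#'
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @return trial table (conditions and onsets only; outcomes unset).
#' @export
generate_trials <- function(cfg, seed) {
  set.seed(seed)
  types <- trial_type_counts(cfg)
  if (min(types$n) < 10L)
    stop("n_trials too small: a trial type would have fewer than 10 trials",
         call. = FALSE)
  seq_t <- sample(rep.int(seq_len(nrow(types)), types$n))
  n <- length(seq_t)
  for (pass in seq_len(200L)) {
    dup <- which(seq_t[-1L] == seq_t[-n]) + 1L
    if (length(dup) == 0L) break
    for (i in dup) {
      if (seq_t[i] != seq_t[i - 1L]) next
      v <- seq_t[i]
      left <- c(seq_t[-1L], -1L)
      right <- c(-1L, seq_t[-n])
      cand <- which(seq_t != v & left != v & right != v)
      cand <- setdiff(cand, c(i - 1L, i, if (i < n) i + 1L))
      if (length(cand) == 0L) next
      j <- cand[sample.int(length(cand), 1L)]
      tmp <- seq_t[j]; seq_t[j] <- seq_t[i]; seq_t[i] <- tmp
    }
  }
  if (any(seq_t[-1L] == seq_t[-n]))
    stop("could not order trials without immediate type repeats", call. = FALSE)

  withhold <- stats::runif(n, cfg$withhold_mean_s - cfg$withhold_jitter_s,
                           cfg$withhold_mean_s + cfg$withhold_jitter_s)
  gap <- cfg$stim_duration_s + cfg$response_window_s + cfg$iti_s
  onset_s <- 30 + cumsum(withhold + c(0, rep(gap, n - 1L)))
  data.frame(
    trial_id = seq_len(n),
    onset_frame = as.integer(floor(onset_s * cfg$frame_rate_hz)),
    contrast = types$contrast[seq_t],
    photostim = types$photostim[seq_t],
    withhold_s = withhold,
    lick_times_s = I(replicate(n, numeric(), simplify = FALSE)),
    outcome = NA_character_,
    exclusion_reason = "none",
    stringsAsFactors = FALSE)
}

#' Simulate licking behavior
#'
#' Assigns lick times and outcomes given the engagement latent. Each trial's
#' hit probability is the state's fixed-asymptote Weibull at its contrast,
#' plus — on photostimulation trials in the engaged state only — the injected
#' additive effect `photostim_dp_engaged`. Catch trials lick at the guess
#' rate. Hits receive a lick inside the 1.5 s response window; a configured
#' fraction of trials is spoiled by an early lick within the first 150 ms.
#' A trial counts as engaged when mean engagement in the pre-trial window
#' exceeds the session median.
#'
#' @param trials trial table from [generate_trials()].
#' @param engagement per-frame engagement latent.
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @return the trial table with `lick_times_s`, `outcome` and a logical
#'   `engaged_true` column added.
#' @export
simulate_behavior <- function(trials, engagement, cfg, seed) {
  set.seed(seed)
  n <- nrow(trials)
  win <- as.integer(round(4 * cfg$frame_rate_hz))
  e_pre <- vapply(trials$onset_frame, function(f)
    mean(engagement[(f - win + 1L):f]), numeric(1L))
  engaged <- e_pre > stats::median(e_pre)

  alpha <- ifelse(engaged, cfg$weibull_engaged[[1L]], cfg$weibull_disengaged[[1L]])
  beta <- ifelse(engaged, cfg$weibull_engaged[[2L]], cfg$weibull_disengaged[[2L]])
  lapse <- ifelse(engaged, cfg$lapse_rate, cfg$lapse_rate_disengaged)
  p <- ifelse(trials$contrast > 0,
              weibull_performance(trials$contrast, alpha, beta,
                                  cfg$guess_rate, lapse),
              cfg$guess_rate)
  dp <- rep(0, n)
  go_stim <- trials$photostim & engaged & trials$contrast > 0
  dp[go_stim] <- cfg$photostim_dp_engaged[as.character(trials$contrast[go_stim])]
  p <- pmin(pmax(p + dp, 0), 1)

  licked <- stats::runif(n) < p
  early <- stats::runif(n) < cfg$early_lick_rate
  licks <- vector("list", n)
  for (i in seq_len(n)) {
    l <- numeric()
    if (licked[i]) {
      first <- stats::runif(1, cfg$early_lick_s + 0.05,
                            cfg$response_window_s - 0.05)
      l <- first + c(0, 0.12, 0.26)[seq_len(sample.int(3L, 1L))]
    }
    if (early[i]) l <- c(stats::runif(1, 0.02, cfg$early_lick_s - 0.001), l)
    licks[[i]] <- sort(l)
  }
  trials$lick_times_s <- I(licks)
  trials$engaged_true <- engaged
  classify_outcomes(trials, response_window_s = cfg$response_window_s,
                    early_lick_s = cfg$early_lick_s)
}

## Center-surround lateral influence kernel (recovered delta-F/F units).
spatial_kernel_amp <- function(dist_um, cfg) {
  ifelse(dist_um < cfg$spatial_excitation_radius_um, cfg$spatial_excitation_amp,
         ifelse(dist_um <= cfg$spatial_suppression_radius_um,
                cfg$spatial_suppression_amp, 0))
}

#' Synthesize fluorescence traces
#'
#' Builds per-cell underlying rates (baseline, state-gained visual drive,
#' engagement-scaled common input, direct photostimulation drive to targets,
#' and distance- plus similarity-dependent background influence), convolves
#' them with an exponential indicator kernel, and emits neuropil-contaminated
#' fluorescence. All injected amplitudes are pre-divided by
#' [pulse_response_factor()] so the windowed response metric recovers them.
#'
#' @param pop population from [generate_population()].
#' @param trials trial table with `engaged_true` (from [simulate_behavior()]).
#' @param eng engagement list from [generate_engagement()] covering
#'   `n_frames`.
#' @param n_frames total frame count.
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @return list with `f_roi`, `f_neuropil` (cells x frames) and
#'   `photostim_frames` (0-based).
#' @export
synthesize_traces <- function(pop, trials, eng, n_frames, cfg, seed) {
  set.seed(seed)
  nc <- cfg$n_cells
  rate <- cfg$frame_rate_hz
  pulse <- as.integer(round(cfg$stim_duration_s * rate))
  atten <- pulse_response_factor(cfg$calcium_tau_s, rate, pulse, 4L)
  pr <- pop$params
  targets <- which(pop$rois$is_target)

  rates <- pr$common_loading %o%
    (eng$common_input * (1 - eng$engagement) * cfg$sync_gain)

  ## lateral distance of every cell to its nearest target (z collapsed)
  dx <- outer(pop$rois$x_um, pop$rois$x_um[targets], "-")
  dy <- outer(pop$rois$y_um, pop$rois$y_um[targets], "-")
  dmin <- sqrt(apply(dx^2 + dy^2, 1L, min))
  kern <- spatial_kernel_amp(dmin, cfg)
  kern[targets] <- 0

  ci <- match(trials$contrast, cfg$contrasts)
  logc <- ifelse(trials$contrast > 0, log10(trials$contrast), 0)
  n_tr <- nrow(trials)
  amp <- matrix(0, nc, n_tr)
  vis <- which(trials$contrast > 0)
  gain <- 1 + cfg$visual_state_gain *
    (eng$engagement[trials$onset_frame + 1L] - 0.5)
  if (length(vis) > 0L)
    amp[, vis] <- pop$curves[, ci[vis], drop = FALSE] *
      rep(gain[vis], each = nc)
  stim <- which(trials$photostim)
  if (length(stim) > 0L) {
    dd <- ifelse(trials$engaged_true[stim],
                 cfg$direct_drive[["more_engaged"]],
                 cfg$direct_drive[["less_engaged"]])
    amp[targets, stim] <- amp[targets, stim] + rep(dd, each = length(targets))
    sim0 <- pop$sim
    sim0[is.na(sim0)] <- 0
    bg <- kern + cfg$suppression_slope * (sim0 %o% logc[stim])
    bg[targets, ] <- 0
    amp[, stim] <- amp[, stim] + bg
  }
  cols <- rep(trials$onset_frame, each = pulse) +
    rep.int(seq_len(pulse), n_tr)
  rates[, cols] <- rates[, cols] +
    amp[, rep(seq_len(n_tr), each = pulse), drop = FALSE] / atten

  s <- exp_filter_rows(rates, exp(-1 / (rate * cfg$calcium_tau_s)))
  s <- pmax(s, -0.9)
  rm(rates)

  ## neuropil: shared slow background plus per-cell slow and fast
  ## components; it never contains the cells' own signal, so the
  ## contamination coefficient is identifiable
  a_np <- exp(-1 / (rate * 1.0))
  shared <- ar1_noise(n_frames, a_np)
  own_slow <- ar1_noise_rows(nc, n_frames, a_np)
  own_fast <- ar1_noise_rows(nc, n_frames, exp(-1 / (rate * 0.15)))
  f0n <- stats::runif(nc, 0.3, 0.8) * pr$baseline_f0
  neu <- f0n * (1 + 0.08 * (stats::runif(nc, 0.5, 1.5) %o% shared) +
                  0.04 * own_slow + 0.20 * own_fast)
  rm(own_slow, own_fast)

  noise <- matrix(stats::rnorm(nc * n_frames, sd = cfg$noise_sd), nrow = nc) *
    pr$baseline_f0
  f_roi <- pr$baseline_f0 * (1 + s) + pr$neuropil_coeff * neu + noise
  f_neu <- neu + matrix(stats::rnorm(nc * n_frames, sd = cfg$noise_sd * 0.3),
                        nrow = nc) * f0n
  ps_frames <- unlist(lapply(which(trials$photostim), function(t)
    trials$onset_frame[t] + 0:(pulse - 1L)))
  list(f_roi = pmax(f_roi, 0), f_neuropil = pmax(f_neu, 0),
       photostim_frames = as.integer(ps_frames))
}

#' Generate a complete synthetic session
#'
#' Composes population, trial, engagement, behavior and trace generation into
#' a validated [session_bundle()] with full ground truth attached. Identical
#' `(cfg, seed)` yield bit-identical bundles.
#'
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @param session_id,animal_id identifiers stored in metadata.
#' @return an `oc_session` with `truth` recording every injected quantity.
#' @export
generate_session <- function(cfg = generator_config(), seed = 1L,
                             session_id = sprintf("sim%04d", seed),
                             animal_id = "simulated") {
  validate_generator_config(cfg)
  pop <- generate_population(cfg, derive_seed(seed, "population"))
  trials <- generate_trials(cfg, derive_seed(seed, "trials"))
  n_frames <- max(trials$onset_frame) +
    as.integer(ceiling(15 * cfg$frame_rate_hz))
  eng <- generate_engagement(n_frames, cfg, derive_seed(seed, "engagement"))
  trials <- simulate_behavior(trials, eng$engagement, cfg,
                              derive_seed(seed, "behavior"))
  tr <- synthesize_traces(pop, trials, eng, n_frames, cfg,
                          derive_seed(seed, "traces"))
  truth <- list(
    params = pop$params, curves = pop$curves, sim = pop$sim,
    engagement = eng$engagement, common_input = eng$common_input,
    engaged_true = trials$engaged_true,
    stim_orientation_deg = pop$stim_orientation_deg,
    photostim_dp_engaged = cfg$photostim_dp_engaged,
    direct_drive = cfg$direct_drive,
    suppression_slope = cfg$suppression_slope,
    target_ids = pop$rois$roi_id[pop$rois$is_target])
  session_bundle(
    trials = trials, rois = pop$rois,
    f_roi = tr$f_roi, f_neuropil = tr$f_neuropil,
    pupil_area = eng$pupil_area, frame_rate_hz = cfg$frame_rate_hz,
    photostim_frames = tr$photostim_frames,
    meta = list(session_id = session_id, animal_id = animal_id,
                stim_orientation_deg = pop$stim_orientation_deg,
                contrasts_used = cfg$contrasts, fov_um = cfg$fov_um),
    truth = truth)
}

#' Generate a pre-task mapping block
#'
#' Emulates the orientation-mapping and photostimulation-responsivity blocks
#' run before the task, emitting trial-level delta-F/F responses directly
#' (the generator's contract covers extracted responses, not raw mapping
#' movies). Visual responses follow each cell's orientation tuning around its
#' true preference with amplitude equal to its full-contrast response;
#' photostimulation responses follow the cell's direct responsivity.
#'
#' @param pop population from [generate_population()].
#' @param cfg an [generator_config()].
#' @param seed integer seed.
#' @param n_rep mapping repeats per condition.
#' @return list with `orientations`, `vis` (cells x orientations x repeats)
#'   and `photo` (cells x repeats) response arrays.
#' @export
generate_mapping_block <- function(pop, cfg, seed, n_rep = 10L) {
  set.seed(seed)
  nc <- cfg$n_cells
  orientations <- seq(0, 315, by = 45)
  amp100 <- pop$curves[, length(cfg$contrasts)]
  ## direction-selective von-Mises-like tuning around the true preference
  tune <- sapply(orientations, function(phi)
    amp100 * exp((cos((phi - pop$params$theta_deg) * pi / 180) - 1) / 0.3))
  vis <- array(rep(tune, n_rep), dim = c(nc, length(orientations), n_rep)) +
    array(stats::rnorm(nc * length(orientations) * n_rep, sd = 0.1),
          dim = c(nc, length(orientations), n_rep))
  photo <- matrix(rep(pop$params$photo_amp, n_rep), nrow = nc) +
    matrix(stats::rnorm(nc * n_rep, sd = 0.1), nrow = nc)
  list(orientations = orientations, vis = vis, photo = photo)
}
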