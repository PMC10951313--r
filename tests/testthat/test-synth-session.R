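test_that("generation is deterministic and seed-sensitive", {
  cfg <- small_cfg()
  b1 <- generate_session(cfg, seed = 11L)
  b2 <- generate_session(cfg, seed = 11L)
  expect_identical(b1$f_roi, b2$f_roi)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$pupil_area, b2$pupil_area)
  b3 <- generate_session(cfg, seed = 12L)
  expect_false(identical(b1$trials$outcome, b3$trials$outcome))
  expect_length(validate_session(b1), 0L)
})

test_that("trial sequences respect counts, proportions and no-repeat rule", {
  cfg <- generator_config()  # 360 trials
  tr <- generate_trials(cfg, seed = 3L)
  type <- paste(tr$contrast, tr$photostim)
  counts <- table(type)
  expect_length(counts, 12L)
  expect_true(all(counts >= 10L))
  expect_equal(sum(tr$contrast == 0), 72L, tolerance = 0)  # 20% of 360
  expect_equal(sum(type[-1L] == type[-length(type)]), 0L)
  expect_true(all(diff(tr$onset_frame) > 0))
  expect_error(generator_config(n_trials = 60L), "< 10")
})

test_that("population construction honors targets, tuning and sign fraction", {
  cfg <- generator_config(n_cells = 1500L, n_targets = 25L,
                          frac_negative_r = 0.3)
  pop <- generate_population(cfg, seed = 5L)
  expect_equal(sum(pop$rois$is_target), 25L)
  tc <- colMeans(pop$curves[pop$rois$is_target, ])
  expect_true(all(diff(tc) > 0))  # target mean curve monotone in contrast
  frac_neg <- mean(pop$params$r_max < 0)
  se <- sqrt(0.3 * 0.7 / 1500)
  expect_lt(abs(frac_neg - 0.3), 4 * se)
  expect_true(all(pop$params$theta_deg[pop$rois$is_target] ==
                    pop$stim_orientation_deg))
  expect_error(generate_population(generator_config(n_cells = 10L,
                                                    n_targets = 20L), 1L))
})

test_that("engagement latent couples pupil positively and synchrony negatively", {
  cfg <- small_cfg()
  eng1 <- generate_engagement(5000L, cfg, seed = 2L)
  eng2 <- generate_engagement(5000L, cfg, seed = 2L)
  expect_identical(eng1$engagement, eng2$engagement)
  expect_true(all(eng1$engagement >= 0 & eng1$engagement <= 1))
  expect_gt(cor(eng1$pupil_area, eng1$engagement), 0.5)

  cfg0 <- small_cfg(pupil_gain = 0)
  eng0 <- generate_engagement(5000L, cfg0, seed = 2L)
  expect_lt(abs(cor(eng0$pupil_area, eng0$engagement)), 0.1)
})

test_that("pre-trial pupil and synchrony are anticorrelated across sessions", {
  ## the constructed engagement latent drives pupil up and shared
  ## variability down; the measured per-trial indices must reflect it
  cors <- vapply(1:4, function(i) {
    cfg <- generator_config(n_cells = 50L, n_targets = 6L, n_trials = 132L,
                            iti_s = 3, withhold_mean_s = 2,
                            withhold_jitter_s = 1)
    b <- generate_session(cfg, seed = 60L + i)
    sa <- suppressWarnings(analyze_session(b, test_acfg(),
                                           psychometrics = FALSE))
    cor(sa$states_df$pupil_norm, sa$states_df$sync_raw,
        use = "complete.obs")
  }, numeric(1L))
  expect_lt(mean(cors), 0)
  expect_gt(mean(cors < 0), 0.5)
})

test_that("simulated behavior matches the injected psychometric structure", {
  cfg <- generator_config(n_cells = 20L, n_targets = 6L, n_trials = 2400L,
                          iti_s = 3, withhold_mean_s = 2, withhold_jitter_s = 1)
  tr <- generate_trials(cfg, seed = 8L)
  n_frames <- max(tr$onset_frame) + 200L
  eng <- generate_engagement(n_frames, cfg, seed = 9L)
  tr <- simulate_behavior(tr, eng$engagement, cfg, seed = 10L)

  hundred <- tr$contrast == 100 & tr$outcome %in% c("hit", "miss")
  hr_eng <- mean(tr$outcome[hundred & tr$engaged_true] == "hit")
  hr_dis <- mean(tr$outcome[hundred & !tr$engaged_true] == "hit")
  expect_lt(abs(hr_eng - (1 - cfg$lapse_rate)),
            3 * sqrt(0.02 / sum(hundred)) + 0.01)
  expect_lt(abs(hr_dis - (1 - cfg$lapse_rate_disengaged)),
            3 * sqrt(0.08 / sum(hundred)) + 0.01)

  catch <- tr$contrast == 0 & tr$outcome %in% c("false_alarm",
                                                "correct_rejection")
  fa <- mean(tr$outcome[catch] == "false_alarm")
  expect_lt(abs(fa - cfg$guess_rate), 4 * sqrt(0.12 * 0.88 / sum(catch)))

  ## injected engaged-only photostimulation effect at 2% contrast
  eng2 <- tr$engaged_true & tr$contrast == 2 & tr$outcome %in% c("hit", "miss")
  d_eng <- mean(tr$outcome[eng2 & tr$photostim] == "hit") -
    mean(tr$outcome[eng2 & !tr$photostim] == "hit")
  dis2 <- !tr$engaged_true & tr$contrast == 2 & tr$outcome %in% c("hit", "miss")
  d_dis <- mean(tr$outcome[dis2 & tr$photostim] == "hit") -
    mean(tr$outcome[dis2 & !tr$photostim] == "hit")
  expect_lt(abs(d_eng - 0.15), 0.12)
  expect_lt(abs(d_dis), 0.12)
})

test_that("windowed metric recovers the calcium-kernel pulse attenuation", {
  ## brute-force oracle: simulate the recursive filter on a unit pulse
  a <- exp(-1 / (7 * 1.5))
  x <- c(rep(0, 20), rep(1, 7), rep(0, 10))
  y <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  oracle <- mean(y[28:31])   # 4 frames after pulse offset
  expect_equal(pulse_response_factor(1.5, 7, 7L, 4L), oracle,
               tolerance = 1e-12)
})

test_that("direct drive and null network effects are recovered from traces", {
  b <- cached_session()
  sa <- cached_analysis()
  ti <- which(b$rois$is_target)
  ct <- b$trials$photostim & b$trials$contrast == 0 &
    b$trials$outcome != "excluded"
  cn <- !b$trials$photostim & b$trials$contrast == 0 &
    b$trials$outcome != "excluded"
  eng <- b$trials$engaged_true
  d_eng <- mean(colMeans(sa$responses[ct & eng, ti, drop = FALSE]) -
                  colMeans(sa$responses[cn & eng, ti, drop = FALSE]))
  d_dis <- mean(colMeans(sa$responses[ct & !eng, ti, drop = FALSE]) -
                  colMeans(sa$responses[cn & !eng, ti, drop = FALSE]))
  expect_lt(abs(d_eng - 0.81), 0.15)
  expect_lt(abs(d_dis - 0.68), 0.15)

  ## with no injected network effect the background change is null
  cfg0 <- small_cfg(suppression_slope = 0, spatial_excitation_amp = 0,
                    spatial_suppression_amp = 0)
  b0 <- generate_session(cfg0, seed = 77L)
  sa0 <- suppressWarnings(analyze_session(b0, test_acfg(),
                                          psychometrics = FALSE))
  bg <- which(!b0$rois$is_target)
  stim <- b0$trials$photostim & b0$trials$outcome != "excluded"
  vis <- !b0$trials$photostim & b0$trials$outcome != "excluded"
  d_bg <- mean(colMeans(sa0$responses[stim, bg]) -
                 colMeans(sa0$responses[vis, bg]))
  expect_lt(abs(d_bg), 0.01)
})

test_that("neuropil contamination is recovered by the estimator", {
  b <- cached_session()
  sa <- cached_analysis()
  err <- abs(sa$neuropil_slopes - b$truth$params$neuropil_coeff)
  expect_lt(mean(err), 0.05)
})
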