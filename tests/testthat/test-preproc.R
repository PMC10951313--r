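make_contaminated <- function(slope = 0.7, n = 20000L, seed = 1L) {
  set.seed(seed)
  a <- exp(-1 / 7)
  slow <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - a^2)), a,
                                   method = "recursive"))
  neu <- 0.5 + 0.04 * slow + 0.10 * rnorm(n)
  ## sparse positive transients: the cell's own signal
  sig <- numeric(n)
  spikes <- sample.int(n - 20L, 5L * n %/% 400L)
  for (s in spikes) sig[s:(s + 15L)] <- sig[s:(s + 15L)] +
      0.6 * exp(-(0:15) / 5)
  roi <- 1 + sig + slope * neu + rnorm(n, sd = 0.03)
  list(roi = roi, neu = neu, sig = sig)
}

test_that("robust regression recovers the contamination slope", {
  d <- make_contaminated(0.7)
  expect_lt(abs(estimate_neuropil_coefficient(d$roi, d$neu) - 0.7), 0.05)

  ## independent traces give ~0; identity gives 1
  set.seed(2)
  roi <- 1 + rnorm(2000, sd = 0.1)
  neu <- 0.5 + rnorm(2000, sd = 0.1)
  expect_lt(abs(estimate_neuropil_coefficient(roi, neu)), 0.05)
  expect_equal(estimate_neuropil_coefficient(neu, neu), 1, tolerance = 1e-6)
  expect_error(estimate_neuropil_coefficient(roi, rep(1, 2000)), "constant")
})

test_that("IRLS bisquare slope agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  d <- make_contaminated(0.62, seed = 3L)
  ref <- MASS::rlm(d$roi ~ d$neu, psi = MASS::psi.bisquare, c = 4.685,
                   maxit = 100)$coefficients[[2L]]
  expect_equal(estimate_neuropil_coefficient(d$roi, d$neu), ref,
               tolerance = 0.01)
})

test_that("Theil-Sen alternative recovers the slope too", {
  d <- make_contaminated(0.8, seed = 4L)
  set.seed(5)
  expect_lt(abs(estimate_neuropil_coefficient(d$roi, d$neu,
                                              estimator = "theil_sen") - 0.8),
            0.08)
})

test_that("neuropil correction removes the baseline correlation", {
  for (s in 1:5) {
    d <- make_contaminated(runif(1, 0.5, 0.9), seed = 10L + s)
    slope <- estimate_neuropil_coefficient(d$roi, d$neu)
    corrected <- neuropil_correct(d$roi, d$neu, slope)
    base <- d$sig == 0     # frames without the cell's own transients
    expect_lt(abs(cor(corrected[base], d$neu[base])), 0.02)
    ## correction reduces the contamination correlation
    expect_lt(abs(cor(corrected[base], d$neu[base])),
              abs(cor(d$roi[base], d$neu[base])))
  }
  x <- rnorm(200)
  expect_identical(neuropil_correct(x, rnorm(200), 0), x)
  expect_equal(neuropil_correct(x, x, 1), rep(0, 200))
})

test_that("trial response implements the windowed delta-F/F metric", {
  trace <- rep(1, 40)
  trace[19:22] <- 1.5    # response window for onset_frame = 11 (0-based)
  expect_equal(trial_response(trace, 11L), 0.5)
  expect_equal(trial_response(rep(2, 40), 11L), 0)
  trace2 <- rep(2, 40); trace2[19:22] <- 1
  expect_equal(trial_response(trace2, 11L), -0.5)

  ## scale invariance
  set.seed(6)
  tr <- runif(60, 0.5, 2)
  expect_equal(trial_response(tr, 20L), trial_response(5.3 * tr, 20L),
               tolerance = 1e-12)

  ## photostim frames are excluded from the windows
  trace3 <- rep(1, 40); trace3[19:22] <- 1.5
  trace3[19] <- 100    # artifact frame (0-based 18) inside response window
  expect_equal(trial_response(trace3, 11L, photostim_frames = 18L),
               mean(c(100, 1.5, 1.5, 1.5)[-1]) - 1, tolerance = 1e-12)
  expect_error(trial_response(trace, 2L), "range")
})

test_that("activity proxy is the smoothed positive derivative", {
  expect_equal(activity_proxy(rep(3, 100)), rep(0, 100))
  ramp <- activity_proxy(seq(0, 10, length.out = 100))
  expect_true(all(ramp[5:95] > 0))

  ## single step: proxy equals the Gaussian kernel centered at the step
  x <- c(rep(0, 50), rep(1, 49))
  p <- activity_proxy(x, frame_rate_hz = 7, sigma_s = 0.5)
  half <- ceiling(4 * 3.5)
  kern <- dnorm(seq(-half, half), sd = 3.5); kern <- kern / sum(kern)
  expect_equal(p[51 + (-10:10)], kern[half + 1 + (-10:10)], tolerance = 1e-10)
})

test_that("exclusion mask implements the target cylinder and edge band", {
  rois <- data.frame(
    roi_id = 1:5,
    x_um = c(300, 310, 320, 300, 300),
    y_um = c(300, 300, 300, 50, 200),
    plane = c(0L, 3L, 1L, 0L, 0L),
    z_um = c(0, 99.9, 33.3, 0, 0),
    is_target = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    included = TRUE)
  inc <- exclusion_mask(rois, radius_um = 15)
  expect_true(inc[1L])        # target retained
  expect_false(inc[2L])       # 10 um away, different plane: cylinder
  expect_true(inc[3L])        # 20 um away: outside radius
  expect_false(inc[4L])       # top edge band (100 rows * 710/512 = 138.7 um)
  expect_true(inc[5L])        # 200 um: below the band

  ## monotone: growing radius never re-includes a cell
  inc_big <- exclusion_mask(rois, radius_um = 40)
  expect_true(all(inc | !inc_big | rois$is_target))
})
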