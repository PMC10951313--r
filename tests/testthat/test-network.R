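test_that("hit:miss matching equalizes ratios and matches enumeration", {
  set.seed(1)
  ra <- c(rnorm(6, 1), rnorm(2, 0))    # 6 hits, 2 misses
  rb <- c(rnorm(3, 2), rnorm(4, 0.5))  # 3 hits, 4 misses
  ha <- rep(c(TRUE, FALSE), c(6, 2))
  hb <- rep(c(TRUE, FALSE), c(3, 4))

  m <- match_hit_miss(ra, rb, ha, hb, n_resamples = 4000L, seed = 2L)
  expect_equal(m$m_hit, 3L)
  expect_equal(m$m_miss, 2L)

  ## exhaustive enumeration oracle over all C(6,3)*C(2,2) x C(3,3)*C(4,2) draws
  enum_mean <- function(x, hit, m_h, m_m) {
    hits <- which(hit); miss <- which(!hit)
    ch <- combn(hits, m_h); cm <- combn(miss, m_m)
    tot <- 0; nn <- 0
    for (i in seq_len(ncol(ch))) for (j in seq_len(ncol(cm))) {
      tot <- tot + mean(x[c(ch[, i], cm[, j])]); nn <- nn + 1
    }
    tot / nn
  }
  ea <- enum_mean(ra, ha, 3, 2)
  eb <- enum_mean(rb, hb, 3, 2)
  ## Monte-Carlo SE of the resampled mean
  se <- sd(ra) / sqrt(4000)
  expect_lt(abs(m$mean_a - ea), 3 * se + 0.02)
  expect_lt(abs(m$mean_b - eb), 3 * se + 0.02)

  ## the exact (infinite-resample) limit equals the enumeration exactly
  mx <- match_hit_miss(ra, rb, ha, hb, n_resamples = Inf)
  expect_equal(mx$mean_a, ea, tolerance = 1e-12)
  expect_equal(mx$mean_b, eb, tolerance = 1e-12)
})

test_that("matching degenerate cases behave as stated", {
  x <- c(1, 2, 3, 4)
  ## identical trial sets: matched means equal plain means exactly
  m <- match_hit_miss(x, x, c(TRUE, TRUE, FALSE, FALSE),
                      c(TRUE, TRUE, FALSE, FALSE), n_resamples = Inf)
  expect_equal(m$mean_a, mean(x))
  expect_equal(m$mean_b, mean(x))
  ## all hits: no misses drawn
  m2 <- match_hit_miss(c(1, 3), c(5, 7, 9), c(TRUE, TRUE),
                       c(TRUE, TRUE, TRUE), n_resamples = Inf)
  expect_equal(m2$m_miss, 0L)
  expect_equal(m2$mean_a, 2)
  expect_equal(m2$mean_b, 7)
  ## nothing to match
  m3 <- match_hit_miss(1, 2, TRUE, FALSE, n_resamples = Inf)
  expect_true(is.na(m3$mean_a))
})

test_that("contrast curves and similarity follow their definitions", {
  resp <- c(0.1, 0.2, 0.15, 0.4, 0.35, 0.8)
  ctr <- c(1, 1, 2, 2, 5, 5)
  cc <- contrast_curve(resp, ctr, c(1, 2, 5, 10))
  expect_equal(cc, c(mean(resp[1:2]), mean(resp[3:4]), mean(resp[5:6]), NA))

  tc <- c(0, 0.1, 0.3, 0.5, 0.6)
  expect_equal(similarity_to_targets(tc, tc), 1)
  expect_equal(similarity_to_targets(mean(tc) - (tc - mean(tc)), tc), -1)
  a <- c(0.05, 0.1, 0.2, 0.5, 0.4)
  expect_equal(similarity_to_targets(a, tc), cor(a, tc))
  expect_true(is.na(similarity_to_targets(rep(1, 5), tc)))
})

test_that("stratified splitting partitions every stratum", {
  sa <- cached_analysis()
  pd <- optocoupling:::prepare_network_data(sa$responses, sa$trials,
                                            sa$states, sa$rois, test_acfg())
  all_idx <- sort(unlist(pd$strata))
  expect_equal(anyDuplicated(all_idx), 0L)
  ok <- sa$trials$outcome %in% c("hit", "miss") & sa$trials$contrast > 0 &
    !is.na(sa$states)
  expect_equal(all_idx, which(ok))
})

test_that("cross-validated similarity recovers the ground-truth structure", {
  b <- cached_session()
  sa <- cached_analysis()
  d <- crossval_similarity_delta(sa$responses, sa$trials, sa$states,
                                 sa$rois, test_acfg(), n_splits = 40L,
                                 seed = 5L)
  expect_gt(cor(d$similarity$r_sim, b$truth$sim, use = "complete.obs"), 0.9)
  expect_equal(dim(d$delta), c(21L, 5L, 3L))
  ## targets row: direct drive visible at every contrast
  expect_true(all(d$delta["targets", , "pooled"] > 0.4))
  ## determinism
  d2 <- crossval_similarity_delta(sa$responses, sa$trials, sa$states,
                                  sa$rois, test_acfg(), n_splits = 40L,
                                  seed = 5L)
  expect_identical(d$delta, d2$delta)
})

test_that("suppression slopes are exact on noiseless constructed input", {
  nb <- 20L
  contrasts <- c(1, 2, 5, 10, 100)
  mk_delta <- function(slope_top) {
    delta <- array(0, dim = c(nb + 1L, 5L, 3L),
                   dimnames = list(c(paste0("bin", 1:nb), "targets"),
                                   contrasts,
                                   c("more_engaged", "less_engaged", "pooled")))
    normsim <- (seq_len(nb) - 0.5) / nb
    for (bi in seq_len(nb))
      delta[bi, , ] <- slope_top * normsim[bi] / max(normsim) *
        log10(contrasts)
    structure(list(delta = delta, split_var = delta * 0,
                   n_cells = rep(5, nb),
                   similarity = NULL, contrasts = contrasts, n_bins = nb,
                   n_splits = 1L), class = "oc_delta")
  }
  deltas <- list(mk_delta(-0.002), mk_delta(-0.002))
  ss <- suppression_slope(deltas, n_boot = 20L, seed = 1L)
  expect_equal(ss$per_bin$slope[nb], -0.002, tolerance = 1e-9)
  ## across-bin fit: per-bin slope is linear in normalized similarity
  expect_equal(ss$fit$slope, -0.002 / max((seq_len(nb) - 0.5) / nb),
               tolerance = 1e-9)
  expect_equal(ss$fit$se, 0, tolerance = 1e-12)  # identical sessions

  zero <- list(mk_delta(0), mk_delta(0))
  s0 <- suppression_slope(zero, n_boot = 5L, seed = 1L)
  expect_equal(s0$per_bin$slope, rep(0, nb), tolerance = 1e-12)
  expect_equal(s0$fit$slope, 0, tolerance = 1e-12)
})

test_that("spatial binning places offsets correctly and flat fields stay flat", {
  rois <- data.frame(roi_id = 1:2, x_um = c(300, 312), y_um = c(300, 303),
                     plane = 0L, z_um = 0,
                     is_target = c(TRUE, FALSE), included = TRUE)
  tr <- mk_trials(c(0, 0, 0, 0), replicate(4, numeric(), simplify = FALSE),
                  photostim = c(TRUE, TRUE, FALSE, FALSE))
  tr <- classify_outcomes(tr)
  resp <- rbind(c(1, 0.9), c(1.1, 0.8), c(0.1, 0.2), c(0.12, 0.18))
  sp <- spatial_influence_profile(resp, tr, rois, max_um = 50)
  ## cell 2 offset (12, 3): x bin (10,15], y bin (0,5]
  breaks <- seq(-50, 50, by = 5)
  bx <- findInterval(12, breaks, rightmost.closed = TRUE)
  by <- findInterval(3, breaks, rightmost.closed = TRUE)
  d2 <- mean(resp[1:2, 2]) - mean(resp[3:4, 2])
  expect_equal(sp$map[by, bx], d2)
  ## 1D: cell 2 at r = sqrt(153) ~ 12.4 -> annulus (10, 15]
  expect_equal(sp$profile$mean_delta[3L], d2)
  expect_equal(sp$profile$n_cells[1L], 1L)  # the target itself at r = 0

  ## constant field: flat profile
  respc <- rbind(c(1, 1), c(1, 1), c(0.5, 0.5), c(0.5, 0.5))
  spc <- spatial_influence_profile(respc, tr, rois, max_um = 50)
  vals <- spc$profile$mean_delta[spc$profile$n_cells > 0]
  expect_equal(vals, rep(0.5, length(vals)))
})

test_that("the generator's center-surround kernel shows up in the profile", {
  b <- cached_session()
  sa <- cached_analysis()
  sp <- spatial_influence_profile(sa$responses, sa$trials, sa$rois)
  near <- sp$profile$r_hi <= 15
  far <- sp$profile$r_lo >= 20 & sp$profile$r_hi <= 100
  expect_gt(sum(sp$profile$n_cells[near] * sp$profile$mean_delta[near],
                na.rm = TRUE) /
              max(sum(sp$profile$n_cells[near]), 1), 0.1)
  expect_lt(sum(sp$profile$n_cells[far] * sp$profile$mean_delta[far],
                na.rm = TRUE) /
              max(sum(sp$profile$n_cells[far]), 1), 0)
})
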