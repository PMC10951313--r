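## Hand-built delta objects: two sessions, values fully controlled.
mk_coupling_fixture <- function(slope_r = 1, n_sessions = 4L, noise = 0,
                                seed = 1L) {
  set.seed(seed)
  nb <- 20L
  contrasts <- c(1, 2, 5, 10, 100)
  normsim <- (seq_len(nb) - 0.5) / nb
  deltas <- list()
  beh_rows <- list()
  for (i in seq_len(n_sessions)) {
    delta <- array(NA_real_, dim = c(nb + 1L, 5L, 3L),
                   dimnames = list(c(paste0("bin", 1:nb), "targets"),
                                   contrasts,
                                   c("more_engaged", "less_engaged", "pooled")))
    y <- rnorm(3)   # session ddprime at contrasts 2, 5, 10
    for (s in 1:3) for (b in seq_len(nb + 1L))
      delta[b, 2:4, s] <- 2 * y + noise * rnorm(3)
    deltas[[i]] <- structure(
      list(delta = delta, split_var = delta * 0, n_cells = rep(5, nb),
           similarity = NULL, contrasts = contrasts, n_bins = nb,
           n_splits = 1L), class = "oc_delta")
    for (s in c("more_engaged", "less_engaged"))
      beh_rows[[paste(i, s)]] <- data.frame(session = i, state = s,
                                            contrast = c(2, 5, 10),
                                            ddprime = y)
  }
  list(deltas = deltas, beh = do.call(rbind, beh_rows))
}

test_that("behavior delta reports only intermediate contrasts", {
  sa <- cached_analysis()
  tab <- summarize_behavior(sa$trials, sa$states, test_acfg())$table
  bd <- behavior_delta(list(tab))
  expect_setequal(unique(bd$contrast), c(2, 5, 10))
  expect_false(any(bd$contrast %in% c(1, 100)))

  ## identical performance with and without stimulation: delta d' = 0
  tab0 <- tab
  tab0$dprime <- 1.3
  bd0 <- behavior_delta(list(tab0))
  expect_equal(bd0$ddprime, rep(0, nrow(bd0)))
})

test_that("per-bin coupling is the pooled Pearson correlation", {
  fx <- mk_coupling_fixture()
  r <- coupling_by_bin(fx$deltas, fx$beh, "more_engaged")
  ## delta = 2 * ddprime exactly -> r = 1 in every bin
  expect_equal(unname(r[1:20]), rep(1, 20))
  sl <- coupling_slope(r, 20L)
  expect_equal(sl[["slope"]], 0)   # constant coupling across bins

  ## exact linear relation across bins
  nb <- 20L
  normsim <- (seq_len(nb) - 0.5) / nb
  r2 <- c(0.5 * normsim, 0.9)
  expect_equal(coupling_slope(r2, nb)[["slope"]], 0.5, tolerance = 1e-12)
  ## the target point is excluded from the fit
  r3 <- c(0.5 * normsim, -5)
  expect_equal(coupling_slope(r3, nb)[["slope"]], 0.5, tolerance = 1e-12)

  ## too few populated bins
  r4 <- c(rep(NA, 16), 0.1, 0.2, 0.3, 0.4, 0.5)
  expect_true(is.na(coupling_slope(r4, nb)[["slope"]]))
})

test_that("bins with fewer than 3 points or no variance are flagged", {
  fx <- mk_coupling_fixture(n_sessions = 4L)
  ## knock a bin down to 2 points
  for (i in 2:4) fx$deltas[[i]]$delta[7L, , ] <- NA
  fx$deltas[[1L]]$delta[7L, 3L, ] <- NA
  r <- coupling_by_bin(fx$deltas, fx$beh, "more_engaged")
  expect_true(is.na(r[7L]))
})

test_that("session bootstrap degenerates correctly", {
  fx <- mk_coupling_fixture(n_sessions = 3L, noise = 0.4)
  ## a single session resampled with replacement never varies
  one <- bootstrap_coupling(fx$deltas[1L], fx$beh[fx$beh$session == 1, ],
                            "more_engaged", n_boot = 20L, seed = 2L)
  expect_true(is.na(one$se_slope) || one$se_slope == 0)

  b1 <- bootstrap_coupling(fx$deltas, fx$beh, "more_engaged", n_boot = 1L,
                           seed = 3L)
  expect_equal(b1$mean_slope, b1$slopes[1L])

  bb <- bootstrap_coupling(fx$deltas, fx$beh, "more_engaged", n_boot = 50L,
                           seed = 4L)
  expect_gte(bb$se_slope, 0)
  expect_length(bb$slopes, 50L)
})

test_that("the shuffle permutes contrast labels without altering the data", {
  ## block permutation of the contrast axis: the identity permutation
  ## reproduces the observed slope exactly, and every permutation only
  ## reorders columns (multisets of values preserved)
  set.seed(5)
  nb <- 20L
  X <- array(rnorm((nb + 1L) * 3 * 4), dim = c(nb + 1L, 3L, 4L))
  Y <- matrix(rnorm(12), 3L, 4L)
  idp <- replicate(4, 1:3, simplify = FALSE)
  s_obs <- optocoupling:::slope_from_tables(X, Y, nb)
  expect_identical(optocoupling:::slope_from_tables(X, Y, nb, idp, idp),
                   s_obs)
  pm <- replicate(4, sample(3L), simplify = FALSE)
  Xp <- X
  for (i in 1:4) Xp[, , i] <- Xp[, pm[[i]], i]
  for (i in 1:4) expect_setequal(Xp[5, , i], X[5, , i])
  ## a common permutation of both coordinates leaves the slope unchanged
  expect_equal(optocoupling:::slope_from_tables(X, Y, nb, pm, pm),
               optocoupling:::slope_from_tables(
                 Xp, do.call(cbind, lapply(1:4, function(i) Y[pm[[i]], i])),
                 nb),
               tolerance = 1e-12)
})

test_that("shuffle null is reproducible and p-values respect the floor", {
  sa <- cached_analysis()
  sess <- list(
    list(responses = sa$responses, trials = sa$trials, states = sa$states,
         rois = sa$rois),
    list(responses = sa$responses, trials = sa$trials, states = sa$states,
         rois = sa$rois))
  acfg <- test_acfg()
  sn1 <- shuffle_null(sess, acfg, n_shuffle = 12L, seed = 6L)
  sn2 <- shuffle_null(sess, acfg, n_shuffle = 12L, seed = 6L)
  expect_identical(sn1$more_engaged$null, sn2$more_engaged$null)
  for (s in names(sn1)) {
    p <- sn1[[s]]$p_value
    expect_gte(p, 1 / 13)
    expect_lte(p, 1)
  }
  expect_error(shuffle_null(sess[1L], acfg), "2")
})
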