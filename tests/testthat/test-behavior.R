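test_that("outcome classification follows the response and early-lick windows", {
  tr <- mk_trials(c(5, 5, 0, 0, 2, 100),
                  list(0.5, 0.1, numeric(), 1.0, numeric(), c(0.2, 1.6)))
  out <- classify_outcomes(tr)
  expect_identical(out$outcome,
                   c("hit", "excluded", "correct_rejection", "false_alarm",
                     "miss", "hit"))
  expect_identical(out$exclusion_reason[2L], "early_lick")
  ## boundary: a lick exactly at 150 ms counts as early
  out2 <- classify_outcomes(mk_trials(5, list(0.15)))
  expect_identical(out2$outcome, "excluded")
  ## lick after the window is not a hit
  out3 <- classify_outcomes(mk_trials(5, list(1.6)))
  expect_identical(out3$outcome, "miss")
})

test_that("session truncation follows the rolling easy-trial rule", {
  mk_easy <- function(outcomes) {
    n <- length(outcomes)
    tr <- mk_trials(rep(100, n), replicate(n, numeric(), simplify = FALSE))
    tr$outcome <- outcomes
    tr
  }
  ## all hits: never truncated
  tr <- truncate_session(mk_easy(rep("hit", 40)))
  expect_true(all(tr$outcome == "hit"))

  ## 30 hits then 20 misses: brute-force rolling oracle in the test
  outcomes <- c(rep("hit", 30), rep("miss", 20))
  hits <- as.numeric(outcomes == "hit")
  roll <- stats::filter(hits, rep(1 / 20, 20), sides = 1)
  cut_oracle <- which(!is.na(roll) & roll < 0.8 * roll[20])[1L]
  tr2 <- truncate_session(mk_easy(outcomes))
  expect_equal(attr(tr2, "truncated_at"), cut_oracle)
  expect_true(all(tr2$exclusion_reason[(cut_oracle + 1):50] == "truncated"))
  expect_true(all(tr2$exclusion_reason[1:cut_oracle] == "none"))

  ## alternating: rolling stays at the starting level, no truncation
  tr3 <- truncate_session(mk_easy(rep(c("hit", "miss"), 25)))
  expect_true(is.na(attr(tr3, "truncated_at")))

  expect_warning(truncate_session(mk_easy(rep("hit", 10))), "window")
})

test_that("target-failure exclusions use the >50% rule and 10-trial validity", {
  tr <- classify_outcomes(mk_trials(rep(c(5, 0), each = 2),
                                    list(0.5, 0.5, numeric(), numeric()),
                                    photostim = c(TRUE, TRUE, FALSE, FALSE)))
  ## 20 targets: 11 responding = 45% failed -> kept; 9 = 55% failed -> excluded
  resp <- matrix(0.05, nrow = 4, ncol = 20)
  resp[1, 1:11] <- 0.5
  resp[2, 1:9] <- 0.5
  out <- apply_trial_exclusions(tr, resp)
  expect_identical(out$outcome[1L], "hit")
  expect_identical(out$exclusion_reason[2L], "target_failure")
  expect_false(attr(out, "session_valid"))  # types have < 10 trials here
})

test_that("d-prime matches an independent normal-quantile oracle", {
  oracle <- function(h, ngo, f, nc) {
    clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    qnorm(clip(h / ngo, ngo)) - qnorm(clip(f / nc, nc))
  }
  expect_equal(dprime(10, 20, 10, 20), 0)
  expect_equal(dprime(16, 20, 4, 20), qnorm(0.8) - qnorm(0.2),
               tolerance = 1e-12)
  expect_equal(dprime(16, 20, 4, 20), 1.6832, tolerance = 1e-4)
  expect_equal(dprime(20, 20, 0, 20), qnorm(0.975) - qnorm(0.025),
               tolerance = 1e-12)
  expect_equal(dprime(20, 20, 0, 20), 3.9199, tolerance = 1e-4)
  for (h in c(0, 3, 11, 20)) for (f in c(0, 2, 9, 15)) {
    expect_equal(dprime(h, 20, f, 15), oracle(h, 20, f, 15),
                 tolerance = 1e-9)
    ## antisymmetry under swapping hits and false alarms
    expect_equal(dprime(h, 20, f, 15), -dprime(f, 15, h, 20),
                 tolerance = 1e-9)
  }
})

test_that("Weibull threshold and width have the stated closed forms", {
  tw <- weibull_threshold_width(5, 3)
  expect_equal(tw[["threshold"]], 5 * log(2)^(1 / 3), tolerance = 1e-12)
  expect_equal(tw[["threshold"]], 4.42498, tolerance = 1e-4)
  expect_equal(tw[["width"]],
               5 * ((-log(0.05))^(1 / 3) - (-log(0.95))^(1 / 3)),
               tolerance = 1e-12)
  expect_equal(tw[["width"]], 5.35017, tolerance = 1e-4)
  ## asymptote: W -> 1 as c -> Inf with gamma = lambda = 0
  expect_equal(weibull_performance(1e6, 5, 3, 0, 0), 1)
})

test_that("the fitter recovers exact parameters from noiseless rates", {
  contrasts <- c(1, 2, 5, 10, 100)
  w <- weibull_performance(contrasts, 5, 3, 0, 0)
  fit <- fit_weibull(contrasts, n_go = rep(200, 5), n_hit = 200 * w,
                     gamma = 0, lambda = 0)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 5, tolerance = 1e-6)
  expect_equal(fit$beta, 3, tolerance = 1e-6)
  expect_equal(fit$threshold, 5 * log(2)^(1 / 3), tolerance = 1e-6)
  expect_equal(fit$width,
               5 * ((-log(0.05))^(1 / 3) - (-log(0.95))^(1 / 3)),
               tolerance = 1e-6)
})

test_that("the fit is equivariant under contrast rescaling", {
  set.seed(9)
  contrasts <- c(1, 2, 5, 10, 100)
  w <- weibull_performance(contrasts, 4, 2, 0.1, 0.02)
  n_hit <- rbinom(5, 100, w)
  f1 <- fit_weibull(contrasts, rep(100, 5), n_hit, gamma = 0.1,
                    lambda = 0.02)
  f2 <- fit_weibull(3 * contrasts, rep(100, 5), n_hit, gamma = 0.1,
                    lambda = 0.02)
  expect_equal(f2$alpha / f1$alpha, 3, tolerance = 1e-3)
  expect_equal(f2$threshold / f1$threshold, 3, tolerance = 1e-3)
  expect_equal(f2$width / f1$width, 3, tolerance = 1e-3)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-3)
})

test_that("parameter recovery from binomial draws is accurate", {
  set.seed(11)
  contrasts <- c(1, 2, 5, 10, 100)
  errs_a <- errs_b <- numeric(15)
  for (i in 1:15) {
    w <- weibull_performance(contrasts, 5, 3, 0.1, 0.02)
    n_hit <- rbinom(5, 200, w)
    f <- fit_weibull(contrasts, rep(200, 5), n_hit, gamma = 0.1,
                     lambda = 0.02)
    errs_a[i] <- abs(f$alpha - 5) / 5
    errs_b[i] <- abs(f$beta - 3) / 3
  }
  expect_lt(median(errs_a), 0.1)
  expect_lt(median(errs_b), 0.2)
})

test_that("behavioral summaries are deterministic and respect missing cells", {
  b <- cached_session()
  sa <- cached_analysis()
  s1 <- summarize_behavior(sa$trials, sa$states, test_acfg())
  s2 <- summarize_behavior(sa$trials, sa$states, test_acfg())
  expect_identical(s1$table, s2$table)
  expect_true(all(c("state", "photostim", "contrast", "dprime",
                    "width") %in% names(s1$table)))
  expect_setequal(unique(s1$table$state), c("more_engaged", "less_engaged"))

  ## a condition with zero trials yields NA, not zero
  tr <- sa$trials[sa$trials$contrast != 2 | !sa$trials$photostim, ]
  st <- sa$states[sa$trials$contrast != 2 | !sa$trials$photostim]
  s3 <- summarize_behavior(tr, st, test_acfg())
  gap <- s3$table[s3$table$contrast == 2 & s3$table$photostim, ]
  expect_true(all(is.na(gap$hit_rate)))
})
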