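# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed
#'
#' All stochastic stages draw their seeds from a master seed through this
#' mixing function, so adding a session (or running stages in a different
#' order) never perturbs another stage's draws. The result is always a valid
#' 32-bit integer seed.
#'
#' @param seed master integer seed.
#' @param stage character stage label (hashed into the stream).
#' @param k integer counter within the stage (e.g. session index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(seed)) * 48271 + (h %% 100003) * 7919 +
                as.numeric(k) * 104729 + 12345) %% 2147483629)
}

## Gaussian smoothing of a vector, edge-replicated so the output has the same
## length as the input.
smooth_gaussian <- function(x, sigma_frames) {
  n <- length(x)
  if (sigma_frames <= 0 || n < 2L) return(x)
  half <- max(1L, as.integer(ceiling(4 * sigma_frames)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_frames)
  kern <- kern / sum(kern)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  out <- stats::filter(xp, kern, sides = 2)
  as.numeric(out)[(half + 1L):(half + n)]
}

## Row-wise Gaussian smoothing of a cells x frames matrix.
smooth_gaussian_rows <- function(m, sigma_frames) {
  if (sigma_frames <= 0) return(m)
  half <- max(1L, as.integer(ceiling(4 * sigma_frames)))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_frames)
  kern <- kern / sum(kern)
  n <- ncol(m)
  xp <- cbind(m[, rep(1L, half), drop = FALSE], m, m[, rep(n, half), drop = FALSE])
  out <- stats::filter(t(xp), kern, sides = 2)
  t(as.matrix(out))[, (half + 1L):(half + n), drop = FALSE]
}

## First-order recursive (exponential) filter along the frame axis of a
## cells x frames matrix: y_t = a * y_{t-1} + (1 - a) * x_t.
exp_filter_rows <- function(m, a) {
  x <- t(m) * (1 - a)
  y <- stats::filter(x, filter = a, method = "recursive", sides = 1)
  t(as.matrix(y))
}

## AR(1) noise with autocorrelation coefficient a and unit stationary variance.
ar1_noise <- function(n, a) {
  innov <- stats::rnorm(n, sd = sqrt(1 - a^2))
  as.numeric(stats::filter(innov, filter = a, method = "recursive", sides = 1))
}

## k independent AR(1) rows (k x n matrix), single filter pass.
ar1_noise_rows <- function(k, n, a) {
  innov <- matrix(stats::rnorm(k * n, sd = sqrt(1 - a^2)), nrow = n)
  t(as.matrix(stats::filter(innov, filter = a, method = "recursive", sides = 1)))
}

## Pearson correlation of every row of `m` with vector `v`; rows (or `v`)
## with zero variance give NA.
row_cor <- function(m, v) {
  mc <- m - rowMeans(m)
  vc <- v - mean(v)
  den <- sqrt(rowSums(mc^2) * sum(vc^2))
  r <- as.numeric(mc %*% vc) / den
  r[!is.finite(r)] <- NA_real_
  r
}

## Mean of all unordered pairwise Pearson correlations between rows of `w`
## (cells x frames window). Rows with zero variance are excluded.
mean_pairwise_cor <- function(w) {
  n <- ncol(w)
  mu <- rowMeans(w)
  ss <- rowSums(w * w) - n * mu * mu
  keep <- is.finite(ss) & ss > 1e-24
  if (sum(keep) < 2L) return(NA_real_)
  z <- (w[keep, , drop = FALSE] - mu[keep]) / sqrt(ss[keep])
  k <- nrow(z)
  cc <- tcrossprod(z)
  (sum(cc) - sum(diag(cc))) / (k * (k - 1L))
}

## Ordinary least squares slope/intercept with optional weights; returns
## c(intercept, slope). Requires >= 2 distinct x.
ols_fit <- function(x, y, w = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(w)) ok <- ok & is.finite(w) & w > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0) return(c(NA_real_, NA_real_))
  w <- if (is.null(w)) rep(1, length(x)) else w[ok]
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  b1 <- sum(w * (x - mx) * (y - my)) / sum(w * (x - mx)^2)
  c(my - b1 * mx, b1)
}

## Simple FNV-1a string hash (hex), used for config digests in manifests.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## Largest-remainder apportionment of n into parts proportional to p.
apportion <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}
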