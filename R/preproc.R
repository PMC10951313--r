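#' Estimate the neuropil contamination coefficient
#'
#' Robust linear regression of the ROI trace on the neuropil trace. The
#' default estimator is iteratively reweighted least squares with Tukey
#' bisquare weights (tuning constant 4.685), which downweights the cell's own
#' transients so the slope reflects only the shared contamination; a
#' Theil-Sen alternative is available. The slope is clipped to `[0, 2]`.
#'
#' @param f_roi_trace,f_neu_trace equal-length traces (>= 100 frames).
#' @param estimator `"irls"` or `"theil_sen"`.
#' @param c_tune bisquare tuning constant.
#' @return scalar slope in `[0, 2]`.
#' @export
estimate_neuropil_coefficient <- function(f_roi_trace, f_neu_trace,
                                          estimator = c("irls", "theil_sen"),
                                          c_tune = 4.685) {
  stopifnot(length(f_roi_trace) == length(f_neu_trace),
            length(f_roi_trace) >= 100L)
  if (stats::sd(f_neu_trace) == 0)
    stop("neuropil trace is constant; contamination slope undefined",
         call. = FALSE)
  estimator <- match.arg(estimator)
  slope <- if (estimator == "irls") {
    irls_bisquare(f_roi_trace, f_neu_trace, c_tune = c_tune)[2L]
  } else {
    theil_sen_slope(f_roi_trace, f_neu_trace)
  }
  min(max(slope, 0), 2)
}

## IRLS with bisquare weights; returns c(intercept, slope). Starts from OLS,
## rescales residuals by the MAD each iteration.
irls_bisquare <- function(y, x, c_tune = 4.685, max_iter = 30L, tol = 1e-6) {
  w <- rep(1, length(y))
  b_prev <- c(Inf, Inf)
  b <- c(0, 0)
  for (iter in seq_len(max_iter)) {
    sw <- sum(w)
    mx <- sum(w * x) / sw
    my <- sum(w * y) / sw
    xc <- x - mx
    den <- sum(w * xc * xc)
    if (den <= 0) break
    b1 <- sum(w * xc * (y - my)) / den
    b <- c(my - b1 * mx, b1)
    if (max(abs(b - b_prev)) < tol * max(1, abs(b[2L]))) break
    b_prev <- b
    r <- y - b[1L] - b[2L] * x
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s <= 0) s <- mean(abs(r)) / 0.7979
    if (s <= 0) break
    u <- abs(r) / (c_tune * s)
    w <- ifelse(u < 1, (1 - u^2)^2, 0)
  }
  b
}

## Median of slopes over random point pairs (subsampled Theil-Sen).
theil_sen_slope <- function(y, x, n_pairs = 20000L) {
  n <- length(x)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n, n_pairs, replace = TRUE)
  keep <- x[i] != x[j]
  stats::median((y[i] - y[j])[keep] / (x[i] - x[j])[keep])
}

#' Subtract scaled neuropil from an ROI trace
#'
#' `corrected = roi - slope * neuropil`. With the slope estimated on the same
#' data the corrected baseline is uncorrelated with the neuropil.
#'
#' @param f_roi_trace,f_neu_trace equal-length traces.
#' @param slope contamination coefficient.
#' @return corrected trace.
#' @export
neuropil_correct <- function(f_roi_trace, f_neu_trace, slope) {
  stopifnot(is.finite(slope))
  f_roi_trace - slope * f_neu_trace
}

#' Neuropil-correct every cell of a session
#'
#' Estimates each ROI's contamination coefficient and returns the corrected
#' cells x frames matrix with the per-cell slopes as an attribute.
#'
#' @param bundle an `oc_session`.
#' @param acfg an [analysis_config()].
#' @return corrected matrix with attribute `neuropil_slopes`.
#' @export
correct_session <- function(bundle, acfg = analysis_config()) {
  nc <- nrow(bundle$f_roi)
  sub <- seq(1L, ncol(bundle$f_roi), by = max(1L, acfg$neuropil_stride))
  slopes <- vapply(seq_len(nc), function(i)
    estimate_neuropil_coefficient(bundle$f_roi[i, sub],
                                  bundle$f_neuropil[i, sub],
                                  estimator = acfg$robust_estimator),
    numeric(1L))
  corrected <- bundle$f_roi - slopes * bundle$f_neuropil
  attr(corrected, "neuropil_slopes") <- slopes
  corrected
}

## R (1-based) column indices of the baseline window: the `n_back` frames
## before a 0-based onset frame.
pretrial_idx <- function(onset_frame, n_back) {
  (onset_frame - n_back + 1L):onset_frame
}

#' Trial response metric (windowed delta-F/F)
#'
#' Mean fluorescence in a ~500 ms (4-frame) window starting immediately after
#' stimulus/photostimulation offset, minus the mean of the ~1 s (7-frame)
#' pre-onset baseline, divided by the baseline mean. Photostimulation-artifact
#' frames never enter either window. Scale-free: multiplying the trace by a
#' positive constant leaves the value unchanged.
#'
#' @param trace one cell's (corrected) fluorescence trace.
#' @param onset_frame 0-based stimulus onset frame.
#' @param stim_frames stimulus duration in frames.
#' @param photostim_frames 0-based artifact frames.
#' @param baseline_frames,response_frames window lengths.
#' @return scalar delta-F/F; `NA` with a warning condition if the baseline
#'   mean is not positive.
#' @export
trial_response <- function(trace, onset_frame, stim_frames = 7L,
                           photostim_frames = integer(),
                           baseline_frames = 7L, response_frames = 4L) {
  base_i <- pretrial_idx(onset_frame, baseline_frames)
  resp_i <- (onset_frame + stim_frames + 1L):(onset_frame + stim_frames + response_frames)
  if (min(base_i) < 1L || max(resp_i) > length(trace))
    stop("response windows out of trace range", call. = FALSE)
  ps <- photostim_frames + 1L
  base_i <- setdiff(base_i, ps)
  resp_i <- setdiff(resp_i, ps)
  mb <- mean(trace[base_i])
  if (!is.finite(mb) || mb <= 0) return(NA_real_)
  (mean(trace[resp_i]) - mb) / mb
}

#' Trial-by-cell response table
#'
#' Applies the windowed delta-F/F metric to every (trial, cell) pair of a
#' session. Cells whose baseline mean is nonpositive on a trial get `NA`
#' there (flagged, not dropped).
#'
#' @param corrected cells x frames corrected fluorescence.
#' @param bundle the `oc_session` providing trials and artifact frames.
#' @param acfg an [analysis_config()].
#' @return trials x cells matrix of delta-F/F values.
#' @export
response_table <- function(corrected, bundle, acfg = analysis_config()) {
  stim_frames <- as.integer(round(bundle$frame_rate_hz))
  ps <- bundle$photostim_frames + 1L
  n_tr <- nrow(bundle$trials)
  n_f <- ncol(corrected)
  base_idx <- lapply(bundle$trials$onset_frame, function(f0)
    setdiff(pretrial_idx(f0, acfg$baseline_frames), ps))
  resp_idx <- lapply(bundle$trials$onset_frame, function(f0)
    setdiff((f0 + stim_frames + 1L):(f0 + stim_frames + acfg$response_frames),
            ps))
  grp <- integer(n_f)
  grp[unlist(base_idx)] <- rep.int(seq_len(n_tr),
                                   lengths(base_idx))
  grp[unlist(resp_idx)] <- rep.int(seq_len(n_tr) + n_tr,
                                   lengths(resp_idx))
  overlap <- anyDuplicated(c(unlist(base_idx), unlist(resp_idx))) > 0L
  if (!overlap) {
    ## windows are disjoint: one grouped-sum pass over the frame axis
    keep <- grp > 0L
    sums <- rowsum(t(corrected[, keep, drop = FALSE]), grp[keep])
    rows <- as.integer(rownames(sums))
    mb <- mr <- matrix(NA_real_, n_tr, nrow(corrected))
    nb <- lengths(base_idx); nr <- lengths(resp_idx)
    bsel <- rows <= n_tr
    mb[rows[bsel], ] <- sums[bsel, , drop = FALSE] / nb[rows[bsel]]
    mr[rows[!bsel] - n_tr, ] <- sums[!bsel, , drop = FALSE] /
      nr[rows[!bsel] - n_tr]
    out <- (mr - mb) / mb
    out[!is.finite(out) | mb <= 0] <- NA_real_
  } else {
    out <- matrix(NA_real_, n_tr, nrow(corrected))
    for (t in seq_len(n_tr)) {
      mb <- rowMeans(corrected[, base_idx[[t]], drop = FALSE])
      mr <- rowMeans(corrected[, resp_idx[[t]], drop = FALSE])
      v <- (mr - mb) / mb
      v[!is.finite(v) | mb <= 0] <- NA_real_
      out[t, ] <- v
    }
  }
  dimnames(out) <- list(NULL, bundle$rois$roi_id)
  out
}

#' Activity proxy for synchrony measurement
#'
#' A fast-timescale activity estimate standing in for spike-deconvolved
#' traces: the positive part of the first difference of the corrected trace,
#' smoothed with a Gaussian filter (sigma in seconds, default 0.5 s). Same
#' length as the input (edge-padded).
#'
#' @param corrected one trace, or a cells x frames matrix.
#' @param frame_rate_hz frame rate.
#' @param sigma_s Gaussian smoothing width in seconds.
#' @return nonnegative proxy trace(s), same shape as the input.
#' @export
activity_proxy <- function(corrected, frame_rate_hz = 7, sigma_s = 0.5) {
  sigma_f <- sigma_s * frame_rate_hz
  if (is.matrix(corrected)) {
    d <- cbind(0, pmax(t(diff(t(corrected))), 0))
    return(smooth_gaussian_rows(d, sigma_f))
  }
  d <- c(0, pmax(diff(corrected), 0))
  smooth_gaussian(d, sigma_f)
}

#' Session-level activity proxies for synchrony
#'
#' Applies [activity_proxy()] to every cell after masking stimulus and
#' photostimulation frames (their first-difference contribution is zeroed
#' before smoothing). The pre-trial synchrony window ends immediately before
#' trial onset while the Gaussian smoothing kernel is symmetric, so without
#' masking, evoked transients would bleed backwards into the window and
#' couple the state index to the upcoming trial's type.
#'
#' @param corrected cells x frames corrected fluorescence.
#' @param bundle the `oc_session` (provides onsets and artifact frames).
#' @param acfg an [analysis_config()].
#' @param cells optional row subset to compute proxies for.
#' @return proxies matrix (length(cells) x frames).
#' @export
session_activity_proxy <- function(corrected, bundle,
                                   acfg = analysis_config(),
                                   cells = seq_len(nrow(corrected))) {
  rate <- bundle$frame_rate_hz
  stim_frames <- as.integer(round(rate))
  evoked <- unlist(lapply(bundle$trials$onset_frame, function(f)
    (f + 1L):(f + stim_frames)))
  evoked <- unique(c(evoked, bundle$photostim_frames + 1L))
  evoked <- evoked[evoked >= 1L & evoked <= ncol(corrected)]
  d <- cbind(0, pmax(t(diff(t(corrected[cells, , drop = FALSE]))), 0))
  d[, evoked] <- 0
  smooth_gaussian_rows(d, acfg$sigma_s * rate)
}

#' Spatial exclusion mask around photostimulation targets
#'
#' Excludes every non-target cell whose lateral distance to any target is
#' below `radius_um` (a 30 um diameter cylinder through all planes) and every
#' cell in the top edge band of the frame (the first `edge_rows` pixel rows,
#' converted to microns via the field-of-view/pixel ratio). Targets are
#' retained and flagged separately. Monotone: growing the radius never
#' re-includes a cell.
#'
#' @param rois ROI table.
#' @param radius_um lateral exclusion radius.
#' @param edge_rows excluded pixel rows at the top of the frame.
#' @param fov_um,image_px frame geometry for the row-to-micron conversion.
#' @return logical inclusion vector (TRUE = analysable background cell or
#'   target; attribute `is_target` marks the targets).
#' @export
exclusion_mask <- function(rois, radius_um = 15, edge_rows = 100L,
                           fov_um = 710, image_px = 512L) {
  targets <- which(rois$is_target)
  if (length(targets) == 0L) stop("no target ROIs", call. = FALSE)
  dx <- outer(rois$x_um, rois$x_um[targets], "-")
  dy <- outer(rois$y_um, rois$y_um[targets], "-")
  dmin <- sqrt(apply(dx^2 + dy^2, 1L, min))
  edge_um <- edge_rows * fov_um / image_px
  included <- !(dmin < radius_um) & rois$y_um >= edge_um
  included[targets] <- rois$y_um[targets] >= edge_um
  attr(included, "is_target") <- rois$is_target
  included
}
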