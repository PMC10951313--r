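#' Hit:miss ratio-matched condition means
#'
#' Equalizes the proportion of lick (hit) to no-lick (miss) trials across two
#' compared conditions before averaging, removing motor/reward confounds.
#' With `m_h = min(hits_A, hits_B)` and `m_m = min(miss_A, miss_B)`, each
#' resample draws `m_h` hits and `m_m` misses without replacement from each
#' condition and averages them; the reported means average over resamples, so
#' both conditions reflect the identical hit fraction `m_h / (m_h + m_m)`.
#' `n_resamples = Inf` returns the exact infinite-resample limit (each hit
#' weighted `m_h / n_hits`, each miss `m_m / n_miss`), which the resampled
#' estimate converges to.
#'
#' @param responses_a,responses_b per-trial responses (vector, or trials x
#'   cells matrix) for the two conditions.
#' @param hit_a,hit_b logical lick labels per trial.
#' @param n_resamples resample count (or `Inf` for the exact limit).
#' @param seed integer seed (ignored when exact).
#' @return list with `mean_a`, `mean_b` (scalar or per-cell), `m_hit`,
#'   `m_miss`.
#' @export
match_hit_miss <- function(responses_a, responses_b, hit_a, hit_b,
                           n_resamples = 10000L, seed = 1L) {
  ra <- if (is.matrix(responses_a)) responses_a else matrix(responses_a, ncol = 1L)
  rb <- if (is.matrix(responses_b)) responses_b else matrix(responses_b, ncol = 1L)
  stopifnot(nrow(ra) == length(hit_a), nrow(rb) == length(hit_b))
  m_h <- min(sum(hit_a), sum(hit_b))
  m_m <- min(sum(!hit_a), sum(!hit_b))
  if (m_h + m_m == 0L)
    return(list(mean_a = rep(NA_real_, ncol(ra)),
                mean_b = rep(NA_real_, ncol(rb)), m_hit = 0L, m_miss = 0L))
  if (is.infinite(n_resamples)) {
    wa <- match_weights(hit_a, m_h, m_m)
    wb <- match_weights(hit_b, m_h, m_m)
    return(list(mean_a = drop(crossprod(ra, wa)), mean_b = drop(crossprod(rb, wb)),
                m_hit = m_h, m_miss = m_m))
  }
  set.seed(seed)
  draw_counts <- function(hit) {
    cnt <- numeric(length(hit))
    hits <- which(hit); miss <- which(!hit)
    for (r in seq_len(n_resamples)) {
      if (m_h > 0) {
        sel <- if (length(hits) == 1L) hits else hits[sample.int(length(hits), m_h)]
        cnt[sel] <- cnt[sel] + 1
      }
      if (m_m > 0) {
        sel <- if (length(miss) == 1L) miss else miss[sample.int(length(miss), m_m)]
        cnt[sel] <- cnt[sel] + 1
      }
    }
    cnt / (n_resamples * (m_h + m_m))
  }
  wa <- draw_counts(hit_a)
  wb <- draw_counts(hit_b)
  list(mean_a = drop(crossprod(ra, wa)), mean_b = drop(crossprod(rb, wb)),
       m_hit = m_h, m_miss = m_m)
}

## Exact matched-mean weights: each hit trial gets probability-proportional
## weight m_h/n_h, each miss m_m/n_m, normalized by (m_h + m_m).
match_weights <- function(hit, m_h, m_m) {
  w <- numeric(length(hit))
  n_h <- sum(hit); n_m <- sum(!hit)
  if (m_h > 0 && n_h > 0) w[hit] <- m_h / n_h
  if (m_m > 0 && n_m > 0) w[!hit] <- m_m / n_m
  w / (m_h + m_m)
}

#' Contrast-response curve of one cell
#'
#' Mean delta-F/F at each contrast over the supplied visual-only trials.
#'
#' @param responses per-trial delta-F/F values.
#' @param contrast per-trial contrasts.
#' @param contrasts contrast levels of the session.
#' @return per-contrast mean vector (NA where a level has no trials).
#' @export
contrast_curve <- function(responses, contrast, contrasts = sort(unique(contrast))) {
  vapply(contrasts, function(cc) {
    sel <- contrast == cc
    if (!any(sel)) NA_real_ else mean(responses[sel])
  }, numeric(1L))
}

#' Functional similarity to the target population
#'
#' Pearson correlation of a cell's contrast-response curve with the
#' target-average curve; undefined (NA) for constant curves.
#'
#' @param cell_curve,target_mean_curve equal-length per-contrast means.
#' @return correlation in `[-1, 1]` or NA.
#' @export
similarity_to_targets <- function(cell_curve, target_mean_curve) {
  stopifnot(length(cell_curve) == length(target_mean_curve))
  if (stats::sd(cell_curve) == 0 || stats::sd(target_mean_curve) == 0)
    return(NA_real_)
  stats::cor(cell_curve, target_mean_curve)
}

## Internal: assemble the inputs of the cross-validated analysis into flat
## vectors/index lists so the per-split work is pure matrix arithmetic. The
## result can be reused across shuffles; only the stratum index lists depend
## on the (possibly relabeled) contrasts.
prepare_network_data <- function(responses, trials, states, rois, acfg,
                                 contrasts = NULL) {
  contrasts <- contrasts %||% sort(unique(trials$contrast[trials$contrast > 0]))
  ok_tr <- trials$outcome %in% c("hit", "miss") & trials$contrast > 0 &
    !is.na(states)
  ci <- match(trials$contrast, contrasts)
  stimi <- trials$photostim + 1L
  sti <- match(states, c("more_engaged", "less_engaged"))
  lick <- trials$outcome == "hit"
  R <- responses
  bad_cell <- colSums(!is.finite(R)) > 0
  R[!is.finite(R)] <- 0
  included <- exclusion_mask(rois, radius_um = acfg$exclusion_radius_um,
                             edge_rows = acfg$edge_rows,
                             fov_um = attr(rois, "fov_um") %||% 710,
                             image_px = acfg$image_px)
  targets <- which(rois$is_target)
  bg <- which(included & !rois$is_target & !bad_cell)
  pd <- list(R = R, contrasts = contrasts, ci = ci, stimi = stimi, sti = sti,
             ok_tr = ok_tr, lick = lick, targets = targets, bg = bg,
             n_cells = ncol(R), n_trials = nrow(R))
  pd$strata <- strata_from(pd, ci)
  pd
}

## Stratum index lists (contrast x photostim x state) for given labels.
strata_from <- function(pd, ci) {
  ncon <- length(pd$contrasts)
  strata <- vector("list", ncon * 2L * 2L)
  dim(strata) <- c(ncon, 2L, 2L)
  grp <- ifelse(pd$ok_tr, (ci - 1L) * 4L + (pd$stimi - 1L) * 2L + pd$sti, NA)
  idx <- split(seq_len(pd$n_trials)[!is.na(grp)], grp[!is.na(grp)])
  for (k in seq_len(ncon)) for (p in 1:2) for (s in 1:2) {
    key <- as.character((k - 1L) * 4L + (p - 1L) * 2L + s)
    strata[[k, p, s]] <- idx[[key]] %||% integer()
  }
  strata
}

#' Cross-validated similarity binning and photostimulation-induced change
#'
#' The functional-similarity measurement and the photostimulation-induced
#' change share trials, so the analysis is split-half cross-validated: each
#' split randomly halves the trials (stratified by contrast x
#' photostimulation x state), measures every cell's contrast-response
#' similarity to the target average on one half, bins cells into `n_bins`
#' evenly spaced similarity bins on `[-1, 1]`, and measures the
#' photostimulation-induced change `delta = mean(visual+stim) - mean(visual)`
#' per bin, contrast and state on the other half, with hit:miss ratio
#' matching across the photostimulation factor. Outputs average over splits.
#' Targets are kept out of the bins and reported as a separate row.
#'
#' @param responses trials x cells delta-F/F matrix ([response_table()]).
#' @param trials trial table with outcomes.
#' @param states per-trial state labels.
#' @param rois ROI table.
#' @param acfg an [analysis_config()].
#' @param n_splits number of random splits.
#' @param seed integer seed.
#' @return object of class `oc_delta`: list with `delta` (array bins+1 x
#'   contrasts x states, last row = targets, states more_engaged /
#'   less_engaged / pooled), `n_cells` (mean cells per bin), `split_var`
#'   (per-entry variance across splits), `similarity` (per-cell mean r_sim,
#'   bin of the mean, normalized similarity), `contrasts`, `n_splits`.
#' @export
crossval_similarity_delta <- function(responses, trials, states, rois,
                                      acfg = analysis_config(),
                                      n_splits = acfg$n_splits, seed = 1L) {
  pd <- prepare_network_data(responses, trials, states, rois, acfg)
  crossval_delta_core(pd, acfg, n_splits, seed)
}

crossval_delta_core <- function(pd, acfg, n_splits, seed, strata = pd$strata,
                                n_groups = 3L) {
  set.seed(seed)
  nb <- acfg$n_bins
  ncon <- length(pd$contrasts)
  groups <- seq_len(n_groups)   # more_engaged, less_engaged[, pooled]
  n_tr <- pd$n_trials
  sizes <- array(vapply(strata, length, integer(1L)), dim = dim(strata))
  n_dropped <- sum(sizes > 0L & sizes < 2L)
  if (any(sizes < 2L)) {
    ## single-trial strata cannot be split in half: drop them (the session
    ## is flagged through the n_dropped_strata attribute). Similarity needs
    ## visual-only trials at every contrast, so losing a whole contrast is
    ## fatal.
    strata[sizes < 2L] <- list(integer())
    sizes[sizes < 2L] <- 0L
    vis_ok <- sizes[, 1L, 1L] + sizes[, 1L, 2L] >= 2L
    if (!all(vis_ok))
      stop(sprintf("no splittable visual-only trials at contrast %s",
                   paste(pd$contrasts[!vis_ok], collapse = ", ")),
           call. = FALSE)
  }
  ## visual-only trial indices and their contrast labels, for similarity
  vis_idx <- unlist(strata[, 1L, ], use.names = FALSE)
  vis_ci <- rep.int(rep(seq_len(ncon), 2L),
                    c(sizes[, 1L, 1L], sizes[, 1L, 2L]))
  ord <- order(vis_idx)
  vis_idx <- vis_idx[ord]; vis_ci <- vis_ci[ord]
  ## columns of the weight matrix: cond p within contrast k within group g
  col_of <- function(g, k, p) ((g - 1L) * ncon + (k - 1L)) * 2L + p
  n_w <- n_groups * ncon * 2L
  vis_cols <- col_of(rep(groups, each = ncon), rep(seq_len(ncon), n_groups), 1L)
  stim_cols <- vis_cols + 1L
  n_gk <- n_groups * ncon
  sum_delta <- matrix(0, nb + 1L, n_gk)
  sum_sq <- matrix(0, nb + 1L, n_gk)
  cnt <- matrix(0, nb + 1L, n_gk)
  bin_n <- numeric(nb)
  sim_sum <- numeric(pd$n_cells)
  sim_cnt <- numeric(pd$n_cells)
  lick <- pd$lick
  ones <- rep(1, pd$n_trials)

  for (split in seq_len(n_splits)) {
    half1 <- logical(n_tr)
    for (idx in strata) {
      k <- length(idx) %/% 2L
      half1[idx[sample.int(length(idx), k)]] <- TRUE
    }
    ## similarity from half 1, visual-only trials, states pooled
    h1v <- half1[vis_idx]
    M <- rowsum(pd$R[vis_idx[h1v], , drop = FALSE], vis_ci[h1v]) /
      tabulate(vis_ci[h1v], ncon)
    tc <- rowMeans(M[, pd$targets, drop = FALSE])
    r_sim <- row_cor(t(M), tc)
    okc <- is.finite(r_sim)
    sim_sum[okc] <- sim_sum[okc] + r_sim[okc]
    sim_cnt[okc] <- sim_cnt[okc] + 1
    bin <- pmin(pmax(floor((r_sim + 1) / 2 * nb) + 1L, 1L), nb)

    ## matched condition means from half 2
    W <- matrix(0, n_tr, n_w)
    have <- matrix(FALSE, n_groups, ncon)
    for (k in seq_len(ncon)) {
      i11 <- strata[[k, 1L, 1L]]; i11 <- i11[!half1[i11]]
      i12 <- strata[[k, 1L, 2L]]; i12 <- i12[!half1[i12]]
      i21 <- strata[[k, 2L, 1L]]; i21 <- i21[!half1[i21]]
      i22 <- strata[[k, 2L, 2L]]; i22 <- i22[!half1[i22]]
      for (g in groups) {
        iv <- switch(g, i11, i12, c(i11, i12))
        ip <- switch(g, i21, i22, c(i21, i22))
        m_h <- min(sum(lick[iv]), sum(lick[ip]))
        m_m <- min(sum(!lick[iv]), sum(!lick[ip]))
        if (m_h + m_m == 0L) next
        W[iv, col_of(g, k, 1L)] <- match_weights(lick[iv], m_h, m_m)
        W[ip, col_of(g, k, 2L)] <- match_weights(lick[ip], m_h, m_m)
        have[g, k] <- TRUE
      }
    }
    D <- crossprod(pd$R, W)                      # cells x (3*ncon*2)
    Dd <- D[, stim_cols, drop = FALSE] - D[, vis_cols, drop = FALSE]
    bgb <- bin[pd$bg]
    okb <- which(is.finite(bgb))
    tab <- tabulate(bgb[okb], nb)
    s_bin <- rowsum(Dd[pd$bg[okb], , drop = FALSE], bgb[okb])
    rows <- as.integer(rownames(s_bin))
    v <- matrix(0, nb + 1L, n_gk)
    v[rows, ] <- s_bin / tab[rows]
    v[nb + 1L, ] <- colMeans(Dd[pd$targets, , drop = FALSE])
    filled <- c(rows, nb + 1L)
    hv <- rep(as.vector(t(have)), each = nb + 1L)   # column-major (gk) mask
    dim(hv) <- c(nb + 1L, n_gk)
    upd <- hv
    upd[setdiff(seq_len(nb + 1L), filled), ] <- FALSE
    sum_delta[upd] <- sum_delta[upd] + v[upd]
    sum_sq[upd] <- sum_sq[upd] + v[upd]^2
    cnt[upd] <- cnt[upd] + 1
    bin_n <- bin_n + tab
  }

  delta <- sum_delta / cnt
  delta[cnt == 0] <- NA_real_
  split_var <- sum_sq / cnt - delta^2
  split_var[cnt < 2] <- NA_real_
  dim(delta) <- dim(split_var) <- c(nb + 1L, ncon, n_groups)
  dimnames(delta) <- dimnames(split_var) <-
    list(c(paste0("bin", seq_len(nb)), "targets"), pd$contrasts,
         c("more_engaged", "less_engaged", "pooled")[groups])
  r_mean <- ifelse(sim_cnt > 0, sim_sum / sim_cnt, NA_real_)
  structure(list(
    delta = delta, split_var = split_var,
    n_cells = as.numeric(bin_n) / n_splits,
    similarity = data.frame(
      roi_id = seq_len(pd$n_cells), r_sim = r_mean,
      bin = ifelse(is.finite(r_mean),
                   pmin(pmax(floor((r_mean + 1) / 2 * nb) + 1L, 1L), nb), NA),
      normalized_similarity = ifelse(is.finite(r_mean),
                                     (pmin(pmax(floor((r_mean + 1) / 2 * nb) + 1L, 1L), nb) - 0.5) / nb,
                                     NA),
      is_target = seq_len(pd$n_cells) %in% pd$targets,
      background = seq_len(pd$n_cells) %in% pd$bg),
    contrasts = pd$contrasts, n_bins = nb, n_splits = n_splits,
    n_dropped_strata = n_dropped),
    class = "oc_delta")
}

#' Suppression slope versus functional similarity
#'
#' Pools the photostimulation-induced change across sessions within each
#' similarity bin (weighted by contributing cell counts), fits a per-bin
#' ordinary least squares slope of delta against log10 contrast, then fits
#' the across-bin relation of that slope to normalized similarity (bin
#' centers mapped to `[0, 1]`), excluding the target row. Standard errors
#' and percentile confidence intervals come from a session-level bootstrap.
#'
#' @param deltas list of `oc_delta`, one per session.
#' @param state which state slice to analyse (default `"pooled"`).
#' @param n_boot bootstrap resamples over sessions.
#' @param seed integer seed.
#' @return list with `per_bin` (bin, normalized similarity, slope, se, CI,
#'   mean cell count), `target_slope`, and `fit` (across-bin slope,
#'   intercept, se, CI).
#' @export
suppression_slope <- function(deltas, state = "pooled", n_boot = 1000L,
                              seed = 1L) {
  stopifnot(length(deltas) >= 1L)
  nb <- deltas[[1L]]$n_bins
  contrasts <- deltas[[1L]]$contrasts
  logc <- log10(contrasts)
  normsim <- (seq_len(nb) - 0.5) / nb

  slopes_of <- function(sess_idx) {
    num <- matrix(0, nb + 1L, length(contrasts))
    den <- matrix(0, nb + 1L, length(contrasts))
    for (i in sess_idx) {
      d <- deltas[[i]]$delta[, , state]
      w <- c(deltas[[i]]$n_cells, 1)
      fin <- is.finite(d)
      num[fin] <- num[fin] + (w * d)[fin]
      den[fin] <- den[fin] + (w * matrix(1, nb + 1L, length(contrasts)))[fin]
    }
    pooled <- num / den
    per_bin <- apply(pooled, 1L, function(y) ols_fit(logc, y)[2L])
    fit <- ols_fit(normsim, per_bin[seq_len(nb)])
    list(per_bin = per_bin, slope = fit[2L], intercept = fit[1L])
  }

  obs <- slopes_of(seq_along(deltas))
  set.seed(seed)
  nses <- length(deltas)
  boot_bins <- matrix(NA_real_, n_boot, nb + 1L)
  boot_slope <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    res <- slopes_of(sample.int(nses, nses, replace = TRUE))
    boot_bins[b, ] <- res$per_bin
    boot_slope[b] <- res$slope
  }
  se_bins <- apply(boot_bins, 2L, stats::sd, na.rm = TRUE)
  ci_bins <- apply(boot_bins, 2L, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  mean_n <- rowMeans(vapply(deltas, function(d) d$n_cells, numeric(nb)))
  list(
    per_bin = data.frame(
      bin = seq_len(nb), normalized_similarity = normsim,
      slope = obs$per_bin[seq_len(nb)], se = se_bins[seq_len(nb)],
      ci_lo = ci_bins[1L, seq_len(nb)], ci_hi = ci_bins[2L, seq_len(nb)],
      mean_n_cells = mean_n),
    target_slope = list(slope = obs$per_bin[nb + 1L], se = se_bins[nb + 1L],
                        ci = ci_bins[, nb + 1L]),
    fit = list(slope = obs$slope, intercept = obs$intercept,
               se = stats::sd(boot_slope, na.rm = TRUE),
               ci = stats::quantile(boot_slope, c(0.025, 0.975),
                                    na.rm = TRUE, names = FALSE),
               boot_slopes = boot_slope))
}

#' Spatial profile of photostimulation influence
#'
#' Aligns every cell to its nearest target (lateral offset, planes
#' collapsed), averages the spontaneous-period photostimulation-induced
#' change (photostimulation-catch minus catch trials) in 5 x 5 um bins, and
#' reduces it to a 1D profile over annular distance bins. The Gaussian-
#' smoothed map (SD 10 um) is a display copy only; the 1D profile uses
#' unsmoothed values.
#'
#' @param responses trials x cells delta-F/F matrix.
#' @param trials trial table with outcomes.
#' @param rois ROI table.
#' @param bin_um spatial bin size.
#' @param smooth_sd_um display smoothing SD.
#' @param max_um map half-extent.
#' @return list with `map` (unsmoothed 2D bin means), `map_smooth`,
#'   `profile` (annular bins: `r_lo`, `r_hi`, `r_mid`, `mean_delta`,
#'   `n_cells`), and `cell_delta`.
#' @export
spatial_influence_profile <- function(responses, trials, rois, bin_um = 5,
                                      smooth_sd_um = 10, max_um = 150) {
  targets <- which(rois$is_target)
  if (length(targets) == 0L) stop("no target ROIs", call. = FALSE)
  ok <- trials$outcome != "excluded" & trials$contrast == 0
  i_stim <- which(ok & trials$photostim)
  i_ctrl <- which(ok & !trials$photostim)
  d_cell <- colMeans(responses[i_stim, , drop = FALSE], na.rm = TRUE) -
    colMeans(responses[i_ctrl, , drop = FALSE], na.rm = TRUE)

  dx <- outer(rois$x_um, rois$x_um[targets], "-")
  dy <- outer(rois$y_um, rois$y_um[targets], "-")
  nearest <- apply(dx^2 + dy^2, 1L, which.min)
  off_x <- dx[cbind(seq_len(nrow(rois)), nearest)]
  off_y <- dy[cbind(seq_len(nrow(rois)), nearest)]

  breaks <- seq(-max_um, max_um, by = bin_um)
  bx <- findInterval(off_x, breaks, rightmost.closed = TRUE)
  by <- findInterval(off_y, breaks, rightmost.closed = TRUE)
  nbins <- length(breaks) - 1L
  inmap <- bx >= 1L & bx <= nbins & by >= 1L & by <= nbins & is.finite(d_cell)
  map <- matrix(NA_real_, nbins, nbins)
  cntm <- matrix(0, nbins, nbins)
  summ <- matrix(0, nbins, nbins)
  for (i in which(inmap)) {
    summ[by[i], bx[i]] <- summ[by[i], bx[i]] + d_cell[i]
    cntm[by[i], bx[i]] <- cntm[by[i], bx[i]] + 1
  }
  map[cntm > 0] <- summ[cntm > 0] / cntm[cntm > 0]

  sd_bins <- smooth_sd_um / bin_um
  filled <- ifelse(is.na(map), 0, map)
  wgt <- ifelse(is.na(map), 0, 1)
  sm_num <- smooth_gaussian_rows(t(smooth_gaussian_rows(filled, sd_bins)), sd_bins)
  sm_den <- smooth_gaussian_rows(t(smooth_gaussian_rows(wgt, sd_bins)), sd_bins)
  map_smooth <- t(sm_num / pmax(sm_den, 1e-12))

  r <- sqrt(off_x^2 + off_y^2)
  r_breaks <- seq(0, max_um, by = bin_um)
  rb <- findInterval(r, r_breaks, rightmost.closed = TRUE)
  okr <- rb >= 1L & rb <= length(r_breaks) - 1L & is.finite(d_cell)
  prof_sum <- tapply(d_cell[okr], rb[okr], sum)
  prof_n <- table(rb[okr])
  nb1 <- length(r_breaks) - 1L
  mean_delta <- rep(NA_real_, nb1)
  n_cells <- rep(0L, nb1)
  idx <- as.integer(names(prof_sum))
  mean_delta[idx] <- prof_sum / as.numeric(prof_n)
  n_cells[idx] <- as.integer(prof_n)
  list(map = map, map_smooth = map_smooth,
       profile = data.frame(r_lo = r_breaks[-length(r_breaks)],
                            r_hi = r_breaks[-1L],
                            r_mid = (r_breaks[-1L] + r_breaks[-length(r_breaks)]) / 2,
                            mean_delta = mean_delta, n_cells = n_cells),
       cell_delta = d_cell)
}
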