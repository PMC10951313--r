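#' Pipeline configuration
#'
#' Assembles the full-pipeline configuration: simulation, analysis and
#' output settings. Every random stage derives its seed from the master
#' `seed` through [derive_seed()], so per-session draws are independent of
#' session order and count.
#'
#' @param n_sessions number of sessions to simulate (or length of `sessions`).
#' @param seed master integer seed (required).
#' @param generator an [generator_config()].
#' @param analysis an [analysis_config()].
#' @param out_dir output directory (NULL for no files).
#' @param save_sessions also write each simulated session bundle.
#' @return list of class `oc_pipeline_config`.
#' @export
pipeline_config <- function(n_sessions = 8L, seed = NULL,
                            generator = generator_config(),
                            analysis = analysis_config(),
                            out_dir = NULL, save_sessions = FALSE) {
  if (is.null(seed) || !is.finite(seed))
    stop("pipeline config requires an explicit integer seed", call. = FALSE)
  structure(list(n_sessions = as.integer(n_sessions), seed = as.integer(seed),
                 generator = generator, analysis = analysis,
                 out_dir = out_dir, save_sessions = isTRUE(save_sessions)),
            class = "oc_pipeline_config")
}

#' Analyse one session bundle
#'
#' Runs the per-session stages: neuropil correction, windowed response
#' extraction, activity proxies and the engagement-state index, outcome
#' classification, session truncation and trial exclusions, and (optionally)
#' the behavioral summary with psychometric fits.
#'
#' @param bundle an `oc_session`.
#' @param acfg an [analysis_config()].
#' @param psychometrics fit the per-condition Weibull curves (skip for
#'   resampling harnesses that only need trial-level quantities).
#' @return list with `responses` (trials x cells), `trials` (outcomes +
#'   exclusions), `states`, `states_df`, `rois`, `summary`,
#'   `session_valid`, `neuropil_slopes`, `truth`.
#' @export
analyze_session <- function(bundle, acfg = analysis_config(),
                            psychometrics = TRUE) {
  corrected <- correct_session(bundle, acfg)
  nc <- nrow(corrected)
  sync_cells <- if (is.finite(acfg$sync_max_cells) && nc > acfg$sync_max_cells)
    unique(round(seq(1L, nc, length.out = acfg$sync_max_cells)))
  else seq_len(nc)
  proxies <- session_activity_proxy(corrected, bundle, acfg, sync_cells)
  responses <- response_table(corrected, bundle, acfg)
  states_df <- state_index(bundle, proxies, acfg)
  trials <- classify_outcomes(bundle$trials)
  trials <- truncate_session(trials, acfg$truncation_window,
                             acfg$truncation_frac)
  target_idx <- which(bundle$rois$is_target)
  trials <- apply_trial_exclusions(trials,
                                   responses[, target_idx, drop = FALSE],
                                   thresh = acfg$response_threshold,
                                   fail_frac = acfg$fail_frac)
  summary <- if (psychometrics) summarize_behavior(trials, states_df$state, acfg)
  rois <- bundle$rois
  attr(rois, "fov_um") <- bundle$meta$fov_um %||% 710
  list(session_id = bundle$meta$session_id,
       responses = responses, trials = trials, states = states_df$state,
       states_df = states_df, rois = rois, summary = summary,
       session_valid = attr(trials, "session_valid"),
       neuropil_slopes = attr(corrected, "neuropil_slopes"),
       truth = bundle$truth)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort of sessions and runs every stage:
#' preprocessing, state indexing, behavioral summaries, cross-validated
#' similarity/delta analysis, suppression-slope and spatial-profile
#' summaries, and the neural-behavioral coupling statistics. Re-running with
#' an identical configuration reproduces all outputs exactly.
#'
#' @param config an [pipeline_config()].
#' @param bundles optional list of pre-built `oc_session` bundles (otherwise
#'   `config$n_sessions` sessions are simulated).
#' @return object of class `oc_results` with per-session analyses and cohort
#'   statistics; files are written when `config$out_dir` is set.
#' @export
run_pipeline <- function(config, bundles = NULL) {
  stopifnot(inherits(config, "oc_pipeline_config"))
  acfg <- config$analysis
  n <- if (is.null(bundles)) config$n_sessions else length(bundles)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    bundle <- if (is.null(bundles)) {
      generate_session(config$generator, derive_seed(config$seed, "session", i),
                       session_id = sprintf("sim%03d", i))
    } else bundles[[i]]
    if (!is.null(config$out_dir) && config$save_sessions)
      save_session(bundle, file.path(config$out_dir, "sessions",
                                     bundle$meta$session_id), overwrite = TRUE)
    sa <- analyze_session(bundle, acfg)
    sa$delta <- crossval_similarity_delta(
      sa$responses, sa$trials, sa$states, sa$rois, acfg,
      n_splits = acfg$n_splits, seed = derive_seed(config$seed, "delta", i))
    sa$spatial <- spatial_influence_profile(sa$responses, sa$trials, sa$rois)
    sessions[[i]] <- sa
  }
  deltas <- lapply(sessions, `[[`, "delta")
  supp <- suppression_slope(deltas, state = "pooled", n_boot = acfg$n_boot,
                            seed = derive_seed(config$seed, "suppboot"))
  coup <- coupling_analysis(sessions, acfg, derive_seed(config$seed, "coupling"))
  res <- structure(list(config = config, sessions = sessions,
                        suppression = supp, coupling = coup),
                   class = "oc_results")
  if (!is.null(config$out_dir)) write_results(res, config$out_dir)
  res
}

## Serialize results to CSV/JSON files under out_dir (deterministic bytes
## for a fixed config).
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    df
  }
  states <- do.call(rbind, lapply(res$sessions, function(s)
    cbind(session_id = s$session_id, s$states_df)))
  utils::write.csv(fmt(states), file.path(out_dir, "state_index.csv"),
                   row.names = FALSE)
  beh <- do.call(rbind, lapply(res$sessions, function(s)
    cbind(session_id = s$session_id, s$summary$table)))
  utils::write.csv(fmt(beh), file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)
  dl <- do.call(rbind, lapply(res$sessions, function(s) {
    d <- s$delta$delta
    long <- expand.grid(bin = rownames(d), contrast = colnames(d),
                        state = dimnames(d)[[3L]], stringsAsFactors = FALSE)
    long$delta <- as.vector(d)
    cbind(session_id = s$session_id, long)
  }))
  utils::write.csv(fmt(dl), file.path(out_dir, "delta_activity.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(res$suppression$per_bin),
                   file.path(out_dir, "suppression_slope.csv"),
                   row.names = FALSE)
  sp <- do.call(rbind, lapply(res$sessions, function(s)
    cbind(session_id = s$session_id, s$spatial$profile)))
  utils::write.csv(fmt(sp), file.path(out_dir, "spatial_profile.csv"),
                   row.names = FALSE)
  coup <- lapply(res$coupling$states, function(st)
    list(coupling_r = st$coupling_r, slope = st$slope,
         boot_mean_slope = st$boot$mean_slope, boot_se = st$boot$se_slope,
         p_value = st$p_value, n_null = sum(is.finite(st$null))))
  jsonlite::write_json(coup, file.path(out_dir, "coupling.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("optocoupling")),
    seed = res$config$seed, n_sessions = length(res$sessions),
    config_digest = fnv1a(paste(utils::capture.output(utils::str(
      res$config[c("n_sessions", "seed", "generator", "analysis")])),
      collapse = "\n")),
    session_ids = vapply(res$sessions, `[[`, character(1L), "session_id"),
    session_valid = vapply(res$sessions, `[[`, logical(1L), "session_valid"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Human-readable results report
#'
#' Formats the principal quantities of an [run_pipeline()] result —
#' per-state psychometric parameters, the d-prime change table, suppression
#' slopes and the coupling statistics — without recomputing anything.
#' Missing components are marked as gaps rather than raising.
#'
#' @param res an `oc_results`.
#' @return character vector of report lines (also printed).
#' @export
report <- function(res) {
  lines <- c("== optocoupling pipeline report ==",
             sprintf("sessions: %d (valid: %d)", length(res$sessions),
                     sum(vapply(res$sessions, `[[`, logical(1L), "session_valid"))))
  beh <- do.call(rbind, lapply(res$sessions, function(s) s$summary$table))
  for (s in c("more_engaged", "less_engaged")) {
    for (ps in c(FALSE, TRUE)) {
      sel <- beh$state == s & beh$photostim == ps
      if (!any(sel)) { lines <- c(lines, sprintf("%s/%s: [missing]", s, ps)); next }
      lines <- c(lines, sprintf(
        "%s %s: mean d' = %.3f, median width = %.2f, median threshold = %.2f",
        s, if (ps) "vis+stim" else "visual ", mean(beh$dprime[sel], na.rm = TRUE),
        stats::median(beh$width[sel], na.rm = TRUE),
        stats::median(beh$threshold[sel], na.rm = TRUE)))
    }
  }
  lines <- c(lines, sprintf(
    "suppression slope vs similarity (pooled): %.5f +/- %.5f (CI %.5f..%.5f)",
    res$suppression$fit$slope, res$suppression$fit$se,
    res$suppression$fit$ci[1L], res$suppression$fit$ci[2L]))
  for (s in names(res$coupling$states)) {
    st <- res$coupling$states[[s]]
    lines <- c(lines, if (is.null(st)) sprintf("coupling %s: [missing]", s) else
      sprintf("coupling %s: slope = %.4f (boot %.4f +/- %.4f), p = %.4g",
              s, st$slope, st$boot$mean_slope, st$boot$se_slope, st$p_value))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
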