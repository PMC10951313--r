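#' Construct a session bundle
#'
#' A session bundle collects everything recorded in one behavioral session:
#' the trial table, the ROI table, matched ROI and neuropil fluorescence
#' matrices (cells x frames), the pupil-area trace, session metadata, and —
#' for synthetic sessions — the generator ground truth.
#'
#' @param trials data.frame with columns `trial_id`, `onset_frame` (0-based),
#'   `contrast` (percent, 0 = catch), `photostim` (logical), `lick_times_s`
#'   (list column of sorted nonnegative seconds relative to stimulus onset),
#'   `withhold_s`, `outcome` (hit/miss/false_alarm/correct_rejection/excluded),
#'   `exclusion_reason` (none/early_lick/target_failure/truncated).
#' @param rois data.frame with columns `roi_id`, `x_um`, `y_um`, `plane`,
#'   `z_um`, `is_target`, `included`.
#' @param f_roi,f_neuropil cells x frames fluorescence matrices (same shape).
#' @param pupil_area per-frame pupil area trace.
#' @param frame_rate_hz imaging volume rate.
#' @param photostim_frames integer vector of 0-based frame indices flagged as
#'   photostimulation artifact.
#' @param meta list of session metadata (`session_id`, `animal_id`,
#'   `stim_orientation_deg`, `contrasts_used`).
#' @param truth optional generator ground truth (list).
#' @param check validate invariants on construction.
#' @return an object of class `oc_session`.
#' @export
session_bundle <- function(trials, rois, f_roi, f_neuropil, pupil_area,
                           frame_rate_hz = 7, photostim_frames = integer(),
                           meta = list(), truth = NULL, check = TRUE) {
  bundle <- structure(list(
    trials = trials, rois = rois,
    f_roi = as.matrix(f_roi), f_neuropil = as.matrix(f_neuropil),
    pupil_area = as.numeric(pupil_area),
    frame_rate_hz = frame_rate_hz,
    photostim_frames = as.integer(sort(unique(photostim_frames))),
    meta = meta, truth = truth), class = "oc_session")
  if (check) {
    report <- validate_session(bundle)
    if (length(report) > 0L)
      stop("invalid session bundle:\n  ", paste(report, collapse = "\n  "),
           call. = FALSE)
  }
  bundle
}

#' @export
print.oc_session <- function(x, ...) {
  cat(sprintf("<oc_session> %s: %d trials, %d ROIs (%d targets), %d frames @ %g Hz%s\n",
              x$meta$session_id %||% "(unnamed)", nrow(x$trials), nrow(x$rois),
              sum(x$rois$is_target), ncol(x$f_roi), x$frame_rate_hz,
              if (is.null(x$truth)) "" else ", ground truth attached"))
  invisible(x)
}

#' Validate a session bundle
#'
#' Checks all structural invariants of the session data model and returns the
#' violations as a character vector (empty when the bundle is valid). The
#' function reports rather than raises, and is pure: repeated calls return
#' identical reports.
#'
#' @param bundle an `oc_session`.
#' @return character vector of violated invariants (possibly empty).
#' @export
validate_session <- function(bundle) {
  v <- character()
  tr <- bundle$trials
  rois <- bundle$rois
  need_tr <- c("trial_id", "onset_frame", "contrast", "photostim",
               "lick_times_s", "outcome", "exclusion_reason")
  miss <- setdiff(need_tr, names(tr))
  if (length(miss) > 0L)
    return(sprintf("trial table missing column(s): %s", paste(miss, collapse = ", ")))
  need_roi <- c("roi_id", "x_um", "y_um", "plane", "z_um", "is_target", "included")
  miss <- setdiff(need_roi, names(rois))
  if (length(miss) > 0L)
    return(sprintf("ROI table missing column(s): %s", paste(miss, collapse = ", ")))

  if (is.unsorted(tr$onset_frame, strictly = TRUE))
    v <- c(v, "trial onset_frame not strictly increasing")
  catch_bad <- tr$contrast == 0 & tr$outcome %in% c("hit", "miss")
  if (any(catch_bad))
    v <- c(v, sprintf("catch trial(s) with hit/miss outcome: trial_id %s",
                      paste(tr$trial_id[catch_bad], collapse = ",")))
  go_bad <- tr$contrast > 0 & tr$outcome %in% c("false_alarm", "correct_rejection")
  if (any(go_bad))
    v <- c(v, sprintf("stimulus trial(s) with catch outcome: trial_id %s",
                      paste(tr$trial_id[go_bad], collapse = ",")))
  unsorted_licks <- vapply(tr$lick_times_s, function(l)
    length(l) > 0 && (is.unsorted(l) || any(l < 0)), logical(1L))
  if (any(unsorted_licks))
    v <- c(v, sprintf("unsorted or negative lick times: trial_id %s",
                      paste(tr$trial_id[unsorted_licks], collapse = ",")))

  if (!identical(dim(bundle$f_roi), dim(bundle$f_neuropil)))
    v <- c(v, "f_roi and f_neuropil shapes differ")
  if (nrow(bundle$f_roi) != nrow(rois))
    v <- c(v, sprintf("f_roi has %d rows but ROI table has %d",
                      nrow(bundle$f_roi), nrow(rois)))
  if (length(bundle$pupil_area) != ncol(bundle$f_roi))
    v <- c(v, sprintf("pupil trace length %d != frame count %d",
                      length(bundle$pupil_area), ncol(bundle$f_roi)))
  if (bundle$frame_rate_hz <= 0) v <- c(v, "frame_rate_hz must be positive")
  nf <- ncol(bundle$f_roi)
  if (length(bundle$photostim_frames) > 0 &&
      (min(bundle$photostim_frames) < 0 || max(bundle$photostim_frames) >= nf))
    v <- c(v, "photostim_frames out of range")
  if (max(tr$onset_frame) >= nf)
    v <- c(v, "trial onset_frame beyond trace length")

  fov <- bundle$meta$fov_um %||% 710
  if (any(rois$x_um < 0 | rois$x_um > fov | rois$y_um < 0 | rois$y_um > fov))
    v <- c(v, "ROI position outside field of view")
  if (any(!rois$plane %in% 0:3))
    v <- c(v, "ROI plane outside {0,1,2,3}")
  if (sum(rois$is_target) > 0 && !all(which(rois$is_target) %in% seq_len(nrow(rois))))
    v <- c(v, "target ROI not present in ROI table")
  v
}

## Full-precision text serialization of a numeric matrix (round-trips
## binary64 exactly through %.17g).
write_matrix_txt <- function(m, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = ","))
  writeLines(lines, con)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
}

#' Save a session bundle to a directory
#'
#' Writes one inspectable directory per session: `trials.csv`, `rois.csv`,
#' `f_roi.csv`, `f_neuropil.csv`, `pupil.csv` (full-precision text matrices),
#' `meta.json`, and `truth.json` when ground truth is attached. Lick times are
#' serialized as a semicolon-separated string column.
#'
#' @param bundle an `oc_session`.
#' @param path target directory.
#' @param overwrite overwrite an existing directory?
#' @return `path`, invisibly.
#' @export
save_session <- function(bundle, path, overwrite = FALSE) {
  if (dir.exists(path) && !overwrite)
    stop(sprintf("'%s' already exists; set overwrite = TRUE to replace it", path),
         call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tr <- bundle$trials
  tr$lick_times_s <- vapply(tr$lick_times_s, function(l)
    paste(sprintf("%.17g", l), collapse = ";"), character(1L))
  tr$withhold_s <- sprintf("%.17g", tr$withhold_s)
  utils::write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE)
  utils::write.csv(bundle$rois, file.path(path, "rois.csv"), row.names = FALSE)
  write_matrix_txt(bundle$f_roi, file.path(path, "f_roi.csv"))
  write_matrix_txt(bundle$f_neuropil, file.path(path, "f_neuropil.csv"))
  write_matrix_txt(matrix(bundle$pupil_area, nrow = 1L), file.path(path, "pupil.csv"))
  meta <- list(frame_rate_hz = bundle$frame_rate_hz,
               photostim_frames = bundle$photostim_frames,
               meta = bundle$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(bundle$truth))
    jsonlite::write_json(bundle$truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a session bundle from a directory
#'
#' Inverse of [save_session()]: integer/flag fields round-trip exactly and
#' float arrays to full precision.
#'
#' @param path session directory written by [save_session()].
#' @return an `oc_session`.
#' @export
load_session <- function(path) {
  need <- c("trials.csv", "rois.csv", "f_roi.csv", "f_neuropil.csv",
            "pupil.csv", "meta.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop(sprintf("session component missing: %s", file.path(path, f)),
           call. = FALSE)
  tr <- utils::read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  tr$lick_times_s <- lapply(tr$lick_times_s, function(s) {
    if (is.na(s) || !nzchar(s)) numeric() else as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
  })
  tr$withhold_s <- as.numeric(tr$withhold_s)
  tr$photostim <- as.logical(tr$photostim)
  rois <- utils::read.csv(file.path(path, "rois.csv"), stringsAsFactors = FALSE)
  rois$is_target <- as.logical(rois$is_target)
  rois$included <- as.logical(rois$included)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  truth <- NULL
  if (file.exists(file.path(path, "truth.json")))
    truth <- jsonlite::read_json(file.path(path, "truth.json"), simplifyVector = TRUE)
  bundle <- session_bundle(
    trials = tr, rois = rois,
    f_roi = read_matrix_txt(file.path(path, "f_roi.csv")),
    f_neuropil = read_matrix_txt(file.path(path, "f_neuropil.csv")),
    pupil_area = as.numeric(read_matrix_txt(file.path(path, "pupil.csv"))),
    frame_rate_hz = meta$frame_rate_hz,
    photostim_frames = as.integer(meta$photostim_frames %||% integer()),
    meta = meta$meta, truth = truth, check = TRUE)
  bundle
}
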