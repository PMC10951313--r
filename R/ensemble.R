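#' Photostimulation responsivity criterion
#'
#' A cell is photostimulation-responsive when its evoked response exceeds
#' `thresh` (30% delta-F/F) on strictly more than `frac` (50%) of mapping
#' trials — both inequalities strict.
#'
#' @param trial_responses per-trial delta-F/F values (>= 4 mapping trials).
#' @param thresh response criterion.
#' @param frac required fraction of supra-threshold trials.
#' @return logical flag.
#' @export
photostim_responsive <- function(trial_responses, thresh = 0.3, frac = 0.5) {
  stopifnot(length(trial_responses) >= 4L)
  mean(trial_responses > thresh) > frac
}

#' Visual responsivity and orientation preference
#'
#' The preferred orientation is the stimulus with the largest mean response
#' (ties broken toward the lowest orientation); the cell is visually
#' responsive when the preferred orientation's trials pass the same
#' criterion as [photostim_responsive()].
#'
#' @param responses_by_orientation cells' mapping responses: a matrix with
#'   one column per orientation (trials in rows), or a list of per-orientation
#'   trial vectors.
#' @param orientations orientation labels (degrees), one per column.
#' @param thresh,frac responsivity criterion.
#' @return list with `responsive` (flag) and `preferred_deg` (NA when not
#'   responsive).
#' @export
visual_responsive_and_preference <- function(responses_by_orientation,
                                             orientations = seq(0, 315, by = 45),
                                             thresh = 0.3, frac = 0.5) {
  if (is.matrix(responses_by_orientation))
    responses_by_orientation <- lapply(seq_len(ncol(responses_by_orientation)),
                                       function(j) responses_by_orientation[, j])
  stopifnot(length(responses_by_orientation) == length(orientations))
  means <- vapply(responses_by_orientation, mean, numeric(1L))
  pref_idx <- which(means == max(means))[1L]
  responsive <- photostim_responsive(responses_by_orientation[[pref_idx]],
                                     thresh, frac)
  list(responsive = responsive,
       preferred_deg = if (responsive) orientations[pref_idx] else NA_real_)
}

#' Build per-cell responsivity records from a mapping block
#'
#' @param mapping mapping block from [generate_mapping_block()] (or the same
#'   structure extracted from real mapping data).
#' @param thresh,frac responsivity criterion.
#' @return data.frame with `roi_id`, `photo_responsive`, `vis_responsive`,
#'   `preferred_orientation_deg`, `mean_photo_response`.
#' @export
responsivity_records <- function(mapping, thresh = 0.3, frac = 0.5) {
  nc <- nrow(mapping$photo)
  out <- data.frame(roi_id = seq_len(nc),
                    photo_responsive = FALSE, vis_responsive = FALSE,
                    preferred_orientation_deg = NA_real_,
                    mean_photo_response = rowMeans(mapping$photo))
  for (i in seq_len(nc)) {
    out$photo_responsive[i] <- photostim_responsive(mapping$photo[i, ],
                                                    thresh, frac)
    vis <- visual_responsive_and_preference(
      t(mapping$vis[i, , , drop = TRUE]), mapping$orientations, thresh, frac)
    out$vis_responsive[i] <- vis$responsive
    out$preferred_orientation_deg[i] <- vis$preferred_deg
  }
  out
}

#' Select the co-tuned photostimulation ensemble
#'
#' Among cells that are both photostimulation- and visually responsive,
#' returns the largest orientation-preference group. Errors when that group
#' is smaller than `min_size`; groups above `max_size` are capped by keeping
#' the cells with the strongest mean photostimulation response.
#'
#' @param records responsivity table from [responsivity_records()].
#' @param min_size,max_size ensemble size limits.
#' @return list with `roi_ids`, `orientation_deg`, and `group_sizes` (all 8
#'   orientation groups).
#' @export
select_ensemble <- function(records, min_size = 6L, max_size = 73L) {
  both <- records[records$photo_responsive & records$vis_responsive, ]
  orientations <- seq(0, 315, by = 45)
  sizes <- vapply(orientations, function(o)
    sum(both$preferred_orientation_deg == o, na.rm = TRUE), integer(1L))
  names(sizes) <- orientations
  best <- orientations[which.max(sizes)]
  group <- both[!is.na(both$preferred_orientation_deg) &
                  both$preferred_orientation_deg == best, ]
  if (nrow(group) < min_size)
    stop(sprintf("largest co-tuned group has %d cells (< %d)",
                 nrow(group), min_size), call. = FALSE)
  if (nrow(group) > max_size)
    group <- group[order(-group$mean_photo_response)[seq_len(max_size)], ]
  list(roi_ids = sort(group$roi_id), orientation_deg = best,
       group_sizes = sizes)
}
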