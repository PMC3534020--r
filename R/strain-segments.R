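# Segment averaging of strain fields and end-systole selection.

#' Average strain measures over myocardial segments
#'
#' Arithmetic mean of each strain measure over the valid myocardial pixels of
#' every segment.  Segments capturing fewer than `min_pixels` valid pixels
#' are emitted with missing values and reported.
#'
#' @param measures named list of `[m, m, n_slices]` arrays (typically `Ecc`,
#'   `Err`, `Ell`, `E1`, `E2`, `E3`, percent strain).
#' @param valid logical `[m, m, n_slices]` validity mask.
#' @param theta array of pixel angles (radians from the ARVP direction).
#' @param models list of per-slice segment data.frames
#'   (see [build_segment_model()]).
#' @param animal_id,time identifiers copied into the output rows.
#' @param min_pixels minimum valid pixels per segment.
#' @return data.frame `animal_id, time, slice, segment_id, class, n_pixels`
#'   plus one column per measure.
#' @export
segment_average <- function(measures, valid, theta, models,
                            animal_id = 1L, time = "baseline",
                            min_pixels = 10) {
  stopifnot(is.list(measures), length(measures) > 0)
  ns <- dim(valid)[3]
  stopifnot(length(models) == ns)
  out <- list()
  starved <- 0L
  for (k in seq_len(ns)) {
    segs <- models[[k]]
    vk <- valid[, , k]
    tk <- theta[, , k]
    for (i in seq_len(nrow(segs))) {
      sel <- vk & angle_in(tk, segs$theta1[i], segs$theta2[i])
      n_px <- sum(sel, na.rm = TRUE)
      vals <- if (n_px >= min_pixels) {
        vapply(measures, function(a) mean(a[, , k][sel], na.rm = TRUE),
               numeric(1))
      } else {
        starved <- starved + 1L
        stats::setNames(rep(NA_real_, length(measures)), names(measures))
      }
      out[[length(out) + 1L]] <- data.frame(
        animal_id = animal_id, time = time, slice = k,
        segment_id = segs$segment_id[i], class = segs$class[i],
        n_pixels = n_px, as.list(vals), stringsAsFactors = FALSE)
    }
  }
  if (starved > 0) {
    message(starved, " segment(s) had fewer than ", min_pixels,
            " valid pixels; emitted with missing values")
  }
  do.call(rbind, out)
}

#' Pick the end-systolic phase from a phase-resolved strain summary
#'
#' End-systole is selected data-drivenly as the phase maximising the absolute
#' mean circumferential strain over remote/healthy tissue.
#'
#' @param mean_ecc_by_phase numeric vector: mean remote/healthy `Ecc` (any
#'   sign convention) per cardiac phase.
#' @return the phase index.
#' @export
pick_end_systole <- function(mean_ecc_by_phase) {
  which.max(abs(mean_ecc_by_phase))
}

#' Write a segment strain table to CSV
#'
#' @param table data.frame from [segment_average()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segment_strain_table <- function(table, path) {
  cols <- c("animal_id", "time", "slice", "segment_id", "class",
            "Ecc", "Err", "Ell", "E1", "E2", "E3")
  cols <- intersect(cols, names(table))
  utils::write.csv(table[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
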