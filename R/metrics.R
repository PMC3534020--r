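# Global LV function and morphology: disk-summation volumes, ejection
# fraction, chordwise wall thickness, scar percentage.

.polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Global LV volumes and ejection fraction by disk summation
#'
#' Endocardial contour areas are summed over slices and multiplied by the
#' slice thickness (no apical cap).  `SV = EDV - ESV`, `EF = 100 SV / EDV`.
#'
#' @param contours_ed,contours_es per-slice lists with an `endo` n x 2 matrix
#'   (mm), as from [geometry_contours()]; every slice must be present in both.
#' @param slice_thickness mm.
#' @return list of class `global_function`: `EDV`, `ESV`, `SV` (ml), `EF` (%).
#' @export
lv_volumes <- function(contours_ed, contours_es, slice_thickness) {
  if (length(contours_ed) != length(contours_es)) {
    stop("end-diastolic and end-systolic contour stacks differ in slice count",
         call. = FALSE)
  }
  miss <- which(vapply(contours_ed, function(s) is.null(s$endo), logical(1)) |
                  vapply(contours_es, function(s) is.null(s$endo), logical(1)))
  if (length(miss) > 0) {
    stop("missing endocardial contour on slice(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  edv <- sum(vapply(contours_ed, function(s) .polygon_area(s$endo), numeric(1))) *
    slice_thickness / 1000
  esv <- sum(vapply(contours_es, function(s) .polygon_area(s$endo), numeric(1))) *
    slice_thickness / 1000
  sv <- edv - esv
  structure(list(EDV = edv, ESV = esv, SV = sv, EF = 100 * sv / edv),
            class = "global_function")
}

#' @export
print.global_function <- function(x, ...) {
  cat(sprintf("LV function: EDV %.1f ml, ESV %.1f ml, SV %.1f ml, EF %.1f%%\n",
              x$EDV, x$ESV, x$SV, x$EF))
  invisible(x)
}

#' Per-segment wall thickness from the chord set
#'
#' Mean endocardium-to-epicardium chord length per segment, from the same
#' chord geometry used for transmurality.
#'
#' @param endo,epi slice contours (mm).
#' @param segments one-slice segment data.frame from [build_segment_model()].
#' @param arvp_angle ARVP direction, radians.
#' @param n_chords chords per slice.
#' @return data.frame `segment_id, class, thickness_mm` (NA where a segment
#'   captured no valid chord).
#' @export
wall_thickness <- function(endo, epi, segments, arvp_angle = 0,
                           n_chords = 120) {
  ctr <- colMeans(endo)
  r_en <- .radial_fun(endo, ctr)
  r_ep <- .radial_fun(epi, ctr)
  angles <- 2 * pi * (seq_len(n_chords) - 1) / n_chords
  len <- r_ep(angles + arvp_angle) - r_en(angles + arvp_angle)
  valid <- is.finite(len) & len > 0
  th <- vapply(seq_len(nrow(segments)), function(i) {
    inseg <- angle_in(angles, segments$theta1[i], segments$theta2[i]) & valid
    if (!any(inseg)) return(NA_real_)
    mean(len[inseg])
  }, numeric(1))
  data.frame(segment_id = segments$segment_id, class = segments$class,
             thickness_mm = th)
}

#' Scar percentage of the LV myocardium
#'
#' @param infarct_mask logical array (or `infarct_mask` object).
#' @param myo_mask logical myocardial mask on the same grid.
#' @return scar volume as a percentage of myocardial volume.
#' @export
scar_percentage <- function(infarct_mask, myo_mask) {
  if (inherits(infarct_mask, "infarct_mask")) infarct_mask <- infarct_mask$mask
  if (!any(myo_mask)) stop("empty myocardial mask", call. = FALSE)
  stopifnot(all(dim(infarct_mask) == dim(myo_mask)))
  100 * sum(infarct_mask & myo_mask) / sum(myo_mask)
}
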