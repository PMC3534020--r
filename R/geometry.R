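# Left-ventricular phantom geometry: a stack of contiguous short-axis annuli
# with linear apical taper.  Lengths are millimetres throughout; the long axis
# runs from Z = 0 (apical slice centre) toward the base; angles are measured
# counterclockwise from the anteroseptal RV attachment point (ARVP) direction.

#' Build the phantom left-ventricular geometry
#'
#' The LV wall is modelled as a stack of `n_slices` contiguous annuli (slice
#' spacing equal to slice thickness) whose endocardial and epicardial radii
#' taper linearly toward the apex.
#'
#' @param n_slices number of short-axis slices (3 to 20).
#' @param slice_thickness slice thickness and spacing, mm.
#' @param endo_radius,epi_radius basal endocardial / epicardial radii, mm.
#' @param apex_scale radius scale factor at the apical slice (linear taper).
#' @param pixel_spacing in-plane pixel size, mm.
#' @param matrix_size image matrix (pixels per side).
#' @param arvp_angle angular position of the ARVP direction in image
#'   coordinates, radians.
#' @param base_extension,apex_extension tissue extent beyond the basal /
#'   apical slice, mm: the wall continues past both ends of the imaged stack
#'   (basal myocardium toward the valve plane, the apical cap below the last
#'   slice), so material moving through the end planes under longitudinal
#'   shortening still carries signal.  Default two slice thicknesses.
#' @return object of class `lv_geometry`.
#' @export
build_lv_geometry <- function(n_slices = 10, slice_thickness = 8,
                              endo_radius = 20, epi_radius = 30,
                              apex_scale = 0.6, pixel_spacing = 1.25,
                              matrix_size = 256, arvp_angle = 0,
                              base_extension = 2 * slice_thickness,
                              apex_extension = 2 * slice_thickness) {
  if (!is.numeric(endo_radius) || !is.numeric(epi_radius) ||
      endo_radius <= 0 || epi_radius <= 0) {
    stop("radii must be positive", call. = FALSE)
  }
  if (endo_radius >= epi_radius) {
    stop("endocardial radius must be smaller than epicardial radius",
         call. = FALSE)
  }
  stopifnot(n_slices >= 1, n_slices <= 20, slice_thickness > 0,
            apex_scale > 0, apex_scale <= 1, pixel_spacing > 0,
            matrix_size >= 16)

  positions <- (seq_len(n_slices) - 1) * slice_thickness
  scale <- if (n_slices > 1) {
    apex_scale + (1 - apex_scale) * positions / max(positions)
  } else {
    rep(1, n_slices)
  }
  geom <- structure(list(
    n_slices = as.integer(n_slices),
    slice_thickness = slice_thickness,
    slice_positions = positions,
    endo_radius = endo_radius * scale,
    epi_radius = epi_radius * scale,
    pixel_spacing = pixel_spacing,
    matrix_size = as.integer(matrix_size),
    fov = matrix_size * pixel_spacing,
    arvp_angle = arvp_angle,
    base_extension = base_extension,
    apex_extension = apex_extension
  ), class = "lv_geometry")
  geom
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf("LV geometry: %d slices x %.0f mm, endo %.1f-%.1f mm, epi %.1f-%.1f mm, %dpx @ %.2f mm\n",
              x$n_slices, x$slice_thickness,
              min(x$endo_radius), max(x$endo_radius),
              min(x$epi_radius), max(x$epi_radius),
              x$matrix_size, x$pixel_spacing))
  invisible(x)
}

# In-plane pixel-centre coordinates (mm), origin on the LV long axis.
pixel_axis <- function(geometry) {
  m <- geometry$matrix_size
  (seq_len(m) - (m + 1) / 2) * geometry$pixel_spacing
}

# Endocardial/epicardial radius as a linear function of long-axis position,
# extrapolated half a thickness beyond the end slices (the imaged slab).
radius_at <- function(geometry, z, which = c("endo", "epi")) {
  which <- match.arg(which)
  r <- if (which == "endo") geometry$endo_radius else geometry$epi_radius
  if (geometry$n_slices == 1) return(rep(r[1], length(z)))
  p <- geometry$slice_positions
  slope <- (r[geometry$n_slices] - r[1]) / (p[geometry$n_slices] - p[1])
  r[1] + slope * (z - p[1])
}

radius_slope <- function(geometry, which = c("endo", "epi")) {
  which <- match.arg(which)
  r <- if (which == "endo") geometry$endo_radius else geometry$epi_radius
  if (geometry$n_slices == 1) return(0)
  p <- geometry$slice_positions
  (r[geometry$n_slices] - r[1]) / (p[geometry$n_slices] - p[1])
}

# Long-axis extent of myocardial tissue: the imaged slab plus the basal
# extension (the wall continues past the most basal slice).
slab_range <- function(geometry) {
  c(min(geometry$slice_positions) - geometry$slice_thickness / 2 -
      (geometry$apex_extension %||% 0),
    max(geometry$slice_positions) + geometry$slice_thickness / 2 +
      (geometry$base_extension %||% 0))
}

# Long-axis extent of the imaged stack only (no extensions).
stack_range <- function(geometry) {
  c(min(geometry$slice_positions) - geometry$slice_thickness / 2,
    max(geometry$slice_positions) + geometry$slice_thickness / 2)
}

#' Myocardial mask on the phantom pixel grid
#'
#' @param geometry an `lv_geometry`.
#' @param partial if `TRUE`, return fractional pixel coverage (8x8 subpixel
#'   sampling) rather than a hard centre-inside test.
#' @return array `[matrix, matrix, n_slices]` of 0/1 (or coverage fractions).
#' @export
myocardium_mask <- function(geometry, partial = FALSE) {
  ax <- pixel_axis(geometry)
  m <- geometry$matrix_size
  out <- array(0, c(m, m, geometry$n_slices))
  px <- geometry$pixel_spacing
  if (partial) {
    sub <- (seq_len(8) - 4.5) / 8 * px
    cov <- matrix(0, m, m)
    for (k in seq_len(geometry$n_slices)) {
      en <- geometry$endo_radius[k]
      ep <- geometry$epi_radius[k]
      cov[] <- 0
      for (dx in sub) {
        for (dy in sub) {
          d <- sqrt(outer((ax + dx)^2, (ax + dy)^2, "+"))
          cov <- cov + (d >= en & d <= ep)
        }
      }
      out[, , k] <- cov / 64
    }
  } else {
    dist <- sqrt(outer(ax^2, ax^2, "+"))
    for (k in seq_len(geometry$n_slices)) {
      out[, , k] <- (dist >= geometry$endo_radius[k] &
                       dist <= geometry$epi_radius[k]) * 1
    }
  }
  out
}

#' Disk-summation cavity volume of the phantom geometry
#'
#' @param geometry an `lv_geometry`.
#' @param radii optional endocardial radii overriding the geometry's (e.g. a
#'   deformed configuration); one value per slice.
#' @return cavity volume in ml.
#' @export
cavity_volume <- function(geometry, radii = NULL) {
  r <- radii %||% geometry$endo_radius
  stopifnot(length(r) == geometry$n_slices)
  sum(pi * r^2 * geometry$slice_thickness) / 1000
}

#' Circular reference contours for each slice
#'
#' @param geometry an `lv_geometry`.
#' @param n_points vertices per contour.
#' @return list with one element per slice, each holding `endo` and `epi`
#'   (`n_points` x 2 matrices, mm) and the slice `z` position.
#' @export
geometry_contours <- function(geometry, n_points = 120) {
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  lapply(seq_len(geometry$n_slices), function(k) {
    list(
      z = geometry$slice_positions[k],
      endo = cbind(x = geometry$endo_radius[k] * cos(th),
                   y = geometry$endo_radius[k] * sin(th)),
      epi = cbind(x = geometry$epi_radius[k] * cos(th),
                  y = geometry$epi_radius[k] * sin(th))
    )
  })
}
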