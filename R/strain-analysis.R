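# Phase-map -> strain-field assembly for whole slices: gradients, tensors,
# anatomical decomposition and pixel angles, ready for segment averaging.

#' Compute decomposed strain fields at one cardiac phase
#'
#' Runs [deformation_gradient_inverse()] and [green_strain()], then decomposes
#' every valid pixel's tensor in the local anatomical basis derived from the
#' supplied (tracked) epicardial contours, and attaches the pixel angle
#' relative to the ARVP ray for segment assignment.
#'
#' @param maps a `phase_map_stack`.
#' @param phase cardiac phase index.
#' @param contours per-slice list; each element needs `epi` (n x 2 matrix,
#'   mm), `centroid` (length 2), and `arvp_angle` (radians, image frame).
#'   Defaults to the reference circular contours of the phantom geometry.
#' @param erode_px in-plane binary erosion (pixels) applied to the quality
#'   mask before decomposition; discards partial-volume wall-edge pixels
#'   whose filtered phase extrapolates into the background.
#' @return list of `[m, m, ns]` arrays `Ecc`, `Err`, `Ell`, `E1`, `E2`, `E3`
#'   (percent), `valid`, `theta` (radians from ARVP), plus `phase`.
#' @export
compute_strain_fields <- function(maps, phase, contours = NULL,
                                  erode_px = 1) {
  geom <- maps$geometry
  m <- geom$matrix_size
  ns <- geom$n_slices
  if (is.null(contours)) {
    ref <- geometry_contours(geom, 90)
    contours <- lapply(ref, function(s) list(
      epi = s$epi, centroid = c(0, 0), arvp_angle = geom$arvp_angle))
  }
  grad <- deformation_gradient_inverse(maps, phase)
  stf <- green_strain(grad)
  if (erode_px > 0) {
    for (k in seq_len(ns)) {
      stf$valid[, , k] <- erode_mask2(stf$valid[, , k], erode_px)
    }
  }
  ax <- pixel_axis(geom)
  xs <- rep(ax, times = m)
  ys <- rep(ax, each = m)

  dims <- c(m, m, ns)
  out <- list(Ecc = array(NA_real_, dims), Err = array(NA_real_, dims),
              Ell = array(NA_real_, dims), E1 = array(NA_real_, dims),
              E2 = array(NA_real_, dims), E3 = array(NA_real_, dims),
              valid = stf$valid, theta = array(NA_real_, dims), phase = phase)
  for (k in seq_len(ns)) {
    vk <- stf$valid[, , k]
    idx <- which(as.vector(vk))
    th_all <- wrap_2pi(atan2(ys - contours[[k]]$centroid[2],
                             xs - contours[[k]]$centroid[1]) -
                         contours[[k]]$arvp_angle)
    out$theta[, , k] <- array(th_all, c(m, m))
    if (length(idx) == 0) next
    pts <- cbind(xs[idx], ys[idx])
    E6 <- matrix(NA_real_, length(idx), 6)
    for (d in 1:6) E6[, d] <- stf$E[, , k, d][idx]
    basis <- local_basis(contours[[k]]$epi, c(0, 0, 1), pts)
    dirs <- directional_strains(E6, basis)
    prin <- principal_strains(E6)
    fill <- function(v) {
      a <- array(NA_real_, c(m, m))
      a[idx] <- v
      a
    }
    out$Ecc[, , k] <- fill(dirs$Ecc)
    out$Err[, , k] <- fill(dirs$Err)
    out$Ell[, , k] <- fill(dirs$Ell)
    out$E1[, , k] <- fill(prin$E1)
    out$E2[, , k] <- fill(prin$E2)
    out$E3[, , k] <- fill(prin$E3)
  }
  out
}

#' Deformed contour landmarks tracked through the cycle
#'
#' Tracks reference endocardial and epicardial contour points, the ARVP
#' landmark and optional infarct border points from the reference phase
#' through every cardiac phase.  Contour landmarks are seeded one pixel
#' inside the drawn boundary: boundary pixels are partial-volume and carry
#' no reliable tag phase.
#'
#' @param maps a `phase_map_stack`.
#' @param n_points contour points per contour.
#' @param border_angles optional angles (radians from ARVP) of infarct border
#'   landmarks placed mid-wall.
#' @param ref_phase reference phase index.
#' @return list over slices; each element has data.frames `endo`, `epi`,
#'   `arvp`, `borders` from [track_landmarks()].
#' @export
track_contours <- function(maps, n_points = 48, border_angles = NULL,
                           ref_phase = 1) {
  geom <- maps$geometry
  px <- geom$pixel_spacing
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  lapply(seq_len(geom$n_slices), function(k) {
    en <- geom$endo_radius[k] + px
    ep <- geom$epi_radius[k] - px
    mw <- (en + ep) / 2
    endo_pts <- cbind(en * cos(th), en * sin(th))
    epi_pts <- cbind(ep * cos(th), ep * sin(th))
    arvp_pt <- cbind(mw * cos(geom$arvp_angle), mw * sin(geom$arvp_angle))
    res <- list(
      endo = track_landmarks(maps, endo_pts, k, ref_phase),
      epi = track_landmarks(maps, epi_pts, k, ref_phase),
      arvp = track_landmarks(maps, arvp_pt, k, ref_phase)
    )
    if (!is.null(border_angles)) {
      ba <- border_angles + geom$arvp_angle
      pts <- cbind(mw * cos(ba), mw * sin(ba))
      res$borders <- track_landmarks(maps, pts, k, ref_phase)
    }
    res
  })
}

# Extract per-slice contour descriptors (epi polyline, endo centroid, ARVP
# ray angle) at one phase from track_contours() output.
contours_at_phase <- function(tracked, phase) {
  lapply(tracked, function(tr) {
    epi <- tr$epi[tr$epi$phase == phase, ]
    endo <- tr$endo[tr$endo$phase == phase, ]
    arvp <- tr$arvp[tr$arvp$phase == phase, ]
    ctr <- c(mean(endo$x_mm), mean(endo$y_mm))
    # sanitise the tracked polylines: median-filter the radial profile and
    # resample onto a uniform angular grid, so isolated tracking failures
    # cannot self-intersect the contour handed to the basis construction
    tidy <- function(df) {
      pts <- cbind(df$x_mm, df$y_mm)
      ang <- wrap_2pi(atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]))
      rad <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
      o <- order(ang)
      ang <- ang[o]; rad <- rad[o]
      n <- length(rad)
      rad <- vapply(seq_len(n), function(i) {
        stats::median(rad[((i + c(-1, 0, 1) - 1) %% n) + 1])
      }, numeric(1))
      grid <- 2 * pi * (seq_len(n) - 1) / n
      rg <- stats::approx(c(ang - 2 * pi, ang, ang + 2 * pi),
                          rep(rad, 3), xout = grid, rule = 2)$y
      cbind(ctr[1] + rg * cos(grid), ctr[2] + rg * sin(grid))
    }
    list(
      epi = tidy(epi),
      endo = tidy(endo),
      centroid = ctr,
      arvp_angle = atan2(arvp$y_mm[1] - ctr[2], arvp$x_mm[1] - ctr[1])
    )
  })
}
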