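# Harmonic-phase extraction: spectral bandpass around the first tag harmonic,
# and separation of the in-plane tag phase from the z-encoded phase using the
# two z-encode polarities.  All phase arithmetic is wrapped; no global
# unwrapping is performed anywhere.

#' FFT bin of the first tag harmonic
#'
#' @param fov field of view, mm.
#' @param tag_spacing tag period, mm.
#' @return nearest integer FFT bin (cycles per FOV) of the harmonic peak.
#' @export
harmonic_peak_bin <- function(fov, tag_spacing) {
  as.integer(round(fov / tag_spacing))
}

#' Extract the harmonic image by spectral bandpass
#'
#' Restricts the 2D spectrum to a circularly symmetric raised-cosine window
#' centred on the tag frequency and inverse-transforms, yielding a complex
#' image whose wrapped phase is the harmonic phase.
#'
#' @param img complex 2D image (first index along x).
#' @param omega tag wavevector, rad/mm (2-vector, e.g. `c(2*pi/7, 0)`).
#' @param pixel_spacing pixel size, mm.
#' @param radius_frac filter radius as a fraction of `|omega|`.  For generic
#'   (real-valued, two-sideband) tagged data the radius must stay below 0.5
#'   so the window excludes the DC and conjugate peaks; complex single-
#'   sideband (complementary-tagging) data carry a single harmonic, and
#'   setting `single_sideband = TRUE` admits wider windows, which sharpens
#'   the strain-limiting spatial resolution.
#' @param window `"raised-cosine"` (cosine taper from the centre) or
#'   `"flat-top"` (flat passband with a raised-cosine edge).
#' @param flat_frac for the flat-top window, the flat fraction of the radius.
#' @param single_sideband set `TRUE` when the input has no conjugate/DC
#'   peaks; lifts the 0.5 radius guard.
#' @return complex filtered image of the same size.
#' @export
extract_harmonic_image <- function(img, omega, pixel_spacing,
                                   radius_frac = 0.4,
                                   window = c("raised-cosine", "flat-top"),
                                   flat_frac = 0.7,
                                   single_sideband = FALSE) {
  window <- match.arg(window)
  stopifnot(is.matrix(img), length(omega) == 2)
  if (!single_sideband && radius_frac >= 0.5) {
    stop("filter radius must stay below |omega|/2", call. = FALSE)
  }
  if (single_sideband && radius_frac > 4) {
    stop("filter radius beyond 4|omega| defeats the harmonic model", call. = FALSE)
  }
  k0 <- omega / (2 * pi)           # cycles/mm
  nyq <- 0.5 / pixel_spacing
  if (sqrt(sum(k0^2)) >= nyq) {
    stop("harmonic peak lies outside the Nyquist band", call. = FALSE)
  }
  m <- nrow(img)
  n <- ncol(img)
  fx <- (seq_len(m) - 1) / (m * pixel_spacing)
  fx <- ifelse(fx >= nyq, fx - 2 * nyq, fx)
  fy <- (seq_len(n) - 1) / (n * pixel_spacing)
  fy <- ifelse(fy >= nyq, fy - 2 * nyq, fy)
  d <- sqrt(outer((fx - k0[1])^2, (fy - k0[2])^2, "+"))
  rad <- radius_frac * sqrt(sum(k0^2))
  w <- if (window == "raised-cosine") {
    ifelse(d < rad, 0.5 * (1 + cos(pi * d / rad)), 0)
  } else {
    ifelse(d < flat_frac * rad, 1,
           ifelse(d < rad,
                  0.5 * (1 + cos(pi * (d - flat_frac * rad) /
                                   ((1 - flat_frac) * rad))), 0))
  }
  stats::fft(stats::fft(img) * w, inverse = TRUE) / (m * n)
}

#' Separate tag phase and z-encoded phase from a polarity pair
#'
#' For harmonic images of the same tag orientation with opposite z-encode
#' polarity, `h+ = A exp(i(phi_tag + phi_z))` and
#' `h- = A exp(i(phi_tag - phi_z))`, so `phi_z = angle(h+ conj(h-))/2` up to a
#' pi ambiguity, resolved by continuity with the previous cardiac phase
#' (first phase: `|phi_z| < pi/2` is assumed).  The tag phase is recovered
#' modulo `2*pi` by choosing the branch of `angle(h+ h-)/2` consistent with
#' `angle(h+)`.
#'
#' @param h_plus,h_minus complex harmonic images (same orientation, opposite
#'   z-encode polarity).
#' @param prev_phi_z optional z-phase of the previous phase for continuity;
#'   entries set to `NA` (e.g. pixels failing the quality mask at the
#'   previous phase) fall back to the first-phase assumption.
#' @return list with `phi_tag` (wrapped to `[-pi, pi)`) and `phi_z`.
#' @export
separate_z_phase <- function(h_plus, h_minus, prev_phi_z = NULL) {
  stopifnot(length(h_plus) == length(h_minus))
  phz <- Arg(h_plus * Conj(h_minus)) / 2
  if (!is.null(prev_phi_z)) {
    k <- round((prev_phi_z - phz) / pi)
    k[is.na(k)] <- 0
    phz <- phz + k * pi
  }
  pht_raw <- Arg(h_plus * h_minus) / 2
  ref <- Arg(h_plus)
  r0 <- abs(wrap_pi(ref - pht_raw - phz))
  r1 <- abs(wrap_pi(ref - pht_raw - pi - phz))
  pht <- wrap_pi(pht_raw + pi * (r1 < r0))
  list(phi_tag = pht, phi_z = phz)
}

#' Harmonic phase maps for a whole tagged image set
#'
#' Bandpass-filters every encoding, separates tag and z phases per
#' orientation (the two z-phase estimates are averaged), and builds the
#' magnitude-based quality mask.
#'
#' @param set a `tagged_image_set`.
#' @param radius_frac bandpass radius as a fraction of `|omega|`.  The
#'   default exploits the single-sideband complementary-tagging signal model
#'   of the synthetic encodings (no DC or conjugate peak), where a wide
#'   flat-top window preserves transmural strain gradients that a
#'   conventional narrow window smooths away.
#' @param window,flat_frac passed to [extract_harmonic_image()].
#' @param quality_frac quality-mask threshold as a fraction of the
#'   98th-percentile magnitude.
#' @return object of class `phase_map_stack`: arrays `phi_h`, `phi_v`
#'   (wrapped tag phases along x and y), `phi_z`, `magnitude`, logical `mask`,
#'   all `[m, m, n_slices, n_phases]`, plus `acq`, `geometry`, `filter`.
#' @export
harp_phase_maps <- function(set, radius_frac = 2.5, window = "flat-top",
                            flat_frac = 0.9, quality_frac = 0.15) {
  stopifnot(inherits(set, "tagged_image_set"))
  acq <- set$acq
  geom <- set$geometry
  m <- geom$matrix_size
  ns <- geom$n_slices
  np <- acq$n_phases
  dims <- c(m, m, ns, np)
  phi_h <- array(NA_real_, dims)
  phi_v <- array(NA_real_, dims)
  phi_z <- array(NA_real_, dims)
  mag <- array(NA_real_, dims)

  om_h <- c(acq$omega, 0)
  om_v <- c(0, acq$omega)
  for (k in seq_len(ns)) {
    prev_z <- NULL
    for (p in seq_len(np)) {
      hp <- extract_harmonic_image(set$images$horizontal$plus[, , k, p], om_h,
                                   geom$pixel_spacing, radius_frac, window,
                                   flat_frac, single_sideband = TRUE)
      hm <- extract_harmonic_image(set$images$horizontal$minus[, , k, p], om_h,
                                   geom$pixel_spacing, radius_frac, window,
                                   flat_frac, single_sideband = TRUE)
      vp <- extract_harmonic_image(set$images$vertical$plus[, , k, p], om_v,
                                   geom$pixel_spacing, radius_frac, window,
                                   flat_frac, single_sideband = TRUE)
      vm <- extract_harmonic_image(set$images$vertical$minus[, , k, p], om_v,
                                   geom$pixel_spacing, radius_frac, window,
                                   flat_frac, single_sideband = TRUE)
      sh <- separate_z_phase(hp, hm, prev_z)
      sv <- separate_z_phase(vp, vm, prev_z)
      phi_h[, , k, p] <- sh$phi_tag
      phi_v[, , k, p] <- sv$phi_tag
      phi_z[, , k, p] <- (sh$phi_z + sv$phi_z) / 2
      mag[, , k, p] <- (Mod(hp) + Mod(hm) + Mod(vp) + Mod(vm)) / 4
      # carry continuity only through well-supported pixels
      prev_z <- phi_z[, , k, p]
      prev_z[mag[, , k, p] <= quality_frac *
               stats::quantile(mag[, , k, p], 0.98)] <- NA
    }
  }
  thr <- quality_frac * apply(mag, 3:4, stats::quantile, probs = 0.98)
  mask <- array(FALSE, dims)
  for (k in seq_len(ns)) {
    for (p in seq_len(np)) {
      mask[, , k, p] <- mag[, , k, p] > thr[k, p]
    }
  }
  structure(list(
    phi_h = phi_h, phi_v = phi_v, phi_z = phi_z,
    magnitude = mag, mask = mask,
    acq = acq, geometry = geom,
    filter = list(shape = window, radius_frac = radius_frac,
                  flat_frac = flat_frac, quality_frac = quality_frac)
  ), class = "phase_map_stack")
}

#' @export
print.phase_map_stack <- function(x, ...) {
  cat(sprintf("Phase maps: %d slices x %d phases, %s filter (%.0f%% of |omega|)\n",
              dim(x$phi_h)[3], dim(x$phi_h)[4], x$filter$shape,
              100 * x$filter$radius_frac))
  invisible(x)
}

# Wrapped central-difference gradients of a 2D phase image (rad/mm).
# One-sided at the borders.  Tag phases need wrapping; z-phase does not, but
# wrapping is harmless for smooth fields.
phase_gradient2 <- function(phi, pixel_spacing) {
  m <- nrow(phi); n <- ncol(phi)
  gx <- matrix(NA_real_, m, n)
  gy <- matrix(NA_real_, m, n)
  gx[2:(m - 1), ] <- wrap_pi(phi[3:m, ] - phi[1:(m - 2), ]) / (2 * pixel_spacing)
  gx[1, ] <- wrap_pi(phi[2, ] - phi[1, ]) / pixel_spacing
  gx[m, ] <- wrap_pi(phi[m, ] - phi[m - 1, ]) / pixel_spacing
  gy[, 2:(n - 1)] <- wrap_pi(phi[, 3:n] - phi[, 1:(n - 2)]) / (2 * pixel_spacing)
  gy[, 1] <- wrap_pi(phi[, 2] - phi[, 1]) / pixel_spacing
  gy[, n] <- wrap_pi(phi[, n] - phi[, n - 1]) / pixel_spacing
  list(gx = gx, gy = gy)
}

# Wrapped through-stack derivative of [m, m, n_slices] phase arrays:
# central across adjacent slices, one-sided at the stack ends and wherever a
# neighbouring slice fails the quality mask (low-magnitude phase values are
# noise and would corrupt the difference); NA where no valid neighbour exists.
phase_gradient_z <- function(phi, slice_spacing, mask = NULL) {
  ns <- dim(phi)[3]
  out <- array(NA_real_, dim(phi))
  if (ns == 1) {
    out[, , 1] <- 0
    return(out)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(phi))
  for (k in seq_len(ns)) {
    up_ok <- if (k < ns) mask[, , k + 1] else array(FALSE, dim(phi)[1:2])
    dn_ok <- if (k > 1) mask[, , k - 1] else array(FALSE, dim(phi)[1:2])
    g <- array(NA_real_, dim(phi)[1:2])
    both <- up_ok & dn_ok
    if (any(both)) {
      g[both] <- wrap_pi(phi[, , k + 1] - phi[, , k - 1])[both] / (2 * slice_spacing)
    }
    uo <- up_ok & !dn_ok
    if (any(uo)) {
      g[uo] <- wrap_pi(phi[, , k + 1] - phi[, , k])[uo] / slice_spacing
    }
    do <- dn_ok & !up_ok
    if (any(do)) {
      g[do] <- wrap_pi(phi[, , k] - phi[, , k - 1])[do] / slice_spacing
    }
    out[, , k] <- g
  }
  out
}

# Bilinear interpolation of a matrix sampled at pixel_axis coordinates.
interp2 <- function(mat, ax, x, y) {
  m <- length(ax)
  px <- ax[2] - ax[1]
  fi <- (x - ax[1]) / px + 1
  fj <- (y - ax[1]) / px + 1
  i0 <- pmin(pmax(floor(fi), 1), m - 1)
  j0 <- pmin(pmax(floor(fj), 1), m - 1)
  di <- pmin(pmax(fi - i0, 0), 1)
  dj <- pmin(pmax(fj - j0, 0), 1)
  v00 <- mat[cbind(i0, j0)]
  v10 <- mat[cbind(i0 + 1, j0)]
  v01 <- mat[cbind(i0, j0 + 1)]
  v11 <- mat[cbind(i0 + 1, j0 + 1)]
  v00 * (1 - di) * (1 - dj) + v10 * di * (1 - dj) +
    v01 * (1 - di) * dj + v11 * di * dj
}

# Interpolate a wrapped phase via its complex representation; an optional
# magnitude image weights the support so low-signal (background) pixels do
# not corrupt phases interpolated near tissue boundaries.
interp_phase <- function(phi, ax, x, y, mag = NULL) {
  w <- if (is.null(mag)) 1 else mag
  re <- interp2(w * cos(phi), ax, x, y)
  im <- interp2(w * sin(phi), ax, x, y)
  atan2(im, re)
}
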