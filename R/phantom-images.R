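# Synthetic zHARP-style tagged images and LGE volumes with known ground truth.
#
# Tagged signal model (ideal complementary-tagging harmonic, no fading): at
# pixel x of the slice plane z_s and cardiac phase with activation s, the
# material point q(x) currently at x contributes
#
#   I(x) = A(x) * exp( i [ omega * q_dir(x)  +/-  kz * w(x) ] ) + noise
#
# where q_dir is the reference-position component along the tag direction,
# w = z_s - q_Z the through-plane displacement, and A a soft-edged tissue
# magnitude.  Complex Gaussian noise is added per encoding.

#' Acquisition parameters for tagged imaging
#'
#' Defaults mirror a 3T short-axis tagging protocol: 7 mm tag spacing in two
#' orthogonal in-plane directions, through-plane phase encoding at
#' `2*pi/33` rad/mm, 40 cardiac phases.
#'
#' @param tag_spacing tag period, mm.
#' @param kz through-plane (z) encoding frequency, rad/mm.
#' @param n_phases cardiac phases over one cycle.
#' @param noise_sd complex-noise SD as a fraction of tissue magnitude
#'   (0.05 = SNR 20).
#' @param es_frac end-systolic position as fraction of the cycle.
#' @return object of class `acquisition_params`.
#' @export
acquisition_params <- function(tag_spacing = 7, kz = 2 * pi / 33,
                               n_phases = 40, noise_sd = 0.05,
                               es_frac = 0.4) {
  stopifnot(tag_spacing > 0, kz > 0, n_phases >= 2, noise_sd >= 0)
  structure(list(
    tag_spacing = tag_spacing,
    omega = 2 * pi / tag_spacing,
    kz = kz,
    n_phases = as.integer(n_phases),
    noise_sd = noise_sd,
    es_frac = es_frac
  ), class = "acquisition_params")
}

validate_acquisition <- function(acq, geometry) {
  if (acq$tag_spacing <= 2 * geometry$pixel_spacing) {
    stop("tag spacing must exceed twice the pixel spacing (harmonic peak unresolvable)",
         call. = FALSE)
  }
  if (acq$kz * geometry$slice_thickness >= pi) {
    stop("kz * slice thickness must stay below pi (through-plane phase aliasing)",
         call. = FALSE)
  }
  margin <- geometry$fov / 2 - max(geometry$epi_radius)
  if (margin < 2 * acq$tag_spacing) {
    stop("image matrix must cover the epicardium with a margin of at least two tag periods",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Soft-edged tissue magnitude at material positions (partial-volume model;
# edge width in mm).
tissue_magnitude <- function(geometry, R, Z, edge = NULL) {
  edge <- edge %||% geometry$pixel_spacing
  en <- radius_at(geometry, Z, "endo")
  ep <- radius_at(geometry, Z, "epi")
  slab <- slab_range(geometry)
  smoothstep((R - en) / edge + 0.5) *
    smoothstep((ep - R) / edge + 0.5) *
    smoothstep((Z - slab[1]) / edge + 0.5) *
    smoothstep((slab[2] - Z) / edge + 0.5)
}

#' Synthesize a zHARP-style tagged image set
#'
#' Emits the four complex encodings (two tag orientations x two z-encode
#' polarities) for every slice and cardiac phase.  The material point imaged
#' at each pixel is found by Newton inversion of the analytic deformation.
#'
#' @param geometry an `lv_geometry`.
#' @param deformation a `deformation_model` on that geometry.
#' @param acq an `acquisition_params`.
#' @param seed integer seed (mandatory; the reproducibility contract).
#' @return object of class `tagged_image_set`: `images[[orientation]][[polarity]]`
#'   complex arrays `[nx, ny, n_slices, n_phases]` with orientation in
#'   `"horizontal"`/`"vertical"` (tag phase along x / y) and polarity
#'   `"plus"`/`"minus"`; plus `activation`, `acq`, `geometry`, `seed`.
#' @export
synthesize_tagged_images <- function(geometry, deformation, acq, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required (reproducibility contract)", call. = FALSE)
  }
  validate_acquisition(acq, geometry)
  m <- geometry$matrix_size
  ns <- geometry$n_slices
  np <- acq$n_phases
  s_profile <- activation_profile(np, acq$es_frac)

  ax <- pixel_axis(geometry)
  grid_xy <- cbind(rep(ax, times = m), rep(ax, each = m))

  dims <- c(m, m, ns, np)
  imgs <- list(
    horizontal = list(plus = array(0i, dims), minus = array(0i, dims)),
    vertical = list(plus = array(0i, dims), minus = array(0i, dims))
  )

  with_seed(stage_seed(seed, "tagging"), {
    for (p in seq_len(np)) {
      s <- s_profile[p]
      for (k in seq_len(ns)) {
        zs <- geometry$slice_positions[k]
        x3 <- cbind(grid_xy, zs)
        inv <- deformation$invert(x3, s)
        q <- inv$q
        Rq <- sqrt(q[, 1]^2 + q[, 2]^2)
        A <- tissue_magnitude(geometry, Rq, q[, 3])
        A[!inv$converged] <- 0
        w <- zs - q[, 3]
        phz <- acq$kz * w
        for (orient in c("horizontal", "vertical")) {
          ph_tag <- acq$omega * q[, if (orient == "horizontal") 1 else 2]
          for (pol in c("plus", "minus")) {
            ph <- ph_tag + if (pol == "plus") phz else -phz
            sig <- A * exp(1i * ph)
            if (acq$noise_sd > 0) {
              sig <- sig + stats::rnorm(m * m, sd = acq$noise_sd) +
                1i * stats::rnorm(m * m, sd = acq$noise_sd)
            }
            imgs[[orient]][[pol]][, , k, p] <- matrix(sig, m, m)
          }
        }
      }
    }
  })

  structure(list(
    images = imgs, acq = acq, geometry = geometry,
    activation = s_profile, seed = seed
  ), class = "tagged_image_set")
}

#' @export
print.tagged_image_set <- function(x, ...) {
  cat(sprintf("Tagged image set: %dx%d px, %d slices, %d phases, 4 encodings, SNR %.0f\n",
              x$geometry$matrix_size, x$geometry$matrix_size,
              x$geometry$n_slices, x$acq$n_phases,
              if (x$acq$noise_sd > 0) 1 / x$acq$noise_sd else Inf))
  invisible(x)
}

#' Ground-truth fields of the phantom at one cardiac phase
#'
#' Reference positions, displacements and analytic Green-Lagrange tensors of
#' the material points imaged at each pixel, by Newton inversion of the
#' deformation and closed-form differentiation.
#'
#' @param geometry an `lv_geometry`.
#' @param deformation a `deformation_model`.
#' @param s activation value of the phase (0 = reference).
#' @return list with arrays `q` (`[m, m, n_slices, 3]` reference mm),
#'   `displacement` (same layout), `E_cyl` (`[m, m, n_slices, 6]`, components
#'   `Err, Ecc, Ell, Erc, Erl, Ecl` in the material cylindrical frame),
#'   `E_cart` (`[m, m, n_slices, 6]`, components `xx, yy, zz, xy, xz, yz` in
#'   scanner coordinates), `mask` (tissue), `theta_rel` (material angle from
#'   ARVP).
#' @export
phantom_ground_truth <- function(geometry, deformation, s) {
  m <- geometry$matrix_size
  ns <- geometry$n_slices
  ax <- pixel_axis(geometry)
  grid_xy <- cbind(rep(ax, times = m), rep(ax, each = m))

  q_arr <- array(NA_real_, c(m, m, ns, 3))
  disp <- array(NA_real_, c(m, m, ns, 3))
  E_arr <- array(NA_real_, c(m, m, ns, 6))
  Ec_arr <- array(NA_real_, c(m, m, ns, 6))
  mask <- array(FALSE, c(m, m, ns))
  th_rel <- array(NA_real_, c(m, m, ns))

  for (k in seq_len(ns)) {
    zs <- geometry$slice_positions[k]
    x3 <- cbind(grid_xy, zs)
    inv <- deformation$invert(x3, s)
    q <- inv$q
    Rq <- sqrt(q[, 1]^2 + q[, 2]^2)
    en <- radius_at(geometry, q[, 3], "endo")
    ep <- radius_at(geometry, q[, 3], "epi")
    slab <- slab_range(geometry)
    tissue <- inv$converged & Rq >= en & Rq <= ep &
      q[, 3] >= slab[1] & q[, 3] <= slab[2]
    E <- deformation$strain(q, s, frame = "cylindrical")
    for (d in 1:3) {
      q_arr[, , k, d] <- matrix(q[, d], m, m)
      disp[, , k, d] <- matrix(x3[, d] - q[, d], m, m)
    }
    # symmetric components: Err, Ecc, Ell, Erc, Erl, Ecl
    comp <- cbind(E[, 1], E[, 5], E[, 9], E[, 2], E[, 3], E[, 6])
    for (d in 1:6) E_arr[, , k, d] <- matrix(comp[, d], m, m)
    Ec <- deformation$strain(q, s, frame = "cartesian")
    compc <- cbind(Ec[, 1], Ec[, 5], Ec[, 9], Ec[, 2], Ec[, 3], Ec[, 6])
    for (d in 1:6) Ec_arr[, , k, d] <- matrix(compc[, d], m, m)
    mask[, , k] <- matrix(tissue, m, m)
    th_rel[, , k] <- matrix(
      wrap_2pi(atan2(q[, 2], q[, 1]) - geometry$arvp_angle), m, m)
  }
  list(q = q_arr, displacement = disp, E_cyl = E_arr, E_cart = Ec_arr,
       mask = mask, theta_rel = th_rel, s = s)
}

#' Synthesize a late-gadolinium-enhancement volume
#'
#' Thin-slice (default 3 mm) scalar volume on the phantom's in-plane grid:
#' remote myocardium at `remote_mean`, hyperenhanced scar exactly where the
#' region map's transmurality profile places infarct, Gaussian noise on top.
#'
#' @param geometry an `lv_geometry`.
#' @param regions a `region_map` (or `NULL` for no enhancement).
#' @param seed integer seed.
#' @param slice_thickness LGE slice thickness, mm.
#' @param n_slices number of LGE slices (defaults to covering the stack).
#' @param remote_mean,remote_sd remote-myocardium intensity model.
#' @param infarct_mean hyperenhanced intensity.
#' @param background_mean background (non-myocardial) intensity.
#' @return object of class `lge_volume`: `data` array `[m, m, n_slices]`,
#'   `z` slice positions, `myo_mask`, `infarct_truth`, intensity parameters.
#' @export
synthesize_lge <- function(geometry, regions, seed, slice_thickness = 3,
                           n_slices = NULL, remote_mean = 100, remote_sd = 8,
                           infarct_mean = 300, background_mean = 0) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required (reproducibility contract)", call. = FALSE)
  }
  stack <- stack_range(geometry)
  n_slices <- n_slices %||% ceiling(diff(stack) / slice_thickness)
  z <- stack[1] + slice_thickness * (seq_len(n_slices) - 0.5)
  m <- geometry$matrix_size
  ax <- pixel_axis(geometry)
  dist <- sqrt(outer(ax^2, ax^2, "+"))
  theta <- wrap_2pi(atan2(rep(ax, each = m), rep(ax, times = m)) -
                      geometry$arvp_angle)
  theta <- matrix(theta, m, m)  # [i, j] corresponds to x = ax[i], y = ax[j]

  data <- array(0, c(m, m, n_slices))
  myo <- array(FALSE, c(m, m, n_slices))
  scar <- array(FALSE, c(m, m, n_slices))
  for (k in seq_len(n_slices)) {
    en <- radius_at(geometry, z[k], "endo")
    ep <- radius_at(geometry, z[k], "epi")
    inmyo <- dist >= en & dist <= ep
    depth <- (dist - en) / pmax(ep - en, 1e-9)
    is_scar <- inmyo
    if (!is.null(regions)) {
      is_scar <- inmyo & infarct_truth(regions, theta, z[k], depth)
    } else {
      is_scar[] <- FALSE
    }
    sl <- matrix(background_mean, m, m)
    sl[inmyo] <- remote_mean
    sl[is_scar] <- infarct_mean
    data[, , k] <- sl
    myo[, , k] <- inmyo
    scar[, , k] <- is_scar
  }
  if (remote_sd > 0) {
    data <- data + with_seed(stage_seed(seed, "lge"),
                             array(stats::rnorm(length(data), sd = remote_sd),
                                   dim = dim(data)))
  }
  structure(list(
    data = data, z = z, slice_thickness = slice_thickness,
    myo_mask = myo, infarct_truth = scar,
    remote_mean = remote_mean, remote_sd = remote_sd,
    infarct_mean = infarct_mean, geometry = geometry, seed = seed
  ), class = "lge_volume")
}

#' @export
print.lge_volume <- function(x, ...) {
  cat(sprintf("LGE volume: %d slices x %.0f mm, scar fraction %.1f%% of myocardium\n",
              length(x$z), x$slice_thickness,
              100 * sum(x$infarct_truth) / max(1, sum(x$myo_mask))))
  invisible(x)
}

#' Scaled-down phantom configuration for fast experimentation
#'
#' The physical parameters (tag spacing, pixel size, slice thickness,
#' z-encoding, contractility calibration) match the full-size defaults; only
#' the matrix, slice count and phase count are reduced so a full synthesis
#' plus analysis runs in seconds.
#'
#' @param n_slices,matrix_size,n_phases reduced dimensions.
#' @param noise_sd complex-noise level (0.05 = SNR 20).
#' @param with_infarct include the default infarct region map.
#' @return list with `geometry`, `regions`, `deformation`, `acq`.
#' @export
small_phantom_config <- function(n_slices = 10, matrix_size = 64, n_phases = 10,
                                 noise_sd = 0.05, with_infarct = TRUE) {
  geometry <- build_lv_geometry(
    n_slices = n_slices, slice_thickness = 8,
    endo_radius = 16, epi_radius = 24, apex_scale = 0.6,
    pixel_spacing = 1.25, matrix_size = matrix_size, arvp_angle = 0)
  regions <- if (with_infarct) region_map(geometry) else NULL
  deformation <- make_deformation(geometry, regions)
  acq <- acquisition_params(n_phases = n_phases, noise_sd = noise_sd)
  list(geometry = geometry, regions = regions,
       deformation = deformation, acq = acq)
}
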