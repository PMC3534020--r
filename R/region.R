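# Regional viability map: where the infarct sits (angular span, longitudinal
# extent, transmural depth) and how contractility is scaled there.  The
# contractility field rho(theta, Z) is smooth (cubic smoothstep shoulders) so
# the deformation stays analytically differentiable across region borders.

#' Define the infarct region and contractility field
#'
#' The infarct occupies the half-open angular interval `[theta1, theta2)`
#' (radians counterclockwise from the ARVP direction) on slices from the apex
#' up to `z_top`, with transmural depth fraction `transmurality` measured from
#' the endocardium.  Contractility is `rho_infarct` on the infarct plateau and
#' recovers smoothly to 1 over `transition` radians (the mechanical border
#' zone) and over `z_transition` mm along the long axis.
#'
#' @param geometry an `lv_geometry`.
#' @param theta1,theta2 infarct angular borders, radians from ARVP (half-open
#'   interval, may wrap through zero).
#' @param rho_infarct contractility multiplier on the infarct plateau, in
#'   `[0, 1)`.
#' @param transition angular width of the border-zone taper for the in-plane
#'   contraction, radians.
#' @param transition_l angular taper width of the longitudinal
#'   (atrioventricular-plane descent) deficit, radians.  Long-axis motion is
#'   smoothed circumferentially by fiber continuity, so its border zone is
#'   wider than the in-plane one.
#' @param margin_l inward shift (radians) of the longitudinal-deficit bump
#'   borders relative to the scar borders: places the steepest part of the
#'   descent-deficit transition inside the flanking (adjacent) zone rather
#'   than in remote myocardium.
#' @param transmurality infarct depth as a fraction of wall thickness.
#' @param z_top long-axis position (mm) of the top of the infarct; defaults
#'   to the slice position nearest 60% of the stack (apical-to-mid infarct,
#'   scar border on a slice plane).
#' @param z_transition longitudinal taper width of the in-plane deficit, mm
#'   (default two slice thicknesses).  Tapers are linear with smoothly
#'   rounded ends (rounding half-width `z_round`), so through-plane gradients
#'   stay representable by centred differences across adjacent slices.
#' @param z_top_l,z_transition_l onset and taper width (mm) of the
#'   longitudinal (descent-deficit) column; the accumulated deficit makes
#'   this field's effective border sit lower and stretch further than the
#'   in-plane one (defaults: two slice thicknesses below `z_top`, four slice
#'   thicknesses wide).
#' @param z_round rounding half-width (mm) of the taper kinks.
#' @return object of class `region_map`.
#' @export
region_map <- function(geometry, theta1 = 0, theta2 = 150 * pi / 180,
                       rho_infarct = 0.18, transition = 40 * pi / 180,
                       transition_l = 105 * pi / 180,
                       margin_l = 0,
                       transmurality = 0.95, z_top = NULL,
                       z_transition = NULL, z_top_l = NULL,
                       z_transition_l = NULL, z_round = 2) {
  z_transition <- z_transition %||% (2 * geometry$slice_thickness)
  z_transition_l <- z_transition_l %||% (4 * geometry$slice_thickness)
  stopifnot(rho_infarct >= 0, rho_infarct < 1,
            transmurality >= 0, transmurality <= 1,
            transition > 0, z_transition > 0, z_round > 0,
            2 * z_round < z_transition)
  z_max <- max(geometry$slice_positions)
  if (is.null(z_top)) {
    z_top <- geometry$slice_positions[
      which.min(abs(geometry$slice_positions - 0.6 * z_max))]
  }
  z_top_l <- z_top_l %||% (z_top - 2 * geometry$slice_thickness)
  structure(list(
    theta1 = wrap_2pi(theta1), theta2 = wrap_2pi(theta2),
    span = wrap_2pi(theta2 - theta1),
    rho_infarct = rho_infarct,
    transition = transition,
    transition_l = transition_l,
    margin_l = margin_l,
    transmurality = transmurality,
    z_top = z_top,
    z_transition = z_transition,
    z_top_l = z_top_l,
    z_transition_l = z_transition_l,
    z_round = z_round,
    geometry = geometry
  ), class = "region_map")
}

# Smoothed piecewise-linear ramp: 0 below 0, 1 above 1, linear in between,
# with C1 quadratic rounding of half-width eps at both kinks.
smooth_ramp <- function(u, eps) {
  out <- pmin(pmax(u, 0), 1)
  lo <- abs(u) < eps
  out[lo] <- (u[lo] + eps)^2 / (4 * eps)
  hi <- abs(u - 1) < eps
  out[hi] <- 1 - (1 - u[hi] + eps)^2 / (4 * eps)
  out
}

smooth_ramp_deriv <- function(u, eps) {
  out <- as.numeric(u > 0 & u < 1)
  lo <- abs(u) < eps
  out[lo] <- (u[lo] + eps) / (2 * eps)
  hi <- abs(u - 1) < eps
  out[hi] <- (1 - u[hi] + eps) / (2 * eps)
  out
}

# Angular distance outside the infarct span and its derivative sign.
# Returns delta = 0 inside [theta1, theta2); outside, distance to the nearest
# border, with ddelta/dtheta in {-1, +1}.
.angular_outside <- function(rm, theta_rel) {
  u <- wrap_2pi(theta_rel - rm$theta1)
  inside <- u < rm$span
  d2 <- u - rm$span        # distance past theta2
  d1 <- 2 * pi - u         # distance short of theta1
  delta <- ifelse(inside, 0, pmin(d1, d2))
  dsign <- ifelse(inside, 0, ifelse(d2 < d1, 1, -1))
  list(delta = delta, dsign = dsign)
}

# In-plane contractility field rho(theta_rel, Z) with analytic partial
# derivatives; theta_rel is measured from the ARVP direction.
rho_eval <- function(rm, theta_rel, z) {
  if (is.null(rm)) {
    n <- max(length(theta_rel), length(z))
    return(list(rho = rep(1, n), dtheta = rep(0, n), dz = rep(0, n)))
  }
  ang <- .angular_outside(rm, theta_rel)
  ut <- ang$delta / rm$transition
  btheta <- 1 - smoothstep(ut)
  dbtheta <- -smoothstep_deriv(ut) / rm$transition * ang$dsign

  uz <- (z - rm$z_top) / rm$z_transition
  epsu <- rm$z_round / rm$z_transition
  bz <- 1 - smooth_ramp(uz, epsu)
  dbz <- -smooth_ramp_deriv(uz, epsu) / rm$z_transition

  depth <- 1 - rm$rho_infarct
  list(
    rho = 1 - depth * btheta * bz,
    dtheta = -depth * dbtheta * bz,
    dz = -depth * btheta * dbz
  )
}

# Antiderivative of smooth_ramp(u, eps) from -eps to v (piecewise cubic).
.ramp_integral <- function(v, eps) {
  lo2 <- 2 * eps^2 / 3
  hi1 <- lo2 + (1 - 2 * eps) / 2           # value at u = 1 - eps
  hi2 <- hi1 + 2 * eps - lo2               # value at u = 1 + eps
  out <- numeric(length(v))
  a <- v > -eps & v < eps
  out[a] <- (v[a] + eps)^3 / (12 * eps)
  b <- v >= eps & v <= 1 - eps
  out[b] <- lo2 + (v[b]^2 - eps^2) / 2
  c <- v > 1 - eps & v < 1 + eps
  out[c] <- hi1 + (v[c] - 1 + eps) + ((1 - v[c] + eps)^3 - 8 * eps^3) / (12 * eps)
  d <- v >= 1 + eps
  out[d] <- hi2 + (v[d] - 1 - eps)
  out
}

# Longitudinal-deficit kernel: the regional long-axis displacement deficit
# accumulates the local shortening deficit along the scar column,
# K(Z) = integral_{z0}^{Z} up(t) bz(t) dt, where `up` ramps in across the
# apical cap (the cap tip moves with the global field, so the
# sector-differential vanishes at the apex) and `bz` tapers out above the
# scar.  The two transitions have disjoint support, so the integrand equals
# up + bz - 1 and the integral stays closed-form.  Returns the angular bump
# and its derivative plus K and dK/dZ.
long_deficit_eval <- function(rm, theta_rel, z) {
  rml <- rm
  rml$theta1 <- wrap_2pi(rm$theta1 + rm$margin_l)
  rml$span <- max(rm$span - 2 * rm$margin_l, 0.1)
  ang <- .angular_outside(rml, theta_rel)
  ut <- ang$delta / rm$transition_l
  btheta <- 1 - smoothstep(ut)
  dbtheta <- -smoothstep_deriv(ut) / rm$transition_l * ang$dsign

  geom <- rm$geometry
  z0 <- slab_range(geom)[1]
  w_up <- (geom$apex_extension %||% geom$slice_thickness) +
    geom$slice_thickness / 2
  eps_up <- rm$z_round / w_up
  vu <- (z - z0) / w_up
  vu0 <- 0
  int_up <- w_up * (.ramp_integral(vu, eps_up) - .ramp_integral(vu0, eps_up))

  W <- rm$z_transition_l
  epsu <- rm$z_round / W
  v <- (z - rm$z_top_l) / W
  v0 <- (z0 - rm$z_top_l) / W
  int_bz <- (z - z0) - W * (.ramp_integral(v, epsu) - .ramp_integral(v0, epsu))

  K <- int_up + int_bz - (z - z0)
  Kp <- smooth_ramp(vu, eps_up) * (1 - smooth_ramp(v, epsu))
  list(btheta = btheta, dbtheta = dbtheta, K = K, Kp = Kp)
}

# Ground-truth infarct membership (the hyperenhancing scar): inside the
# angular plateau, below z_top (plus nothing of the taper), and within the
# transmural depth fraction from the endocardium.
infarct_truth <- function(rm, theta_rel, z, depth_frac) {
  ang <- .angular_outside(rm, theta_rel)
  (ang$delta == 0) & (z <= rm$z_top) & (depth_frac <= rm$transmurality)
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf(
    "Region map: infarct span [%.0f, %.0f) deg from ARVP, rho %.2f, taper %.0f deg, transmurality %.0f%%, z <= %.0f mm\n",
    x$theta1 * 180 / pi, x$theta2 * 180 / pi, x$rho_infarct,
    x$transition * 180 / pi, 100 * x$transmurality, x$z_top))
  invisible(x)
}
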