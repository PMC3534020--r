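# Analytic myocardial deformation model.
#
# In material cylindrical coordinates (R, Theta, Z) the end-systolic map with
# activation s(t) in [0, 1] and regional contractility rho(Theta, Z) is
#
#   r^2   = R^2 - [ DeltaA(Z) + kappa (R^2 - Re(Z)^2) ] * s * rho
#   theta = Theta + tau * Z * s * rho
#   z     = zf + (Z - zf) (1 - lambda_l * s * rho)
#
# with DeltaA = Re^2 (1 - c^2) the endocardial area pulled in (c the
# endocardial contraction fraction), kappa a wall-compressibility parameter
# (kappa = 0 recovers exact in-plane area conservation of the annulus), tau
# the base-to-apex twist rate and zf the longitudinally fixed plane.  All
# partial derivatives are available in closed form, so the ground-truth
# Green-Lagrange tensor is analytic.

#' Closed-form calibration of the contraction parameters
#'
#' Solves the contraction fraction `c`, wall compressibility `kappa` and
#' longitudinal shortening `lambda_l` so that the analytic mid-wall
#' end-systolic strains in fully contractile tissue match the target
#' circumferential, radial and longitudinal strains.
#'
#' @param geometry an `lv_geometry`.
#' @param targets named vector with `Ecc`, `Err`, `Ell` in percent (defaults:
#'   the packaged healthy-baseline calibration).
#' @return list with `contraction`, `kappa`, `lambda_l` and the implied
#'   mid-wall stretches.
#' @export
calibrate_deformation <- function(geometry, targets = NULL) {
  if (is.null(targets)) {
    cal <- segment_strain_calibration()
    cell <- cal[cal$class == "healthy", ]
    targets <- stats::setNames(cell$mean, cell$measure)[c("Ecc", "Err", "Ell")]
  }
  lam_c2 <- 1 + 2 * targets[["Ecc"]] / 100
  lam_r2 <- 1 + 2 * targets[["Err"]] / 100
  lam_l2 <- 1 + 2 * targets[["Ell"]] / 100
  if (lam_c2 <= 0 || lam_r2 <= 0 || lam_l2 <= 0) {
    stop("strain targets below -50% are not realisable", call. = FALSE)
  }
  kappa <- 1 - sqrt(lam_c2 * lam_r2)
  re <- geometry$endo_radius[geometry$n_slices]
  rp <- geometry$epi_radius[geometry$n_slices]
  m <- ((re + rp) / 2)^2 / re^2
  c2 <- 1 - m * (1 - lam_c2) + kappa * (m - 1)
  if (c2 <= 0 || c2 >= 1 || kappa >= 1) {
    stop("calibration targets produce a non-invertible contraction", call. = FALSE)
  }
  list(contraction = sqrt(c2), kappa = kappa, lambda_l = 1 - sqrt(lam_l2),
       lambda_c = sqrt(lam_c2), lambda_r = sqrt(lam_r2))
}

# Longitudinal plateau scaling of the infarct, solved from the pooled
# post-infarct longitudinal strain of the packaged calibration.
.default_rho_infarct_l <- function(lambda_l) {
  cal <- segment_strain_calibration()
  ell <- mean(cal$mean[cal$class == "infarct" & cal$measure == "Ell"])
  lam <- sqrt(1 + 2 * ell / 100)
  (1 - lam) / lambda_l
}

#' Build the analytic deformation model
#'
#' @param geometry an `lv_geometry`.
#' @param regions optional `region_map`; `NULL` means uniformly contractile
#'   (`rho == 1` everywhere).
#' @param contraction endocardial contraction fraction `c` (end-systolic endo
#'   radius / reference endo radius); default from [calibrate_deformation()].
#' @param kappa wall compressibility (0 = in-plane incompressible annulus).
#' @param lambda_l longitudinal shortening fraction at end-systole.
#' @param rho_infarct_l longitudinal contractility on the infarct plateau
#'   (defaults to the value reproducing the packaged post-infarct
#'   longitudinal strain).  Longitudinal shortening is modelled as a global
#'   mid-anchored term plus an apex-anchored regional deficit that
#'   accumulates through the infarct and persists toward the base (a
#'   regionally reduced atrioventricular-plane descent), so local strain is
#'   exact and no artificial shear concentrates at the apical cap.
#' @param twist_total total base-to-apex twist at end-systole, radians.
#' @param z_fix_frac long-axis position of the longitudinally fixed plane,
#'   as a fraction of the stack extent.  The mid-ventricular default keeps
#'   the through-plane displacement within the unambiguous z-encoding range
#'   (|w| < pi/kz) over the whole stack.
#' @return object of class `deformation_model` exposing `map(q, s)`,
#'   `gradient(q, s)`, `strain(q, s)`, `invert(x, s)`.
#' @export
make_deformation <- function(geometry, regions = NULL,
                             contraction = NULL, kappa = NULL,
                             lambda_l = NULL, rho_infarct_l = NULL,
                             twist_total = 0.15, z_fix_frac = 0.5) {
  cal <- calibrate_deformation(geometry)
  cc <- contraction %||% cal$contraction
  kp <- kappa %||% cal$kappa
  ll <- lambda_l %||% cal$lambda_l
  rl <- rho_infarct_l %||% .default_rho_infarct_l(ll)
  dep_l <- 1 - rl
  if (cc <= 0 || cc >= 1 || kp >= 1 || ll >= 1) {
    stop("deformation parameters produce a non-invertible map", call. = FALSE)
  }
  z_max <- max(geometry$slice_positions)
  tau <- if (z_max > 0) twist_total / z_max else 0
  zf <- z_fix_frac * z_max
  e_slope <- radius_slope(geometry, "endo")

  arvp <- geometry$arvp_angle

  # Evaluate map + all cylindrical partials at material points q (n x 3, mm).
  core <- function(q, s) {
    x <- q[, 1]; y <- q[, 2]; z0 <- q[, 3]
    R <- sqrt(x^2 + y^2)
    Th <- atan2(y, x)
    re <- radius_at(geometry, z0, "endo")
    rho <- rho_eval(regions, wrap_2pi(Th - arvp), z0)
    g <- s * rho$rho
    dA <- re^2 * (1 - cc^2)
    D <- dA + kp * (R^2 - re^2)
    r2 <- R^2 - D * g
    r <- sqrt(pmax(r2, 1e-9))
    dDdZ <- 2 * re * e_slope * (1 - cc^2 - kp)

    if (is.null(regions)) {
      zdef <- list(btheta = 0, dbtheta = 0, K = 0, Kp = 0)
    } else {
      zdef <- long_deficit_eval(regions, wrap_2pi(Th - arvp), z0)
    }
    # twist is uniform (not regionally scaled): torsion is transmitted
    # through the stiff scar as near-rigid rotation, and a regionally scaled
    # twist would imprint a differential-torsion shear on the flanks far
    # beyond anything reported in vivo
    list(
      R = R, Th = Th, rho = rho, g = g, D = D, r = r,
      theta = Th + tau * z0 * s,
      z = zf + (z0 - zf) * (1 - ll * s) +
        ll * s * dep_l * zdef$btheta * zdef$K,
      r_R = R * (1 - kp * g) / r,
      r_T = -(D * s * rho$dtheta) / (2 * r),
      r_Z = -(g * dDdZ + D * s * rho$dz) / (2 * r),
      t_T = 1,
      t_Z = tau * s,
      z_T = ll * s * dep_l * zdef$dbtheta * zdef$K,
      z_Z = 1 - ll * s + ll * s * dep_l * zdef$btheta * zdef$Kp
    )
  }

  map <- function(q, s) {
    q <- rbind(q)
    cc_ <- core(q, s)
    cbind(cc_$r * cos(cc_$theta), cc_$r * sin(cc_$theta), cc_$z)
  }

  # Deformation gradient in the material cylindrical frame (rows follow the
  # deformed r/theta/z directions, columns the material R/Theta/Z directions).
  gradient_cyl <- function(q, s) {
    q <- rbind(q)
    cc_ <- core(q, s)
    R <- cc_$R
    cbind(
      cc_$r_R, 0, 0,                                    # column d/dR
      cc_$r_T / R, (cc_$r / R) * cc_$t_T, cc_$z_T / R,  # column (1/R) d/dTheta
      cc_$r_Z, cc_$r * cc_$t_Z, cc_$z_Z                 # column d/dZ
    )
  }

  gradient <- function(q, s, frame = c("cartesian", "cylindrical")) {
    frame <- match.arg(frame)
    q <- rbind(q)
    Fc <- gradient_cyl(q, s)
    if (frame == "cylindrical") return(Fc)
    cc_ <- core(q, s)
    rot <- function(a) cbind(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1)
    mat3_mat(mat3_mat(rot(cc_$theta), Fc), .mat3_t(rot(cc_$Th)))
  }

  strain <- function(q, s, frame = c("cylindrical", "cartesian")) {
    frame <- match.arg(frame)
    Fm <- gradient(q, s, frame = if (frame == "cylindrical") "cylindrical" else "cartesian")
    E <- mat3_crossprod(Fm)
    E[, c(1, 5, 9)] <- E[, c(1, 5, 9)] - 1
    E / 2
  }

  invert <- function(x, s, max_iter = 25, tol = 1e-9) {
    x <- rbind(x)
    q <- x
    ok <- rep(TRUE, nrow(x))
    for (it in seq_len(max_iter)) {
      res <- map(q, s) - x
      err <- sqrt(rowSums(res^2))
      active <- ok & err > tol
      if (!any(active)) break
      Fm <- gradient(q[active, , drop = FALSE], s)
      iv <- inv3x3(Fm)
      bad <- !is.finite(iv$det) | abs(iv$det) < 1e-12
      step <- mat3_vec(iv$inv, res[active, , drop = FALSE])
      step[bad, ] <- 0
      ok[active][bad] <- FALSE
      q[active, ] <- q[active, ] - step
    }
    res <- map(q, s) - x
    ok <- ok & sqrt(rowSums(res^2)) < 1e-6
    list(q = q, converged = ok)
  }

  structure(list(
    map = map, gradient = gradient, strain = strain, invert = invert,
    params = list(contraction = cc, kappa = kp, lambda_l = ll,
                  rho_infarct_l = rl, twist_total = twist_total,
                  tau = tau, z_fix = zf),
    geometry = geometry, regions = regions
  ), class = "deformation_model")
}

# Transpose of stacked 3x3 matrices in n x 9 column-major layout.
.mat3_t <- function(m) {
  m[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
}

#' @export
print.deformation_model <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Deformation model: contraction %.3f, kappa %.3f, lambda_l %.3f, twist %.2f rad, regions: %s\n",
    p$contraction, p$kappa, p$lambda_l, p$twist_total,
    if (is.null(x$regions)) "none (uniform)" else "infarct map"))
  invisible(x)
}

#' Cardiac activation time profile
#'
#' Smooth activation `s(t)` over one cardiac cycle: 0 at the reference
#' (mid-diastolic) phase, 1 at end-systole, returning to 0 at the last phase.
#'
#' @param n_phases number of cardiac phases.
#' @param es_frac position of end-systole as a fraction of the cycle.
#' @return numeric vector of length `n_phases` in `[0, 1]`.
#' @export
activation_profile <- function(n_phases, es_frac = 0.4) {
  stopifnot(n_phases >= 2, es_frac > 0, es_frac < 1)
  u <- seq(0, 1, length.out = n_phases)
  ifelse(u <= es_frac,
         0.5 - 0.5 * cos(pi * u / es_frac),
         0.5 + 0.5 * cos(pi * (u - es_frac) / (1 - es_frac)))
}
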