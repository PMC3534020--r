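# Per-pixel 3D strain from the three phase encodings.
#
# The wrapped spatial gradients of the two tag phases and of the recovered
# reference long-axis coordinate are, up to the encoding matrix, the rows of
# the inverse deformation gradient: phi_h(x)/omega and phi_v(x)/omega are the
# reference x/y coordinates (mod one tag period — irrelevant after
# differentiation) and z_s - phi_z(x)/kz is the reference z.  Inverting
# pixelwise gives F, and E = (F'F - I)/2 the Green-Lagrange tensor.

#' Inverse deformation gradient field from phase maps
#'
#' In-plane derivatives use wrapped central differences; through-plane
#' derivatives use centred differences across adjacent slices (one-sided at
#' the stack ends).  Pixels with `|det| outside [0.2, 5]` are invalidated as
#' non-physical.
#'
#' @param maps a `phase_map_stack`.
#' @param phase cardiac phase index.
#' @return list: `f_inv` (`[m, m, ns, 9]`, pixelwise 3x3 column-major),
#'   `det`, logical `valid`.
#' @export
deformation_gradient_inverse <- function(maps, phase) {
  stopifnot(inherits(maps, "phase_map_stack"))
  geom <- maps$geometry
  px <- geom$pixel_spacing
  dz <- geom$slice_thickness
  om <- maps$acq$omega
  kz <- maps$acq$kz
  m <- geom$matrix_size
  ns <- geom$n_slices

  ph <- maps$phi_h[, , , phase, drop = FALSE]; dim(ph) <- c(m, m, ns)
  pv <- maps$phi_v[, , , phase, drop = FALSE]; dim(pv) <- c(m, m, ns)
  pz <- maps$phi_z[, , , phase, drop = FALSE]; dim(pz) <- c(m, m, ns)
  msk <- maps$mask[, , , phase, drop = FALSE]; dim(msk) <- c(m, m, ns)

  f_inv <- array(NA_real_, c(m, m, ns, 9))
  gzh <- phase_gradient_z(ph, dz, msk)
  gzv <- phase_gradient_z(pv, dz, msk)
  gzz <- phase_gradient_z(pz, dz, msk)
  for (k in seq_len(ns)) {
    gh <- phase_gradient2(ph[, , k], px)
    gv <- phase_gradient2(pv[, , k], px)
    gz <- phase_gradient2(pz[, , k], px)
    # rows: reference-coordinate gradients; columns: spatial x, y, z
    f_inv[, , k, 1] <- gh$gx / om
    f_inv[, , k, 2] <- gv$gx / om
    f_inv[, , k, 3] <- -gz$gx / kz
    f_inv[, , k, 4] <- gh$gy / om
    f_inv[, , k, 5] <- gv$gy / om
    f_inv[, , k, 6] <- -gz$gy / kz
    f_inv[, , k, 7] <- gzh[, , k] / om
    f_inv[, , k, 8] <- gzv[, , k] / om
    f_inv[, , k, 9] <- 1 - gzz[, , k] / kz
  }
  fm <- matrix(f_inv, ncol = 9)
  det <- inv3x3(fm)$det
  det_arr <- array(det, c(m, m, ns))
  valid <- msk & is.finite(det_arr) & abs(det_arr) >= 0.2 & abs(det_arr) <= 5
  list(f_inv = f_inv, det = det_arr, valid = valid)
}

#' Green-Lagrange strain tensors from an inverse-gradient field
#'
#' `E = (F'F - I)/2` with `F = (F_inv)^-1`, symmetrised numerically; pixels
#' with singular `F_inv` are invalidated.
#'
#' @param grad result of [deformation_gradient_inverse()].
#' @return object of class `strain_tensor_field`: `E` (`[m, m, ns, 6]` with
#'   components `Exx, Eyy, Ezz, Exy, Exz, Eyz`), logical `valid`.
#' @export
green_strain <- function(grad) {
  dims <- dim(grad$f_inv)
  m <- dims[1]; ns <- dims[3]
  fm <- matrix(grad$f_inv, ncol = 9)
  iv <- inv3x3(fm)
  ok <- is.finite(iv$det) & abs(iv$det) > 1e-12
  Fm <- iv$inv
  Fm[!ok, ] <- NA_real_
  Em <- mat3_crossprod(Fm)
  Em[, c(1, 5, 9)] <- Em[, c(1, 5, 9)] - 1
  Em <- Em / 2
  # numerical symmetrisation
  sym <- cbind(Em[, 1], Em[, 5], Em[, 9],
               (Em[, 2] + Em[, 4]) / 2,
               (Em[, 3] + Em[, 7]) / 2,
               (Em[, 6] + Em[, 8]) / 2)
  # physiological bound: |strain| beyond 100% is non-physical noise
  sane <- ok & apply(abs(sym) < 1, 1, all)
  E <- array(sym, c(m, m, ns, 6))
  structure(list(E = E, valid = grad$valid & array(sane, c(m, m, ns))),
            class = "strain_tensor_field")
}

#' Local anatomical basis from the epicardial contour
#'
#' For each query point the radial direction is the outward in-plane normal
#' of the nearest epicardial contour vertex (central-difference tangent), the
#' longitudinal direction is the slice normal orthogonalised against it, and
#' the circumferential direction completes the right-handed triad
#' `e_c = e_l x e_r`.
#'
#' @param epi_contour n x 2 closed polyline (mm), counterclockwise or
#'   clockwise; must be star-shaped about its centroid.
#' @param slice_normal 3-vector, default `c(0, 0, 1)`.
#' @param points q x 2 matrix of in-plane query positions (mm).
#' @return list of q x 3 matrices `e_c`, `e_l`, `e_r`.
#' @export
local_basis <- function(epi_contour, slice_normal = c(0, 0, 1), points) {
  epi_contour <- as.matrix(epi_contour)
  points <- rbind(points)
  n <- nrow(epi_contour)
  stopifnot(n >= 8)
  ctr <- colMeans(epi_contour)
  ang <- atan2(epi_contour[, 2] - ctr[2], epi_contour[, 1] - ctr[1])
  dang <- wrap_pi(diff(c(ang, ang[1])))
  if (!(all(dang > 0) || all(dang < 0))) {
    stop("degenerate (non-star-shaped / self-intersecting) epicardial contour",
         call. = FALSE)
  }

  nx <- numeric(n); ny <- numeric(n)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  tx <- epi_contour[ip, 1] - epi_contour[im, 1]
  ty <- epi_contour[ip, 2] - epi_contour[im, 2]
  len <- sqrt(tx^2 + ty^2)
  nx <- ty / len
  ny <- -tx / len
  outward <- nx * (epi_contour[, 1] - ctr[1]) +
    ny * (epi_contour[, 2] - ctr[2])
  flip <- outward < 0
  nx[flip] <- -nx[flip]
  ny[flip] <- -ny[flip]

  # nearest contour vertex per query point: pre-select by angle about the
  # centroid, then take the exact nearest within a window
  ord <- order(ang)
  ang_sorted <- ang[ord]
  qa <- atan2(points[, 2] - ctr[2], points[, 1] - ctr[1])
  pos <- findInterval(qa, ang_sorted)
  win <- -6:6
  idx <- vapply(seq_len(nrow(points)), function(i) {
    cand <- ord[((pos[i] + win - 1) %% n) + 1]
    d2 <- (points[i, 1] - epi_contour[cand, 1])^2 +
      (points[i, 2] - epi_contour[cand, 2])^2
    cand[which.min(d2)]
  }, integer(1))
  e_r <- cbind(nx[idx], ny[idx], 0)

  sn <- slice_normal / sqrt(sum(slice_normal^2))
  e_l <- matrix(sn, nrow(points), 3, byrow = TRUE)
  proj <- e_l[, 1] * e_r[, 1] + e_l[, 2] * e_r[, 2] + e_l[, 3] * e_r[, 3]
  e_l <- e_l - proj * e_r
  e_l <- e_l / sqrt(rowSums(e_l^2))
  e_c <- cbind(
    e_l[, 2] * e_r[, 3] - e_l[, 3] * e_r[, 2],
    e_l[, 3] * e_r[, 1] - e_l[, 1] * e_r[, 3],
    e_l[, 1] * e_r[, 2] - e_l[, 2] * e_r[, 1]
  )
  list(e_c = e_c, e_l = e_l, e_r = e_r)
}

# quadratic form e' E e for stacked symmetric tensors (n x 6, order
# xx,yy,zz,xy,xz,yz) and stacked unit vectors (n x 3).
.sym_quad <- function(E, v) {
  E[, 1] * v[, 1]^2 + E[, 2] * v[, 2]^2 + E[, 3] * v[, 3]^2 +
    2 * (E[, 4] * v[, 1] * v[, 2] + E[, 5] * v[, 1] * v[, 3] +
           E[, 6] * v[, 2] * v[, 3])
}

#' Directional strains in the local anatomical basis
#'
#' @param E n x 6 matrix of symmetric tensors (`xx, yy, zz, xy, xz, yz`), or
#'   a single length-6 vector / 3x3 matrix.
#' @param basis triad list from [local_basis()] (matching row count).
#' @return data.frame with `Ecc`, `Ell`, `Err` in percent.
#' @export
directional_strains <- function(E, basis) {
  E <- .as_sym6(E)
  data.frame(
    Ecc = 100 * .sym_quad(E, basis$e_c),
    Ell = 100 * .sym_quad(E, basis$e_l),
    Err = 100 * .sym_quad(E, basis$e_r)
  )
}

.as_sym6 <- function(E) {
  if (is.matrix(E) && ncol(E) == 3 && nrow(E) == 3) {
    E <- c(E[1, 1], E[2, 2], E[3, 3], E[1, 2], E[1, 3], E[2, 3])
  }
  if (is.null(dim(E))) E <- matrix(E, 1)
  stopifnot(ncol(E) == 6)
  E
}

#' Principal strains of symmetric tensors
#'
#' Eigenvalues sorted descending (`E1 >= E2 >= E3`).  For a single tensor the
#' principal directions are returned as well, with near-degenerate pairs
#' ordered by alignment with the radial direction for reproducibility.
#'
#' @param E as in [directional_strains()].
#' @param e_r optional radial unit vector used for tie-breaking directions.
#' @return for stacked input, a data.frame `E1, E2, E3` in percent; for a
#'   single tensor, a list with `values` (percent) and `vectors` (columns).
#' @export
principal_strains <- function(E, e_r = c(1, 0, 0)) {
  single <- (is.matrix(E) && ncol(E) == 3 && nrow(E) == 3) ||
    (is.null(dim(E)) && length(E) == 6)
  Em <- .as_sym6(E)
  if (single) {
    M <- matrix(c(Em[1, 1], Em[1, 4], Em[1, 5],
                  Em[1, 4], Em[1, 2], Em[1, 6],
                  Em[1, 5], Em[1, 6], Em[1, 3]), 3, 3)
    eg <- eigen(M, symmetric = TRUE)
    ord <- order(eg$values, decreasing = TRUE)
    vals <- eg$values[ord]
    vecs <- eg$vectors[, ord, drop = FALSE]
    for (i in 1:2) {  # stable tie-break: align degenerate pairs with e_r
      if (abs(vals[i] - vals[i + 1]) < 1e-12) {
        al <- abs(crossprod(vecs[, i:(i + 1)], e_r))
        if (al[2] > al[1]) {
          vecs[, i:(i + 1)] <- vecs[, (i + 1):i]
        }
      }
    }
    return(list(values = 100 * vals, vectors = vecs))
  }
  vals <- .sym_eigvals(Em)
  data.frame(E1 = 100 * vals[, 1], E2 = 100 * vals[, 2], E3 = 100 * vals[, 3])
}

# Closed-form eigenvalues of stacked symmetric 3x3 tensors (descending),
# by the trigonometric method (numerically safe for real symmetric input).
.sym_eigvals <- function(E) {
  a <- E[, 1]; b <- E[, 2]; c <- E[, 3]
  d <- E[, 4]; e <- E[, 5]; f <- E[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-300
  r <- rep(0, length(a))
  # det of (E - qI)/p
  aa <- (a - q); bb <- (b - q); cc <- (c - q)
  detB <- aa * (bb * cc - f * f) - d * (d * cc - f * e) + e * (d * f - bb * e)
  r[ok] <- detB[ok] / (2 * p[ok]^3)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  cbind(l1, l2, l3)
}
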