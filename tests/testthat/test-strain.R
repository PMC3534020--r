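# Tensor machinery: deformation-gradient assembly, Green-Lagrange strain,
# local bases, directional/principal decompositions, segment averaging.

# exact phase maps for a rigid in-plane translation of the tag pattern
.translation_maps <- function(geom, acq, shift) {
  m <- geom$matrix_size
  ns <- geom$n_slices
  ax <- (seq_len(m) - (m + 1) / 2) * geom$pixel_spacing
  X <- outer(ax - shift[1], rep(1, m))
  Y <- outer(rep(1, m), ax - shift[2])
  d4 <- c(m, m, ns, 1)
  ph <- array(wrap_pi(acq$omega * X), d4)
  pv <- array(wrap_pi(acq$omega * Y), d4)
  structure(list(
    phi_h = ph, phi_v = pv, phi_z = array(0, d4),
    magnitude = array(1, d4), mask = array(TRUE, d4),
    acq = acq, geometry = geom,
    filter = list(shape = "exact", radius_frac = NA, quality_frac = NA)
  ), class = "phase_map_stack")
}

test_that("identity and rigid translation give F = I and zero strain", {
  geom <- tiny_geometry()
  acq <- acquisition_params(n_phases = 2, noise_sd = 0)
  for (shift in list(c(0, 0), c(2.3, -1.1))) {
    maps <- .translation_maps(geom, acq, shift)
    grad <- deformation_gradient_inverse(maps, 1)
    interior <- grad$f_inv[4:44, 4:44, 2, ]
    eye <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = 41 * 41)
    expect_lt(max(abs(as.vector(interior) - eye)), 1e-3)
    stf <- green_strain(grad)
    expect_lt(max(abs(stf$E[4:44, 4:44, 2, ])), 1e-3)
  }
})

test_that("Green strain matches closed forms", {
  # F = I -> E = 0; uniaxial stretch 1.2 along x -> Exx = 0.22
  f_inv <- array(rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), each = 4), c(2, 2, 1, 9))
  stf <- green_strain(list(f_inv = f_inv, det = array(1, c(2, 2, 1)),
                           valid = array(TRUE, c(2, 2, 1))))
  expect_lt(max(abs(stf$E)), 1e-14)

  f_inv[, , 1, 1] <- 1 / 1.2
  stf2 <- green_strain(list(f_inv = f_inv, det = array(1 / 1.2, c(2, 2, 1)),
                            valid = array(TRUE, c(2, 2, 1))))
  expect_equal(stf2$E[1, 1, 1, 1], 0.5 * (1.2^2 - 1), tolerance = 1e-12)
  expect_lt(max(abs(stf2$E[, , , 2:6])), 1e-14)
})

test_that("local basis matches analytic normals and is orthonormal", {
  th <- seq(0, 2 * pi, length.out = 8193)[-8193]
  circle <- cbind(25 * cos(th), 25 * sin(th))
  b <- local_basis(circle, c(0, 0, 1), cbind(25, 0))
  expect_equal(as.numeric(b$e_r), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(as.numeric(b$e_l), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(as.numeric(b$e_c), c(0, 1, 0), tolerance = 1e-6)

  # 2:1 ellipse: outward normal at (a cos t, b sin t) is
  # (b cos t, a sin t)/|.|
  a <- 30; bb <- 15
  ellipse <- cbind(a * cos(th), bb * sin(th))
  t0 <- th[821]   # query on a contour vertex
  pt <- cbind(a * cos(t0), bb * sin(t0))
  n_true <- c(bb * cos(t0), a * sin(t0), 0)
  n_true <- n_true / sqrt(sum(n_true^2))
  be <- local_basis(ellipse, c(0, 0, 1), pt)
  expect_lt(max(abs(as.numeric(be$e_r) - n_true)), 1e-6)

  # orthonormality of the triad everywhere
  set.seed(1)
  pts <- cbind(runif(50, -20, 20), runif(50, -10, 10))
  bt <- local_basis(ellipse, c(0, 0, 1), pts)
  gram_err <- vapply(1:50, function(i) {
    M <- rbind(bt$e_c[i, ], bt$e_l[i, ], bt$e_r[i, ])
    max(abs(M %*% t(M) - diag(3)))
  }, numeric(1))
  expect_lt(max(gram_err), 1e-10)

  tt <- seq(0, 2 * pi, length.out = 17)[-17]
  figure8 <- cbind(10 * sin(2 * tt), 10 * sin(tt))
  expect_error(local_basis(figure8, points = cbind(0, 0)), "contour")
})

test_that("directional strains are the quadratic forms of the tensor", {
  basis <- list(e_c = rbind(c(0, 1, 0)), e_l = rbind(c(0, 0, 1)),
                e_r = rbind(c(1, 0, 0)))
  expect_equal(unlist(directional_strains(rep(0, 6), basis)),
               c(Ecc = 0, Ell = 0, Err = 0))
  E <- c(0.16, -0.20, -0.22, 0, 0, 0)  # diagonal in the local frame
  d <- directional_strains(E, basis)
  expect_equal(c(d$Err, d$Ecc, d$Ell), 100 * E[1:3])
})

test_that("principal strains match characteristic-polynomial roots and are
          rotation invariant", {
  # already-diagonal tensor (stacked API takes an n x 6 matrix)
  p <- principal_strains(matrix(c(0.16, -0.20, -0.22, 0, 0, 0), 1))
  expect_equal(unlist(p[1, ]), c(E1 = 16, E2 = -20, E3 = -22))

  # circ-long shear on a physiological diagonal: compare to polyroot()
  E6 <- c(-0.196, -0.217, 0.164, 0.05, 0, 0)
  M <- matrix(c(E6[1], E6[4], E6[5],
                E6[4], E6[2], E6[6],
                E6[5], E6[6], E6[3]), 3, 3)
  cp <- c(-det(M),
          (sum(diag(M))^2 - sum(diag(M %*% M))) / 2,
          -sum(diag(M)), 1)
  roots <- sort(Re(polyroot(cp)), decreasing = TRUE)
  got <- unlist(principal_strains(matrix(E6, 1))[1, ]) / 100
  expect_lt(max(abs(got - roots)), 1e-10)

  # eigenvalues invariant under random rotations
  set.seed(6)
  for (r in 1:20) {
    A <- matrix(rnorm(9), 3)
    R <- qr.Q(qr(A))
    S <- matrix(rnorm(9), 3); S <- (S + t(S)) / 4
    Sr <- t(R) %*% S %*% R
    v1 <- unlist(principal_strains(matrix(c(S[1, 1], S[2, 2], S[3, 3],
                                            S[1, 2], S[1, 3], S[2, 3]), 1)))
    v2 <- unlist(principal_strains(matrix(c(Sr[1, 1], Sr[2, 2], Sr[3, 3],
                                            Sr[1, 2], Sr[1, 3], Sr[2, 3]), 1)))
    expect_lt(max(abs(v1 - v2)), 1e-8)
    expect_true(all(diff(v1) <= 1e-12))  # sorted descending
  }

  # single-tensor API returns eigenpairs satisfying E v = lambda v
  ps <- principal_strains(M)
  for (j in 1:3) {
    expect_lt(max(abs(M %*% ps$vectors[, j] -
                        ps$values[j] / 100 * ps$vectors[, j])), 1e-8)
  }
})

test_that("trace identity Ecc+Ell+Err = E1+E2+E3 holds per tensor", {
  set.seed(9)
  basis_of <- function(angle) {
    e_r <- c(cos(angle), sin(angle), 0)
    e_l <- c(0, 0, 1)
    e_c <- c(-sin(angle), cos(angle), 0)
    list(e_c = rbind(e_c), e_l = rbind(e_l), e_r = rbind(e_r))
  }
  for (r in 1:50) {
    E6 <- matrix(rnorm(6, sd = 0.15), 1)
    d <- directional_strains(E6, basis_of(runif(1, 0, 2 * pi)))
    p <- principal_strains(E6)
    expect_lt(abs((d$Ecc + d$Ell + d$Err) - (p$E1 + p$E2 + p$E3)), 1e-8)
  }
})

test_that("segment averages equal a brute-force mean and flag starved rows", {
  vals <- array(NA_real_, c(4, 4, 1))
  vals[1, 1, 1] <- 10; vals[2, 1, 1] <- 20; vals[1, 2, 1] <- 60
  valid <- !is.na(vals)
  theta <- array(0.1, c(4, 4, 1))
  model <- list(data.frame(segment_id = 1, class = "healthy",
                           theta1 = 0, theta2 = 2 * pi,
                           level = "mid", slice = 1))
  tab <- suppressMessages(
    segment_average(list(Ecc = vals), valid, theta, model, min_pixels = 3))
  expect_equal(tab$Ecc, mean(c(10, 20, 60)))
  starved <- suppressMessages(
    segment_average(list(Ecc = vals), valid, theta, model, min_pixels = 4))
  expect_true(is.na(starved$Ecc))
  expect_equal(starved$n_pixels, 3)
})

test_that("end-systole is the phase of peak circumferential shortening", {
  expect_equal(pick_end_systole(c(-2, -8, -19, -12, -3)), 3)
})
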