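# HARP material-point tracking: the tag phase pair is a material property, so
# a point is followed by finding, in the next frame, the location carrying the
# same wrapped (phi_h, phi_v) — a Newton iteration on the wrapped residual.

#' Track one set of points across a single phase step
#'
#' Newton iteration on the wrapped two-component tag-phase residual
#' `W(phi(x, t1) - phi_target)`, with the Jacobian taken from wrapped
#' central-difference phase gradients.  The step is damped by 0.8 whenever the
#' residual grows; convergence requires a residual below `tol` within
#' `max_iter` iterations and a per-step jump below half a tag period.
#'
#' @param maps a `phase_map_stack`.
#' @param slice slice index.
#' @param from_phase,to_phase cardiac phase indices (consecutive in normal
#'   use).
#' @param points n x 2 matrix of positions (mm) at `from_phase`.
#' @param init optional n x 2 matrix of starting positions at `to_phase`
#'   (defaults to `points`); lets a sequential estimate be refined against a
#'   distant reference phase.
#' @param tol residual tolerance, radians.
#' @param max_iter Newton iteration cap.
#' @return list: `points` (n x 2, positions at `to_phase`), `z_mm`
#'   (slice position plus through-plane displacement `phi_z / kz`),
#'   `converged` (logical n).
#' @export
harp_track <- function(maps, slice, from_phase, to_phase, points,
                       init = NULL, tol = 1e-3, max_iter = 20) {
  stopifnot(inherits(maps, "phase_map_stack"))
  points <- rbind(points)
  init <- if (is.null(init)) points else rbind(init)
  ax <- pixel_axis(maps$geometry)
  px <- maps$geometry$pixel_spacing
  ph_h0 <- maps$phi_h[, , slice, from_phase]
  ph_v0 <- maps$phi_v[, , slice, from_phase]
  ph_h1 <- maps$phi_h[, , slice, to_phase]
  ph_v1 <- maps$phi_v[, , slice, to_phase]
  gh <- phase_gradient2(ph_h1, px)
  gv <- phase_gradient2(ph_v1, px)

  target_h <- interp_phase(ph_h0, ax, points[, 1], points[, 2])
  target_v <- interp_phase(ph_v0, ax, points[, 1], points[, 2])

  n <- nrow(points)
  x <- init
  converged <- rep(FALSE, n)
  res_of <- function(x, t_h, t_v) {
    cbind(wrap_pi(interp_phase(ph_h1, ax, x[, 1], x[, 2]) - t_h),
          wrap_pi(interp_phase(ph_v1, ax, x[, 1], x[, 2]) - t_v))
  }
  r <- res_of(x, target_h, target_v)
  for (it in seq_len(max_iter)) {
    rn <- pmax(abs(r[, 1]), abs(r[, 2]))
    converged <- rn < tol
    active <- which(!converged)
    if (length(active) == 0) break
    xa <- x[active, , drop = FALSE]
    j11 <- interp2(gh$gx, ax, xa[, 1], xa[, 2])
    j12 <- interp2(gh$gy, ax, xa[, 1], xa[, 2])
    j21 <- interp2(gv$gx, ax, xa[, 1], xa[, 2])
    j22 <- interp2(gv$gy, ax, xa[, 1], xa[, 2])
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-12] <- NA
    sx <- (j22 * r[active, 1] - j12 * r[active, 2]) / det
    sy <- (-j21 * r[active, 1] + j11 * r[active, 2]) / det
    sx[is.na(sx)] <- 0
    sy[is.na(sy)] <- 0
    trial <- xa - cbind(sx, sy)
    r_trial <- res_of(trial, target_h[active], target_v[active])
    worse <- pmax(abs(r_trial[, 1]), abs(r_trial[, 2])) >
      pmax(abs(r[active, 1]), abs(r[active, 2]))
    if (any(worse)) {
      trial[worse, ] <- xa[worse, , drop = FALSE] -
        0.8 * cbind(sx[worse], sy[worse])
      r_trial[worse, ] <- res_of(trial[worse, , drop = FALSE],
                                 target_h[active][worse],
                                 target_v[active][worse])
    }
    x[active, ] <- trial
    r[active, ] <- r_trial
  }
  rn <- pmax(abs(r[, 1]), abs(r[, 2]))
  converged <- rn < tol
  # jump guard: more than half a tag period from the start is non-physical
  jump <- sqrt(rowSums((x - init)^2))
  bad <- jump > maps$acq$tag_spacing / 2
  x[bad, ] <- init[bad, , drop = FALSE]
  converged[bad] <- FALSE

  # through-plane position: w/(1 - dw/dz) is the first-order solution of
  # Z_ref(z*) = z_slice (the landmark originally in this slice plane), with
  # dw/dz from centred differences across the neighbouring slices.
  phz <- interp_phase(maps$phi_z[, , slice, to_phase], ax, x[, 1], x[, 2])
  w <- phz / maps$acq$kz
  ns <- dim(maps$phi_z)[3]
  k0 <- max(1, slice - 1)
  k1 <- min(ns, slice + 1)
  dphz <- interp_phase(maps$phi_z[, , k1, to_phase], ax, x[, 1], x[, 2]) -
    interp_phase(maps$phi_z[, , k0, to_phase], ax, x[, 1], x[, 2])
  dwdz <- dphz / maps$acq$kz /
    ((k1 - k0) * maps$geometry$slice_thickness)
  # the slope correction is only trusted where both neighbouring slices carry
  # tissue signal at this in-plane position; background phase is noise
  mag1 <- interp2(maps$magnitude[, , k1, to_phase], ax, x[, 1], x[, 2])
  mag0 <- interp2(maps$magnitude[, , k0, to_phase], ax, x[, 1], x[, 2])
  thr <- 0.15 * stats::quantile(maps$magnitude[, , slice, to_phase], 0.98)
  dwdz[!is.finite(dwdz) | mag1 < thr | mag0 < thr] <- 0
  dwdz <- pmin(pmax(dwdz, -0.45), 0.45)
  z_mm <- maps$geometry$slice_positions[slice] + w / (1 - dwdz)
  list(points = x, z_mm = z_mm, converged = converged)
}

#' Track landmarks through the cardiac cycle
#'
#' Applies [harp_track()] sequentially phase-to-phase for each landmark
#' defined at the reference (mid-diastolic) phase.  A slice where more than
#' 20% of landmarks fail to converge at any phase is flagged for review.
#'
#' @param maps a `phase_map_stack`.
#' @param points n x 2 matrix of landmark positions (mm) at the reference
#'   phase.
#' @param slice slice index.
#' @param ref_phase reference phase index (default 1).
#' @param phases phases to track through (default: the whole cycle).
#' @return data.frame `landmark_id, phase, x_mm, y_mm, z_mm, converged`, with
#'   attribute `flagged` set if the 20% rule fired.
#' @export
track_landmarks <- function(maps, points, slice, ref_phase = 1,
                            phases = NULL) {
  points <- rbind(points)
  np <- dim(maps$phi_h)[4]
  phases <- phases %||% seq_len(np)
  stopifnot(ref_phase %in% phases)
  n <- nrow(points)
  zs <- maps$geometry$slice_positions[slice]

  out <- vector("list", length(phases))
  ord <- order(abs(phases - ref_phase))  # walk outward from the reference
  pos <- list()
  conv <- list()
  pos[[as.character(ref_phase)]] <- points
  conv[[as.character(ref_phase)]] <- rep(TRUE, n)
  zmm <- list()
  zmm[[as.character(ref_phase)]] <- rep(zs, n)

  flagged <- FALSE
  for (p in phases[ord]) {
    if (p == ref_phase) next
    prev <- if (p > ref_phase) p - 1 else p + 1
    res <- harp_track(maps, slice, prev, p, pos[[as.character(prev)]])
    keep_old <- !res$converged
    res$points[keep_old, ] <- pos[[as.character(prev)]][keep_old, , drop = FALSE]
    pos[[as.character(p)]] <- res$points
    conv[[as.character(p)]] <- res$converged & conv[[as.character(prev)]]
    zmm[[as.character(p)]] <- res$z_mm
    if (mean(res$converged) < 0.8) flagged <- TRUE
  }
  if (flagged) {
    message("slice ", slice, ": more than 20% of landmarks failed to converge; flagged for review")
  }
  out <- do.call(rbind, lapply(phases, function(p) {
    data.frame(landmark_id = seq_len(n), phase = p,
               x_mm = pos[[as.character(p)]][, 1],
               y_mm = pos[[as.character(p)]][, 2],
               z_mm = zmm[[as.character(p)]],
               converged = conv[[as.character(p)]])
  }))
  attr(out, "flagged") <- flagged
  out
}
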