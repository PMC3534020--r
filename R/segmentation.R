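# Viability-driven myocardial segmentation: infarct delineation on LGE
# (FWHM and n-SD thresholds), chordwise transmurality, transmural-border
# detection, and the infarct/adjacent/remote (post-MI) or equal-division
# (baseline) segment models.  Angles are radians counterclockwise from the
# ARVP direction; angular intervals are half-open [theta1, theta2) and may
# wrap through zero.

# ---- membership helpers ------------------------------------------------------

# is angle inside the (possibly wrapping) half-open interval?  An interval
# whose endpoints differ but wrap to the same angle covers the full circle.
angle_in <- function(theta, theta1, theta2) {
  width <- wrap_2pi(theta2 - theta1)
  if (width == 0 && abs(theta2 - theta1) > 1e-12) width <- 2 * pi
  wrap_2pi(theta - theta1) < width
}

# overlap length of two wrapped half-open intervals
interval_overlap <- function(a1, a2, b1, b2) {
  wa <- wrap_2pi(a2 - a1)
  wb <- wrap_2pi(b2 - b1)
  # distance of b's start into a's frame
  s <- wrap_2pi(b1 - a1)
  ov1 <- max(0, min(wa, s + wb) - s)
  s2 <- wrap_2pi(a1 - b1)
  ov2 <- max(0, min(wb, s2 + wa) - s2)
  max(ov1, ov2)
}

# ---- infarct delineation -----------------------------------------------------

# 6-connected components of a logical 3D array; returns labels (0 outside).
connected_components3 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  nxt <- 0L
  d1 <- d[1]; d12 <- d[1] * d[2]
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      v <- queue
      queue <- integer(0)
      i <- ((v - 1) %% d1) + 1
      j <- (((v - 1) %/% d1) %% d[2]) + 1
      k <- ((v - 1) %/% d12) + 1
      nb <- c(v[i > 1] - 1L, v[i < d1] + 1L,
              v[j > 1] - d1, v[j < d[2]] + d1,
              v[k > 1] - d12, v[k < d[3]] + d12)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      nb <- unique(nb)
      lab[nb] <- nxt
      queue <- nb
    }
  }
  lab
}

.remote_tertile <- function(data, myo_mask) {
  vals <- data[myo_mask]
  cut <- stats::quantile(vals, 1 / 3)
  myo_mask & data <= cut
}

#' Full-width-at-half-maximum infarct delineation
#'
#' Threshold at the remote mean plus half the distance to the maximal
#' myocardial intensity; the remote signal is estimated automatically from
#' the lowest-intensity tertile of the myocardium.  Only the largest
#' 6-connected component is kept.  If no voxel clearly enhances (maximum
#' below remote mean + 2 SD) an empty mask is returned with a notice.
#'
#' @param lge an `lge_volume`, or a numeric 3D array.
#' @param myo_mask logical myocardial mask (defaults to the volume's).
#' @return object of class `infarct_mask`: logical `mask`, `method`,
#'   `threshold`.
#' @export
fwhm_infarct_mask <- function(lge, myo_mask = NULL) {
  data <- if (inherits(lge, "lge_volume")) lge$data else lge
  myo_mask <- myo_mask %||% (if (inherits(lge, "lge_volume")) lge$myo_mask else NULL)
  if (is.null(myo_mask) || !any(myo_mask)) {
    stop("a nonempty myocardial mask is required", call. = FALSE)
  }
  remote <- .remote_tertile(data, myo_mask)
  mu <- mean(data[remote])
  mx <- max(data[myo_mask])
  # no-enhancement guard: in a uniform myocardium the maximum sits within a
  # few robust SDs of the median; hyperenhancement exceeds it by far
  med <- stats::median(data[myo_mask])
  madv <- stats::mad(data[myo_mask])
  if (mx <= med + 6 * madv) {
    message("no myocardial enhancement detected; returning empty infarct mask")
    return(structure(list(mask = array(FALSE, dim(data)), method = "fwhm",
                          threshold = NA_real_), class = "infarct_mask"))
  }
  thr <- mu + 0.5 * (mx - mu)
  mask <- myo_mask & data > thr
  lab <- connected_components3(mask)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  structure(list(mask = mask, method = "fwhm", threshold = thr),
            class = "infarct_mask")
}

#' n-SD infarct delineation
#'
#' Voxels above the remote mean plus `n` remote standard deviations; `n` must
#' stay below 4.
#'
#' @param lge an `lge_volume` or numeric 3D array.
#' @param n threshold multiplier, `0 < n < 4`.
#' @param remote_region logical array marking remote myocardium (defaults to
#'   the lowest-intensity tertile).
#' @param myo_mask logical myocardial mask.
#' @return an `infarct_mask`.
#' @export
nsd_infarct_mask <- function(lge, n, remote_region = NULL, myo_mask = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0 || n >= 4) {
    stop("n must lie in (0, 4)", call. = FALSE)
  }
  data <- if (inherits(lge, "lge_volume")) lge$data else lge
  myo_mask <- myo_mask %||% (if (inherits(lge, "lge_volume")) lge$myo_mask else NULL)
  if (is.null(myo_mask) || !any(myo_mask)) {
    stop("a nonempty myocardial mask is required", call. = FALSE)
  }
  remote_region <- remote_region %||% .remote_tertile(data, myo_mask)
  mu <- mean(data[remote_region])
  sdv <- stats::sd(data[remote_region])
  thr <- mu + n * sdv
  structure(list(mask = myo_mask & data > thr, method = "nsd", threshold = thr),
            class = "infarct_mask")
}

#' @export
print.infarct_mask <- function(x, ...) {
  cat(sprintf("Infarct mask (%s, threshold %.1f): %d voxels\n",
              x$method, x$threshold, sum(x$mask)))
  invisible(x)
}

# ---- chords ------------------------------------------------------------------

# Radial representation r(theta) of a star-shaped contour about a centre.
.radial_fun <- function(contour, ctr) {
  th <- wrap_2pi(atan2(contour[, 2] - ctr[2], contour[, 1] - ctr[1]))
  rr <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  o <- order(th)
  th <- th[o]; rr <- rr[o]
  th_ext <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rr_ext <- c(rr[length(rr)], rr, rr[1])
  function(theta) stats::approx(th_ext, rr_ext, xout = wrap_2pi(theta))$y
}

#' Chordwise infarct transmurality
#'
#' Chords are cast from the endocardial centroid at `n_chords` uniform angles
#' (counterclockwise from the ARVP direction) from the endocardial to the
#' epicardial contour; the transmurality of each chord is the fraction of its
#' length occupied by infarct, and chords with fraction strictly greater than
#' 0.5 are flagged transmural.
#'
#' @param infarct_mask logical 2D slice mask (image grid).
#' @param endo,epi slice contours, n x 2 matrices (mm).
#' @param pixel_axis_mm pixel-centre coordinates of the mask grid (mm).
#' @param arvp_angle ARVP direction in image coordinates, radians.
#' @param n_chords number of chords (>= 36).
#' @param step sampling step along each chord, mm.
#' @return data.frame `angle` (rad from ARVP), `fraction`, `transmural`,
#'   `valid`, `length_mm`.
#' @export
chord_transmurality <- function(infarct_mask, endo, epi, pixel_axis_mm,
                                arvp_angle = 0, n_chords = 120, step = 0.3) {
  stopifnot(n_chords >= 36)
  ctr <- colMeans(endo)
  r_en <- .radial_fun(endo, ctr)
  r_ep <- .radial_fun(epi, ctr)
  angles <- 2 * pi * (seq_len(n_chords) - 1) / n_chords
  px <- pixel_axis_mm[2] - pixel_axis_mm[1]
  m <- length(pixel_axis_mm)
  out <- data.frame(angle = angles, fraction = 0, transmural = FALSE,
                    valid = TRUE, length_mm = NA_real_)
  for (i in seq_len(n_chords)) {
    a_img <- angles[i] + arvp_angle
    r0 <- r_en(a_img); r1 <- r_ep(a_img)
    if (!is.finite(r0) || !is.finite(r1) || r1 <= r0) {
      out$valid[i] <- FALSE
      next
    }
    rr <- seq(r0, r1, by = step)
    xs <- ctr[1] + rr * cos(a_img)
    ys <- ctr[2] + rr * sin(a_img)
    ii <- pmin(pmax(round((xs - pixel_axis_mm[1]) / px) + 1, 1), m)
    jj <- pmin(pmax(round((ys - pixel_axis_mm[1]) / px) + 1, 1), m)
    occ <- infarct_mask[cbind(ii, jj)]
    out$fraction[i] <- mean(occ)
    out$length_mm[i] <- r1 - r0
  }
  out$transmural <- out$valid & out$fraction > 0.5  # strictly greater
  out
}

#' Angular borders of the transmural infarct
#'
#' Finds the largest circular run of transmural chords, closing isolated
#' single-chord gaps; errors if a second disjoint run wider than 30 degrees
#' exists (multi-focal infarcts are unsupported).
#'
#' @param chords data.frame from [chord_transmurality()] (uniform angles).
#' @return `c(theta1, theta2)` in radians from ARVP (the run's first and last
#'   chord angles; the interval may wrap), or `NULL` if no chord is
#'   transmural.
#' @export
find_transmural_borders <- function(chords) {
  fl <- chords$transmural
  n <- length(fl)
  if (!any(fl)) return(NULL)
  if (all(fl)) stop("transmural run covers the full circumference", call. = FALSE)
  # close single-chord gaps (circular)
  prv <- c(fl[n], fl[-n]); nxt <- c(fl[-1], fl[1])
  fl <- fl | (prv & nxt)
  # enumerate circular runs
  start <- which(fl & !c(fl[n], fl[-n])) # run starts
  runs <- lapply(start, function(s) {
    len <- 1
    while (fl[((s + len - 1) %% n) + 1]) len <- len + 1
    c(start = s, len = len)
  })
  lens <- vapply(runs, function(r) r["len"], numeric(1))
  spacing <- 2 * pi / n
  big <- lens * spacing > 30 * pi / 180
  if (sum(big) > 1) {
    stop("two disjoint transmural runs wider than 30 degrees: multi-focal infarct unsupported",
         call. = FALSE)
  }
  r <- runs[[which.max(lens)]]
  th1 <- chords$angle[r["start"]]
  th2 <- chords$angle[((r["start"] + r["len"] - 2) %% n) + 1]
  c(theta1 = unname(th1), theta2 = unname(th2))
}

# ---- segment models ----------------------------------------------------------

#' Slice level (apical / mid / basal) from the slice index
#'
#' Slices are split into equal thirds by index (index 1 = apex); remainder
#' slices are assigned to the basal third.
#'
#' @param slice_index 1-based slice index from the apex.
#' @param n_slices total slice count (>= 3).
#' @return `"apical"`, `"mid"` or `"basal"`.
#' @export
classify_slice_level <- function(slice_index, n_slices) {
  stopifnot(n_slices >= 3, slice_index >= 1, slice_index <= n_slices)
  third <- floor(n_slices / 3)
  if (slice_index <= third) return("apical")
  if (slice_index <= 2 * third) return("mid")
  "basal"
}

#' Build the segment model for one slice
#'
#' With transmural borders: the infarct segment spans `[theta1, theta2)` and
#' the remaining circumference is divided, starting at `theta2`, into five
#' (basal/mid) or three (apical) equal arcs; the two arcs abutting the
#' infarct are adjacent, the rest remote.  Without borders (baseline or no
#' enhancement): six (basal/mid) or four (apical) equal healthy arcs starting
#' at the ARVP direction.
#'
#' @param borders `c(theta1, theta2)` in radians from ARVP, or `NULL`.
#' @param level slice level (`"apical"`, `"mid"`, `"basal"`).
#' @param slice slice index stored in the output.
#' @return data.frame `segment_id, class, theta1, theta2, level, slice`.
#' @export
build_segment_model <- function(borders = NULL, level, slice = NA_integer_) {
  level <- match.arg(level, c("apical", "mid", "basal"))
  if (is.null(borders)) {
    n <- if (level == "apical") 4L else 6L
    th <- 2 * pi * (0:n) / n
    return(data.frame(
      segment_id = seq_len(n), class = "healthy",
      theta1 = th[-(n + 1)], theta2 = th[-1],
      level = level, slice = slice, stringsAsFactors = FALSE))
  }
  span <- wrap_2pi(borders[2] - borders[1])
  if (span >= 300 * pi / 180) {
    stop("infarct span of 300 degrees or more is non-physiological for this model",
         call. = FALSE)
  }
  n <- if (level == "apical") 3L else 5L
  arc <- (2 * pi - span) / n
  th1 <- wrap_2pi(borders[1])
  th2 <- wrap_2pi(borders[2])
  starts <- wrap_2pi(th2 + arc * (0:(n - 1)))
  ends <- wrap_2pi(th2 + arc * (1:n))
  cls <- rep("remote", n)
  cls[1] <- "adjacent"          # abuts theta2
  cls[n] <- "adjacent"          # abuts theta1
  data.frame(
    segment_id = seq_len(n + 1),
    class = c("infarct", cls),
    theta1 = c(th1, starts), theta2 = c(th2, ends),
    level = level, slice = slice, stringsAsFactors = FALSE)
}

#' Propagate adjacency across neighbouring slices
#'
#' Any remote- or healthy-labelled segment whose angular interval overlaps an
#' infarct segment in the slice immediately above or below is relabelled
#' adjacent.
#'
#' @param models list of per-slice segment data.frames (ordered apex to
#'   base, as from [build_segment_model()]).
#' @return the updated list.
#' @export
propagate_adjacency <- function(models) {
  ns <- length(models)
  infarcts <- lapply(models, function(df) df[df$class == "infarct", , drop = FALSE])
  for (k in seq_len(ns)) {
    nb <- c(k - 1, k + 1)
    nb <- nb[nb >= 1 & nb <= ns]
    for (j in nb) {
      inf <- infarcts[[j]]
      if (nrow(inf) == 0) next
      df <- models[[k]]
      for (i in seq_len(nrow(df))) {
        if (!(df$class[i] %in% c("remote", "healthy"))) next
        if (interval_overlap(df$theta1[i], df$theta2[i],
                             inf$theta1[1], inf$theta2[1]) > 1e-9) {
          df$class[i] <- "adjacent"
        }
      }
      models[[k]] <- df
    }
  }
  models
}

#' Write a multi-slice segment model to JSON
#'
#' @param models list of per-slice segment data.frames.
#' @param path output path; `NULL` returns the JSON string.
#' @return path invisibly, or JSON string.
#' @export
write_segment_model <- function(models, path = NULL) {
  payload <- list(slices = lapply(models, function(df) {
    list(slice = df$slice[1], level = df$level[1],
         segments = lapply(seq_len(nrow(df)), function(i) list(
           id = df$segment_id[i], class = df$class[i],
           theta1_deg = df$theta1[i] * 180 / pi,
           theta2_deg = df$theta2[i] * 180 / pi,
           level = df$level[i])))
  }))
  if (is.null(path)) return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- registration ------------------------------------------------------------

#' Least-squares 2D affine registration from landmark pairs
#'
#' @param from,to n x 2 matrices of paired landmarks (n >= 3, non-collinear).
#' @return list: `A` (2 x 2), `b` (length 2), `rms` residual (mm),
#'   `transform` (function mapping n x 2 points).
#' @export
register_lge_to_tag <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  stopifnot(nrow(from) == nrow(to), nrow(from) >= 3)
  X <- cbind(from, 1)
  if (qr(X)$rank < 3) stop("landmarks are collinear", call. = FALSE)
  beta <- qr.solve(X, to)
  A <- t(beta[1:2, ])
  b <- beta[3, ]
  fitted <- X %*% beta
  rms <- sqrt(mean(rowSums((fitted - to)^2)))
  list(A = A, b = b, rms = rms,
       transform = function(p) {
         p <- rbind(p)
         sweep(p %*% t(A), 2, -b)
       })
}

#' Pair each tagged slice with the nearest LGE slice
#'
#' @param tag_z tagged-slice long-axis positions, mm.
#' @param lge_z LGE-slice positions, mm.
#' @return integer vector: for each tagged slice, the index of the closest
#'   LGE slice.
#' @export
pair_lge_slices <- function(tag_z, lge_z) {
  vapply(tag_z, function(z) which.min(abs(lge_z - z)), integer(1))
}
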