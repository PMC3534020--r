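# Shared fixtures, built once per test run and cached.  All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# Scaled-down but fully structured phantom study at SNR 20: tagged images,
# LGE, phase maps (wide filter for strain, narrower for tracking), ground
# truth at end-systole, LGE-derived segment models, and deformed contours.
phantom_fixture <- function() {
  if (!is.null(.fixtures$phantom)) return(.fixtures$phantom)
  cfg <- small_phantom_config(noise_sd = 0.05)
  geom <- cfg$geometry
  ns <- geom$n_slices
  set <- synthesize_tagged_images(geom, cfg$deformation, cfg$acq, seed = 7)
  lge <- synthesize_lge(geom, cfg$regions, seed = 3)
  s_es_idx <- which.max(set$activation)
  s_es <- set$activation[s_es_idx]
  gt <- phantom_ground_truth(geom, cfg$deformation, s_es)
  gt_ref <- phantom_ground_truth(geom, cfg$deformation, 1)
  maps <- harp_phase_maps(set)
  maps_track <- harp_phase_maps(set, radius_frac = 1.2, flat_frac = 0.7)

  inf <- fwhm_infarct_mask(lge)
  ax <- (seq_len(geom$matrix_size) - (geom$matrix_size + 1) / 2) *
    geom$pixel_spacing
  ref <- geometry_contours(geom, 90)
  l4t <- pair_lge_slices(geom$slice_positions, lge$z)
  models <- propagate_adjacency(lapply(seq_len(ns), function(k) {
    ch <- chord_transmurality(inf$mask[, , l4t[k]], ref[[k]]$endo,
                              ref[[k]]$epi, ax, geom$arvp_angle)
    build_segment_model(find_transmural_borders(ch),
                        classify_slice_level(k, ns), slice = k)
  }))
  contours_es <- lapply(seq_len(ns), function(k) {
    epi_def <- cfg$deformation$map(cbind(ref[[k]]$epi, ref[[k]]$z), s_es)
    list(epi = epi_def[, 1:2], centroid = c(0, 0),
         arvp_angle = geom$arvp_angle)
  })

  .fixtures$phantom <- list(
    cfg = cfg, geom = geom, set = set, lge = lge, maps = maps,
    maps_track = maps_track, infarct = inf, models = models,
    contours_es = contours_es, ref_contours = ref, ax = ax,
    s_es_idx = s_es_idx, s_es = s_es, gt = gt, gt_ref = gt_ref
  )
  .fixtures$phantom
}

# Tiny geometry for cheap synthetic-image tests (margin still covers two tag
# periods).
tiny_geometry <- function(n_slices = 3) {
  build_lv_geometry(n_slices = n_slices, slice_thickness = 8,
                    endo_radius = 10, epi_radius = 16, apex_scale = 0.7,
                    pixel_spacing = 1.25, matrix_size = 48, arvp_angle = 0)
}

# Packaged calibration targets pooled over post-infarct time points.
pooled_calibration_target <- function(class, measure) {
  cal <- segment_strain_calibration()
  cc <- cal[cal$class == class & cal$measure == measure, ]
  c(mean = mean(cc$mean), sd = mean(cc$sd))
}

# Ground-truth directional strain fields decomposed with the same contour
# basis the measurement pipeline uses (so recovery tests compare like with
# like).
truth_directional_fields <- function(fx) {
  geom <- fx$geom
  m <- geom$matrix_size
  ns <- geom$n_slices
  xs <- rep(fx$ax, times = m)
  ys <- rep(fx$ax, each = m)
  out <- list(Ecc = array(NA_real_, c(m, m, ns)),
              Err = array(NA_real_, c(m, m, ns)),
              Ell = array(NA_real_, c(m, m, ns)))
  for (k in seq_len(ns)) {
    idx <- which(as.vector(fx$gt$mask[, , k]))
    if (length(idx) == 0) next
    E6 <- vapply(1:6, function(d) fx$gt$E_cart[, , k, d][idx],
                 numeric(length(idx)))
    basis <- local_basis(fx$contours_es[[k]]$epi, c(0, 0, 1),
                         cbind(xs[idx], ys[idx]))
    dd <- directional_strains(E6, basis)
    for (nm in names(out)) {
      a <- array(NA_real_, c(m, m))
      a[idx] <- dd[[nm]]
      out[[nm]][, , k] <- a
    }
  }
  out
}
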