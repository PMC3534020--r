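# End-to-end orchestration: simulate -> harp -> strain -> segment -> metrics
# -> stats, with a JSON manifest (seed, parameter hash, per-stage artifact
# checksums) for reproducibility.

.log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

#' Run the full phantom analysis pipeline
#'
#' Executes the enabled stages on a config-defined phantom: image synthesis
#' with ground truth, harmonic-phase analysis and tracking, per-pixel strain,
#' LGE segmentation, global function metrics, and the strain model-comparison
#' statistics.  All artifacts land under `config$output_dir` together with a
#' `manifest.json`.
#'
#' @param config a `run_config`, a path to a YAML config, or a list of
#'   overrides (see [default_run_config()]).
#' @return invisible list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("zharpstrain")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(
      .write_json(cfg[setdiff(names(cfg), "output_dir")],
                  file.path(out_dir, "config.resolved.json")))),
    stages = list(), files = list()
  )
  res <- list(config = cfg)
  stage_names <- c("simulate", "harp", "strain", "segment", "metrics", "stats")

  finish <- function(status) {
    manifest$files <<- .checksum_dir(out_dir)
    .write_json(manifest, file.path(out_dir, "manifest.json"))
    status
  }

  for (stage in stage_names) {
    if (!isTRUE(cfg$stages[[stage]])) {
      manifest$stages[[stage]] <- "skipped"
      next
    }
    .log(cfg, "stage: ", stage)
    ok <- tryCatch({
      res <- .run_stage(stage, cfg, res, out_dir)
      TRUE
    }, error = function(e) {
      manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e))
      FALSE
    })
    if (!ok) {
      finish("failed")
      stop("pipeline stage '", stage, "' failed; see manifest in ", out_dir,
           call. = FALSE)
    }
    manifest$stages[[stage]] <- "complete"
  }
  manifest$status <- finish("complete")
  invisible(c(res, list(manifest = manifest)))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  path
}

.checksum_dir <- function(dir) {
  files <- setdiff(list.files(dir, recursive = TRUE),
                   c("manifest.json"))
  as.list(tools::md5sum(file.path(dir, files)))
}

.run_stage <- function(stage, cfg, res, out_dir) {
  switch(stage,
    simulate = .stage_simulate(cfg, res, out_dir),
    harp = .stage_harp(cfg, res, out_dir),
    strain = .stage_strain(cfg, res, out_dir),
    segment = .stage_segment(cfg, res, out_dir),
    metrics = .stage_metrics(cfg, res, out_dir),
    stats = .stage_stats(cfg, res, out_dir)
  )
}

.stage_simulate <- function(cfg, res, out_dir) {
  g <- cfg$geometry
  geometry <- build_lv_geometry(
    n_slices = g$n_slices, slice_thickness = g$slice_thickness,
    endo_radius = g$endo_radius, epi_radius = g$epi_radius,
    apex_scale = g$apex_scale, pixel_spacing = g$pixel_spacing,
    matrix_size = g$matrix_size, arvp_angle = g$arvp_angle)
  r <- cfg$regions
  regions <- if (isTRUE(r$enabled)) {
    region_map(geometry,
               theta1 = r$theta1_deg * pi / 180, theta2 = r$theta2_deg * pi / 180,
               rho_infarct = r$rho_infarct,
               transition = r$transition_deg * pi / 180,
               transmurality = r$transmurality,
               z_top = if (is.na(r$z_top)) NULL else r$z_top,
               z_transition = r$z_transition)
  } else NULL
  d <- cfg$deformation
  deformation <- make_deformation(
    geometry, regions,
    contraction = if (is.na(d$contraction)) NULL else d$contraction,
    kappa = if (is.na(d$kappa)) NULL else d$kappa,
    lambda_l = if (is.na(d$lambda_l)) NULL else d$lambda_l,
    twist_total = d$twist_total, z_fix_frac = d$z_fix_frac)
  a <- cfg$acquisition
  acq <- acquisition_params(tag_spacing = a$tag_spacing,
                            kz = 2 * pi / a$kz_period_mm,
                            n_phases = a$n_phases, noise_sd = a$noise_sd,
                            es_frac = a$es_frac)
  set <- synthesize_tagged_images(geometry, deformation, acq, seed = cfg$seed)
  lge <- synthesize_lge(geometry, regions, seed = cfg$seed,
                        slice_thickness = cfg$lge$slice_thickness,
                        remote_mean = cfg$lge$remote_mean,
                        remote_sd = cfg$lge$remote_sd,
                        infarct_mean = cfg$lge$infarct_mean)
  write_tagged_nifti(set, file.path(out_dir, "tagged"))
  nifti_write(lge$data, file.path(out_dir, "lge.nii"),
              pixdim = c(geometry$pixel_spacing, geometry$pixel_spacing,
                         cfg$lge$slice_thickness),
              description = "synthetic LGE")
  truth <- phantom_ground_truth(geometry, deformation, 1)
  nifti_write(truth$E_cyl[, , , 1:3], file.path(out_dir, "truth_strain_es.nii"),
              pixdim = c(geometry$pixel_spacing, geometry$pixel_spacing,
                         geometry$slice_thickness, 1),
              description = "true Err/Ecc/Ell at end-systole")
  res$geometry <- geometry
  res$regions <- regions
  res$deformation <- deformation
  res$acq <- acq
  res$tagged <- set
  res$lge <- lge
  res$truth_es <- truth
  res
}

.stage_harp <- function(cfg, res, out_dir) {
  res$maps <- harp_phase_maps(res$tagged)
  borders <- if (!is.null(res$regions)) {
    c(res$regions$theta1, res$regions$theta2)
  } else NULL
  res$tracked <- track_contours(res$maps, border_angles = borders)
  trajs <- do.call(rbind, lapply(seq_along(res$tracked), function(k) {
    df <- res$tracked[[k]]$epi
    df$slice <- k
    df
  }))
  utils::write.csv(trajs, file.path(out_dir, "tracked_epicardium.csv"),
                   row.names = FALSE)
  res
}

.stage_strain <- function(cfg, res, out_dir) {
  np <- res$acq$n_phases
  mean_ecc <- numeric(np)
  fields <- vector("list", np)
  for (p in seq_len(np)) {
    ctr <- contours_at_phase(res$tracked, p)
    fields[[p]] <- compute_strain_fields(res$maps, p, ctr)
    mean_ecc[p] <- mean(fields[[p]]$Ecc[fields[[p]]$valid], na.rm = TRUE)
  }
  res$es_phase <- pick_end_systole(mean_ecc)
  res$mean_ecc_by_phase <- mean_ecc
  res$fields <- fields
  es <- fields[[res$es_phase]]
  geom <- res$geometry
  arr <- array(NA_real_, c(dim(es$Ecc), 6))
  for (d in seq_along(c("Ecc", "Err", "Ell", "E1", "E2", "E3"))) {
    arr[, , , d] <- es[[c("Ecc", "Err", "Ell", "E1", "E2", "E3")[d]]]
  }
  nifti_write(arr, file.path(out_dir, "strain_es.nii"),
              pixdim = c(geom$pixel_spacing, geom$pixel_spacing,
                         geom$slice_thickness, 1),
              description = "measured strain at end-systole")
  res
}

.stage_segment <- function(cfg, res, out_dir) {
  lge <- res$lge
  geom <- res$geometry
  method <- cfg$segmentation$method
  inf <- if (identical(method, "nsd")) {
    nsd_infarct_mask(lge, cfg$segmentation$nsd_n)
  } else {
    fwhm_infarct_mask(lge)
  }
  res$infarct_mask <- inf
  ax <- pixel_axis(geom)
  lge_for_tag <- pair_lge_slices(geom$slice_positions, lge$z)
  ref <- geometry_contours(geom, 90)
  models <- lapply(seq_len(geom$n_slices), function(k) {
    level <- classify_slice_level(k, geom$n_slices)
    chords <- chord_transmurality(inf$mask[, , lge_for_tag[k]],
                                  ref[[k]]$endo, ref[[k]]$epi, ax,
                                  arvp_angle = geom$arvp_angle,
                                  n_chords = cfg$segmentation$n_chords)
    borders <- find_transmural_borders(chords)
    build_segment_model(borders, level, slice = k)
  })
  res$segment_models <- propagate_adjacency(models)
  res$chord_sets <- lapply(seq_len(geom$n_slices), function(k) {
    chord_transmurality(inf$mask[, , lge_for_tag[k]],
                        ref[[k]]$endo, ref[[k]]$epi, ax,
                        arvp_angle = geom$arvp_angle,
                        n_chords = cfg$segmentation$n_chords)
  })
  write_segment_model(res$segment_models,
                      file.path(out_dir, "segment_model.json"))
  res
}

.stage_metrics <- function(cfg, res, out_dir) {
  geom <- res$geometry
  es <- res$es_phase
  ed_contours <- lapply(contours_at_phase(res$tracked, 1), function(s) {
    list(endo = s$endo)
  })
  es_contours <- lapply(contours_at_phase(res$tracked, es), function(s) {
    list(endo = s$endo)
  })
  gf <- lv_volumes(ed_contours, es_contours, geom$slice_thickness)
  gf$scar_pct <- scar_percentage(res$infarct_mask, res$lge$myo_mask)

  ctr_ed <- contours_at_phase(res$tracked, 1)
  ctr_es <- contours_at_phase(res$tracked, es)
  mid <- which(vapply(seq_len(geom$n_slices),
                      function(k) classify_slice_level(k, geom$n_slices),
                      character(1)) == "mid")
  wt <- do.call(rbind, lapply(mid, function(k) {
    rbind(
      cbind(slice = k, phase = "ED",
            wall_thickness(ctr_ed[[k]]$endo, ctr_ed[[k]]$epi,
                           res$segment_models[[k]], geom$arvp_angle)),
      cbind(slice = k, phase = "ES",
            wall_thickness(ctr_es[[k]]$endo, ctr_es[[k]]$epi,
                           res$segment_models[[k]], geom$arvp_angle))
    )
  }))
  res$global_function <- gf
  res$wall_thickness <- wt
  .write_json(gf[c("EDV", "ESV", "SV", "EF", "scar_pct")],
              file.path(out_dir, "global_function.json"))
  utils::write.csv(wt, file.path(out_dir, "wall_thickness.csv"),
                   row.names = FALSE)
  res
}

.stage_stats <- function(cfg, res, out_dir) {
  # segment strain table of this phantom run at end-systole
  es <- res$fields[[res$es_phase]]
  tab <- segment_average(
    es[c("Ecc", "Err", "Ell", "E1", "E2", "E3")], es$valid, es$theta,
    res$segment_models, animal_id = 1L,
    time = if (is.null(res$regions)) "baseline" else "early")
  res$segment_table <- tab
  write_segment_strain_table(tab, file.path(out_dir, "segment_strain.csv"))

  # cohort-level model comparison on the calibrated sampler (or a user table)
  s <- cfg$stats
  reports <- list()
  for (contrast in s$contrasts) {
    table <- if (!is.null(s$table_csv) && !is.na(s$table_csv)) {
      utils::read.csv(s$table_csv, stringsAsFactors = FALSE)
    } else {
      draw_contrast_sample(contrast, n_healthy = s$n_healthy,
                           n_per_time = s$n_per_time,
                           seed = stage_seed(cfg$seed, contrast))
    }
    rep <- run_model_comparison(table, contrast)
    reports[[contrast]] <- rep
    write_model_comparison(rep, file.path(
      out_dir, sprintf("model_comparison_%s.json", contrast)))
  }
  res$reports <- reports
  res
}
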