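# YAML run configuration with schema validation: unknown keys are rejected,
# values are merged over documented defaults.

#' Default pipeline configuration
#'
#' The scaled-down phantom defaults (64-pixel matrix, 5 slices, 10 phases)
#' keep an end-to-end run in seconds; physical parameters (tag spacing,
#' voxel sizes, z-encoding, contractility calibration) follow the full-size
#' acquisition.
#'
#' @return nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "zharp-run",
    log_level = "info",
    stages = list(simulate = TRUE, harp = TRUE, strain = TRUE,
                  segment = TRUE, metrics = TRUE, stats = TRUE),
    geometry = list(n_slices = 5L, slice_thickness = 8, endo_radius = 16,
                    epi_radius = 24, apex_scale = 0.6, pixel_spacing = 1.25,
                    matrix_size = 64L, arvp_angle = 0),
    regions = list(enabled = TRUE, theta1_deg = 0, theta2_deg = 130,
                   rho_infarct = 0.18, transition_deg = 60,
                   transmurality = 0.95, z_top = NA, z_transition = 8),
    deformation = list(contraction = NA, kappa = NA, lambda_l = NA,
                       twist_total = 0.15, z_fix_frac = 0.3),
    acquisition = list(tag_spacing = 7, kz_period_mm = 33, n_phases = 10L,
                       noise_sd = 0.05, es_frac = 0.4),
    lge = list(slice_thickness = 3, remote_mean = 100, remote_sd = 8,
               infarct_mean = 300),
    segmentation = list(n_chords = 120L, method = "fwhm", nsd_n = 3),
    stats = list(n_replicates = 5L, n_healthy = 200L, n_per_time = 100L,
                 contrasts = c("adjacent", "infarct"), table_csv = NA)
  )
}

.merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) stop("config section '", path, "' must be a mapping",
                           call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "/"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param config path to a YAML file, or a named list; missing keys take the
#'   documented defaults, unknown keys are rejected.
#' @return validated configuration list of class `run_config`.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(default_run_config(), config)
  if (is.null(cfg$seed) || is.na(cfg$seed)) {
    stop("config must provide a seed", call. = FALSE)
  }
  stopifnot(cfg$geometry$n_slices >= 3, cfg$acquisition$n_phases >= 2)
  structure(cfg, class = "run_config")
}
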