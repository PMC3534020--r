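# Segment-level strain sampler calibrated to published porcine infarct data.
#
# Each (class, time) cell of the calibration carries the per-measure mean and
# SD of end-systolic segment strain (percent).  Rows are drawn as independent
# Gaussians per measure: the source publication prints no covariance, so no
# multivariate structure is imposed (a documented limitation for joint-model
# targets; see the methods vignette).

.strain_measures <- c("Ecc", "Err", "Ell", "E1", "E2", "E3")

.cell_order <- data.frame(
  class = c("healthy", "remote", "remote", "adjacent", "adjacent", "infarct", "infarct"),
  time  = c("baseline", "early", "late", "early", "late", "early", "late"),
  stringsAsFactors = FALSE
)

#' Packaged segment-strain calibration table
#'
#' Per-cell (`class` x `time`) Gaussian means and SDs of end-systolic segment
#' strain in percent, for the six strain measures: directional (`Ecc`, `Err`,
#' `Ell`) and principal (`E1`, `E2`, `E3`).  Classes are `healthy` (pre-infarct
#' baseline only) and post-infarct `remote`, `adjacent`, `infarct` at `early`
#' (~11 days) and `late` (~1 month) time points.
#'
#' @return data.frame with columns `class`, `time`, `measure`, `mean`, `sd`.
#' @export
segment_strain_calibration <- function() {
  path <- system.file("extdata", "segment_strain_calibration.csv",
                      package = "zharpstrain", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.calibration_cell <- function(calibration, class, time) {
  cell <- calibration[calibration$class == class & calibration$time == time, ]
  if (nrow(cell) == 0) {
    stop(sprintf("calibration has no cell for class='%s', time='%s'", class, time),
         call. = FALSE)
  }
  missing <- setdiff(.strain_measures, cell$measure)
  if (length(missing) > 0) {
    stop(sprintf("calibration cell class='%s', time='%s' lacks measure(s): %s",
                 class, time, paste(missing, collapse = ", ")), call. = FALSE)
  }
  cell
}

#' Draw segment-level strain samples from a Gaussian calibration
#'
#' Generates independent Gaussian draws of the six strain measures for every
#' requested `(class, time)` cell.  Healthy segments exist only at baseline;
#' remote/adjacent/infarct only at the post-infarct time points.  Draws are
#' deterministic under a fixed seed and do not disturb the caller's RNG state.
#'
#' @param n_per_cell non-negative integer, rows drawn per cell.
#' @param seed integer seed (mandatory).
#' @param calibration calibration table as returned by
#'   [segment_strain_calibration()] (the default).
#' @param classes optional character vector restricting the classes drawn.
#' @param times optional character vector restricting the time points drawn.
#' @return data.frame with columns `class`, `time`, `Ecc`, `Err`, `Ell`,
#'   `E1`, `E2`, `E3` (strain in percent).
#' @export
sample_segment_strains <- function(n_per_cell, seed,
                                   calibration = segment_strain_calibration(),
                                   classes = NULL, times = NULL) {
  stopifnot(is.numeric(n_per_cell), length(n_per_cell) == 1, n_per_cell >= 0)
  if (missing(seed)) stop("a seed is required (reproducibility contract)", call. = FALSE)
  n_per_cell <- as.integer(n_per_cell)

  cells <- .cell_order
  if (!is.null(classes)) cells <- cells[cells$class %in% classes, , drop = FALSE]
  if (!is.null(times)) cells <- cells[cells$time %in% times, , drop = FALSE]
  if (!is.null(classes)) {
    unknown <- setdiff(classes, .cell_order$class)
    if (length(unknown) > 0) {
      stop("unknown class(es): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  empty <- data.frame(class = character(), time = character(),
                      Ecc = numeric(), Err = numeric(), Ell = numeric(),
                      E1 = numeric(), E2 = numeric(), E3 = numeric(),
                      stringsAsFactors = FALSE)
  if (n_per_cell == 0 || nrow(cells) == 0) return(empty)

  with_seed(seed, {
    out <- vector("list", nrow(cells))
    for (k in seq_len(nrow(cells))) {
      cell <- .calibration_cell(calibration, cells$class[k], cells$time[k])
      draws <- lapply(.strain_measures, function(m) {
        row <- cell[cell$measure == m, ]
        stats::rnorm(n_per_cell, mean = row$mean, sd = row$sd)
      })
      names(draws) <- .strain_measures
      out[[k]] <- data.frame(class = cells$class[k], time = cells$time[k],
                             draws, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Draw a paired healthy-vs-contrast sample for model comparison
#'
#' Builds the standard design used for the diagnostic-accuracy simulations:
#' `n_healthy` baseline healthy segments plus `n_per_time` segments of the
#' contrast class at each post-infarct time point (early and late pooled).
#'
#' @param contrast `"infarct"` or `"adjacent"`.
#' @param n_healthy healthy baseline rows.
#' @param n_per_time contrast rows per post-infarct time point.
#' @param seed integer seed.
#' @param calibration calibration table.
#' @return data.frame as from [sample_segment_strains()].
#' @export
draw_contrast_sample <- function(contrast = c("adjacent", "infarct"),
                                 n_healthy = 200, n_per_time = 100, seed,
                                 calibration = segment_strain_calibration()) {
  contrast <- match.arg(contrast)
  healthy <- sample_segment_strains(n_healthy, seed = stage_seed(seed, "healthy"),
                                    calibration = calibration, classes = "healthy")
  post <- sample_segment_strains(n_per_time, seed = stage_seed(seed, contrast),
                                 calibration = calibration, classes = contrast)
  rbind(healthy, post)
}

#' Write a strain sample set to CSV
#'
#' @param samples data.frame from [sample_segment_strains()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_strain_samples <- function(samples, path) {
  utils::write.csv(samples[, c("class", "time", .strain_measures)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
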