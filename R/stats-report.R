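# Model-comparison engine: 1D / 2D / 3D directional and 3D principal logistic
# models of segment strain, evaluated in-sample by ROC c-statistic with paired
# DeLong contrasts — the incremental-value question the package exists to
# answer.

.standard_models <- list(
  "1D"           = c("Ecc"),
  "2D"           = c("Ecc", "Err"),
  "3D"           = c("Ecc", "Err", "Ell"),
  "3D_principal" = c("E1", "E2", "E3")
)

#' Compare 1D, 2D and 3D strain models for one viability contrast
#'
#' Builds the paired design (baseline healthy segments versus one post-infarct
#' class with early and late time points pooled), applies the univariate entry
#' screen to the directional strains, fits the univariate (Ecc), bivariate
#' (Ecc + Err), multivariate (Ecc + Err + Ell) and principal-strain
#' (E1 + E2 + E3) logistic models, and summarises each by its in-sample ROC
#' c-statistic, Youden-point diagnostic accuracy, and pairwise DeLong tests.
#'
#' @param table data.frame with columns `class`, `time` and the six strain
#'   measures (e.g. from [sample_segment_strains()] or [segment_average()]).
#' @param contrast `"infarct"` or `"adjacent"`.
#' @param entry_p univariate entry threshold for the multivariable models.
#' @param models named list of covariate sets; default the standard four.
#' @return object of class `model_comparison_report`: per-model `roc`,
#'   `accuracy`, `fit`; `delong` (list of pairwise comparisons); `selected`
#'   covariates; design sizes.
#' @export
run_model_comparison <- function(table, contrast = c("adjacent", "infarct"),
                                 entry_p = 0.05, models = .standard_models) {
  contrast <- match.arg(contrast)
  stopifnot(all(c("class", "time") %in% names(table)))
  if (!any(table$class == contrast)) {
    stop("table contains no '", contrast, "' rows", call. = FALSE)
  }
  if (!any(table$class == "healthy")) {
    stop("table contains no 'healthy' rows", call. = FALSE)
  }
  # post-infarct time points pooled
  rows <- table[table$class %in% c("healthy", contrast), , drop = FALSE]
  y <- as.integer(rows$class == contrast)

  directional <- intersect(c("Ecc", "Err", "Ell"), names(rows))
  screen <- stepwise_select(rows[, directional, drop = FALSE], y, entry_p)

  fits <- list()
  rocs <- list()
  accuracy <- numeric(0)
  for (nm in names(models)) {
    vars <- models[[nm]]
    gated <- vars
    # multivariable directional models only admit screened covariates
    if (length(vars) > 1 && all(vars %in% directional)) {
      gated <- intersect(vars, screen$selected)
      if (length(gated) == 0) gated <- vars[1]
    }
    fit <- fit_logistic(rows[, gated, drop = FALSE], y)
    roc <- roc_auc(fit$linear_predictors, y)
    fits[[nm]] <- fit
    rocs[[nm]] <- roc
    accuracy[nm] <- as.numeric(diagnostic_accuracy(roc))
  }

  pairs <- utils::combn(names(models), 2, simplify = FALSE)
  delong <- lapply(pairs, function(p) {
    cmp <- delong_test(rocs[[p[1]]], rocs[[p[2]]])
    list(model_a = p[1], model_b = p[2], auc_diff = cmp$auc_diff,
         z = cmp$z, p_value = cmp$p_value)
  })

  structure(list(
    contrast = contrast,
    n_healthy = sum(y == 0), n_contrast = sum(y == 1),
    selected = screen$selected, univariate_p = screen$p_values,
    models = stats::setNames(lapply(names(models), function(nm) list(
      name = nm, covariates = fits[[nm]]$covariates,
      coefficients = fits[[nm]]$coefficients,
      c_statistic = rocs[[nm]]$auc, se = rocs[[nm]]$se, ci = rocs[[nm]]$ci,
      accuracy = accuracy[[nm]]
    )), names(models)),
    roc = rocs, fits = fits, delong = delong,
    accuracy_rule = "youden"
  ), class = "model_comparison_report")
}

#' @export
print.model_comparison_report <- function(x, ...) {
  cat(sprintf("Contrast: healthy vs %s (%d vs %d segments)\n",
              x$contrast, x$n_healthy, x$n_contrast))
  cat("Screened covariates:", paste(x$selected, collapse = ", "), "\n")
  for (m in x$models) {
    cat(sprintf("  %-12s c-statistic %.3f (SE %.3f)  accuracy %.0f%%\n",
                m$name, m$c_statistic, m$se, m$accuracy))
  }
  for (d in x$delong) {
    cat(sprintf("  %s vs %s: diff %+.4f, p = %.4g\n",
                d$model_a, d$model_b, d$auc_diff, d$p_value))
  }
  invisible(x)
}

#' Serialise a model-comparison report to JSON
#'
#' @param report a `model_comparison_report`.
#' @param path output path; if `NULL` the JSON string is returned.
#' @return path invisibly, or JSON string.
#' @export
write_model_comparison <- function(report, path = NULL) {
  payload <- list(
    contrast = report$contrast,
    n_healthy = report$n_healthy,
    n_contrast = report$n_contrast,
    accuracy_rule = report$accuracy_rule,
    selected_covariates = report$selected,
    models = lapply(report$models, function(m) {
      m$coefficients <- as.list(m$coefficients)
      m
    }),
    delong = report$delong
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Replicated c-statistics on calibration-driven draws
#'
#' Repeats the healthy-vs-contrast simulation: per replicate, draws the
#' standard design from the packaged Gaussian calibration, runs the model
#' comparison, and records each model's in-sample c-statistic.  Replicate
#' seeds are `seed + 0 .. n_replicates - 1`.
#'
#' @param contrast `"adjacent"` or `"infarct"`.
#' @param n_replicates number of replicates.
#' @param seed base seed.
#' @param n_healthy,n_per_time design sizes per replicate.
#' @param calibration calibration table.
#' @return data.frame: `replicate`, `seed`, one column per model with the
#'   in-sample c-statistic.
#' @export
replicate_cstatistics <- function(contrast, n_replicates = 25, seed = 1,
                                  n_healthy = 200, n_per_time = 100,
                                  calibration = segment_strain_calibration()) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + r - 1
    tab <- draw_contrast_sample(contrast, n_healthy = n_healthy,
                                n_per_time = n_per_time, seed = rep_seed,
                                calibration = calibration)
    rep_report <- suppressWarnings(run_model_comparison(tab, contrast))
    aucs <- vapply(rep_report$models, function(m) m$c_statistic, numeric(1))
    out[[r]] <- data.frame(replicate = r, seed = rep_seed, t(aucs),
                           check.names = FALSE)
  }
  do.call(rbind, out)
}

#' Plot ROC curves of a model-comparison report
#'
#' @param report a `model_comparison_report`.
#' @return a ggplot object (requires the suggested ggplot2 package).
#' @export
plot_roc_curves <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- do.call(rbind, lapply(names(report$roc), function(nm) {
    cv <- report$roc[[nm]]$curve
    data.frame(model = nm, fpr = 1 - cv$spec, tpr = cv$sens)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr, colour = model)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("healthy vs %s", report$contrast)) +
    ggplot2::coord_equal()
}
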