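# Logistic-regression layer of the model-comparison engine.  Fitting is
# delegated to stats::glm (iteratively reweighted least squares); this file
# owns input validation, Wald summaries, separation detection and the
# univariate entry screen.

#' Fit a binary logistic regression model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares.  Perfect
#' separation is detected (diverging coefficients / degenerate fitted
#' probabilities) and reported via the `separation` flag; the fit obtained at
#' the iteration cap is still returned.
#'
#' @param x data.frame or matrix of covariates (no constant columns).
#' @param y binary response: logical, 0/1 numeric, or two-level factor.
#' @param max_iter maximum IRLS iterations.
#' @param tol convergence tolerance on the relative deviance change.
#' @return object of class `logistic_model` with elements `coefficients`,
#'   `se`, `z`, `p_values`, `vcov`, `converged`, `separation`, `deviance`,
#'   `null_deviance`, `fitted`, `linear_predictors`, `terms`.
#' @export
fit_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  x <- as.data.frame(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (min(table(y)) < 2) stop("need at least 2 rows per class", call. = FALSE)
  const <- vapply(x, function(col) stats::var(as.numeric(col)) == 0, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ", paste(names(x)[const], collapse = ", "),
         call. = FALSE)
  }

  dat <- cbind(x, .y = y)
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  separation <- sep_warned || any(abs(stats::coef(fit)[-1]) > 1e4)
  if (separation) {
    warning("possible complete separation; coefficients may be unbounded",
            call. = FALSE)
  }

  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = stats::coef(fit),
    se = sm[, "Std. Error"],
    z = sm[, "z value"],
    p_values = sm[, "Pr(>|z|)"],
    vcov = stats::vcov(fit),
    converged = fit$converged,
    separation = separation,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    fitted = stats::fitted(fit),
    linear_predictors = fit$linear.predictors,
    covariates = names(x),
    glm = fit
  ), class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model:", paste(x$covariates, collapse = " + "), "\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p_values)
  print(round(tab, 4))
  if (x$separation) cat("note: possible complete separation\n")
  invisible(x)
}

#' Predict linear scores from a logistic model
#'
#' @param object a `logistic_model`.
#' @param newdata data.frame with the model's covariates; if omitted the
#'   in-sample linear predictors are returned.
#' @param ... unused.
#' @return numeric vector of linear-predictor scores.
#' @export
predict.logistic_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$linear_predictors)
  as.numeric(stats::predict(object$glm, newdata = as.data.frame(newdata),
                            type = "link"))
}

#' Univariate entry screen for multivariable models
#'
#' Each candidate covariate is fitted alone against the response; candidates
#' whose Wald p-value falls below `entry_p` are selected as covariates for the
#' multivariable models.
#'
#' @param x data.frame of candidate covariates.
#' @param y binary response.
#' @param entry_p entry threshold in (0, 1), default 0.05.
#' @return list with `selected` (character vector) and `p_values`
#'   (named numeric of univariate Wald p-values).
#' @export
stepwise_select <- function(x, y, entry_p = 0.05) {
  stopifnot(entry_p > 0, entry_p < 1)
  x <- as.data.frame(x)
  p <- vapply(names(x), function(nm) {
    fit <- fit_logistic(x[, nm, drop = FALSE], y)
    unname(fit$p_values[2])
  }, numeric(1))
  list(selected = names(x)[p < entry_p], p_values = p)
}
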