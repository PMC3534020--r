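# ROC analysis with DeLong structural components.
#
# The c-statistic is computed from midranks (exactly the Mann-Whitney U with
# ties counted 1/2) and its variance from the DeLong placement components, so
# paired AUC differences can be tested without resampling.

#' ROC curve and c-statistic with DeLong standard error
#'
#' @param scores numeric scores; larger is taken to indicate the positive class.
#' @param labels binary labels (logical, 0/1, or two-level factor); 1/TRUE is
#'   the positive class.
#' @param conf_level confidence level for the logit-transformed Wald CI.
#' @return object of class `roc_result`: `auc`, `se`, `ci`, `n_pos`, `n_neg`,
#'   `curve` (data.frame threshold/sens/spec), placement components `v10`,
#'   `v01`, plus the input `scores` and `labels`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)

  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  auc <- (sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong placements: v10_i = P(neg < pos_i) + P(neg == pos_i)/2, and dually.
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)

  ci <- if (auc > 0 && auc < 1 && se > 0) {
    l <- stats::qlogis(auc)
    sl <- se / (auc * (1 - auc))
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    stats::plogis(c(l - zq * sl, l + zq * sl))
  } else {
    c(auc, auc)
  }

  thr <- sort(unique(scores))
  cut <- c(-Inf, thr)  # predict positive when score > cut
  sens <- vapply(cut, function(t) mean(pos > t), numeric(1))
  spec <- vapply(cut, function(t) mean(neg <= t), numeric(1))

  structure(list(
    auc = auc, se = se, ci = ci, n_pos = n1, n_neg = n0,
    curve = data.frame(cutoff = cut, sens = sens, spec = spec),
    v10 = v10, v01 = v01, scores = scores, labels = labels
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: c-statistic %.3f (SE %.4f, %d pos / %d neg), CI [%.3f, %.3f]\n",
              x$auc, x$se, x$n_pos, x$n_neg, x$ci[1], x$ci[2]))
  invisible(x)
}

#' DeLong paired comparison of two c-statistics
#'
#' Both ROC results must be computed on the same rows (identical labels in the
#' same order): the covariance of the two AUCs is estimated from the paired
#' placement components.
#'
#' @param roc_a,roc_b `roc_result` objects from [roc_auc()] on paired scores.
#' @return list of class `delong_comparison`: `auc_diff`, `var_diff`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (length(roc_a$labels) != length(roc_b$labels) ||
      any(roc_a$labels != roc_b$labels)) {
    stop("DeLong comparison requires paired scores on identical rows",
         call. = FALSE)
  }
  n1 <- roc_a$n_pos
  n0 <- roc_a$n_neg
  d10 <- roc_a$v10 - roc_b$v10
  d01 <- roc_a$v01 - roc_b$v01
  var_diff <- (if (n1 > 1) stats::var(d10) else 0) / n1 +
    (if (n0 > 1) stats::var(d01) else 0) / n0
  diff <- roc_a$auc - roc_b$auc
  z <- if (var_diff > 0) diff / sqrt(var_diff) else 0
  p <- if (var_diff > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(diff == 0) * 1
  if (var_diff == 0 && diff != 0) p <- 0
  structure(list(auc_diff = diff, var_diff = var_diff, z = z, p_value = p),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC diff %.4f, z = %.3f, p = %.4g\n",
              x$auc_diff, x$z, x$p_value))
  invisible(x)
}

#' Diagnostic accuracy at an operating point
#'
#' Accuracy `(TP + TN)/n` at the cutoff chosen by the given rule.  The only
#' implemented rule is `youden`: the cutoff maximising sensitivity +
#' specificity - 1 (ties broken toward higher accuracy, then lower cutoff).
#'
#' @param roc a `roc_result`.
#' @param rule operating-point rule; only `"youden"`.
#' @return accuracy in percent, with attributes `cutoff`, `sens`, `spec`.
#' @export
diagnostic_accuracy <- function(roc, rule = "youden") {
  rule <- match.arg(rule, "youden")
  cv <- roc$curve
  n1 <- roc$n_pos
  n0 <- roc$n_neg
  j <- cv$sens + cv$spec - 1
  acc <- (cv$sens * n1 + cv$spec * n0) / (n1 + n0)
  best_j <- max(j)
  cand <- which(j >= best_j - 1e-12)
  cand <- cand[order(-acc[cand], cv$cutoff[cand])]
  k <- cand[1]
  structure(100 * acc[k], cutoff = cv$cutoff[k], sens = cv$sens[k],
            spec = cv$spec[k], rule = rule)
}
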