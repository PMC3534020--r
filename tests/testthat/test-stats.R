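# Logistic fitting, ROC/DeLong machinery and the model-comparison engine,
# checked against closed forms and brute-force oracles.

test_that("logistic fit recovers null and closed-form slopes", {
  # symmetric null: zero-information covariate
  set.seed(4)
  x <- data.frame(Ecc = rnorm(400))
  y <- rep(c(0, 1), 200)
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$coefficients[["Ecc"]]), 0.2)
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 0.2)
  expect_true(fit$converged)

  # two-Gaussian data, equal variance: slope -> (mu1 - mu0) / sigma^2 (LDA
  # equivalence at large n)
  set.seed(5)
  n <- 40000
  mu0 <- -1; mu1 <- 1; sigma <- 2
  xx <- c(rnorm(n, mu0, sigma), rnorm(n, mu1, sigma))
  yy <- rep(0:1, each = n)
  fit2 <- fit_logistic(data.frame(v = xx), yy)
  expect_lt(abs(fit2$coefficients[["v"]] - (mu1 - mu0) / sigma^2), 0.03)

  # optimality: in-sample log-likelihood beats perturbed coefficients
  ll <- function(beta) {
    eta <- beta[1] + beta[2] * xx
    sum(yy * eta - log1p(exp(eta)))
  }
  opt <- c(fit2$coefficients[["(Intercept)"]], fit2$coefficients[["v"]])
  for (d in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    expect_gt(ll(opt), ll(opt + d))
  }
})

test_that("logistic fit validates input and flags separation", {
  expect_error(fit_logistic(data.frame(a = rep(1, 10)), rep(0:1, 5)),
               "constant")
  expect_error(fit_logistic(data.frame(a = rnorm(10)), c(1, rep(0, 9))),
               "2 rows per class")
  sep <- data.frame(a = c(-(5:1), 1:5))
  fit <- suppressWarnings(fit_logistic(sep, c(rep(0, 5), rep(1, 5))))
  expect_true(fit$separation)
})

test_that("univariate screen has the nominal entry rate and power", {
  # pure-noise covariate enters at about the entry threshold
  hits <- vapply(1:400, function(r) {
    set.seed(1000 + r)
    x <- data.frame(noise = rnorm(200))
    y <- rep(0:1, 100)
    "noise" %in% stepwise_select(x, y, entry_p = 0.05)$selected
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)

  # a covariate with 1.5 SD class separation always enters at n = 200
  set.seed(77)
  x <- data.frame(sig = c(rnorm(100), rnorm(100, 1.5)))
  y <- rep(0:1, each = 100)
  expect_true("sig" %in% stepwise_select(x, y)$selected)
})

test_that("AUC equals the exhaustive pair-count oracle, with ties at 1/2", {
  brute_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(8)
  for (r in 1:40) {
    n1 <- sample(2:60, 1); n0 <- sample(2:60, 1)
    scores <- sample(seq(-3, 3, by = 0.5), n1 + n0, replace = TRUE) # many ties
    labels <- c(rep(1, n1), rep(0, n0))
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # degenerate corners
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("DeLong variance tracks the bootstrap and self-comparison is null", {
  set.seed(12)
  scores <- c(rnorm(100), rnorm(100, 1))
  labels <- rep(0:1, each = 100)
  r <- roc_auc(scores, labels)
  boot <- vapply(1:2000, function(i) {
    idx1 <- sample(which(labels == 1), replace = TRUE)
    idx0 <- sample(which(labels == 0), replace = TRUE)
    roc_auc(scores[c(idx1, idx0)], labels[c(idx1, idx0)])$auc
  }, numeric(1))
  expect_lt(abs(r$se - sd(boot)) / sd(boot), 0.15)

  self <- delong_test(r, r)
  expect_equal(self$auc_diff, 0)
  expect_equal(self$p_value, 1)
  r2 <- roc_auc(rnorm(200), labels)
  expect_error(delong_test(r, roc_auc(rnorm(50), rep(0:1, 25))), "paired")
  expect_s3_class(delong_test(r, r2), "delong_comparison")
})

test_that("diagnostic accuracy at the Youden point matches a threshold scan", {
  brute <- function(scores, labels) {
    cuts <- c(-Inf, sort(unique(scores)))
    accs <- vapply(cuts, function(t) {
      pred <- scores > t
      mean(pred == (labels == 1))
    }, numeric(1))
    js <- vapply(cuts, function(t) {
      mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1
    }, numeric(1))
    100 * max(accs[js >= max(js) - 1e-12])
  }
  set.seed(3)
  for (r in 1:20) {
    scores <- sample(1:8, 30, replace = TRUE)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- roc_auc(scores, labels)
    expect_equal(as.numeric(diagnostic_accuracy(roc)), brute(scores, labels))
  }
  expect_equal(as.numeric(diagnostic_accuracy(roc_auc(c(1, 2, 3, 4),
                                                      c(0, 0, 1, 1)))), 100)
  expect_equal(as.numeric(diagnostic_accuracy(roc_auc(rep(1, 10),
                                                      rep(0:1, 5)))), 50)
})

test_that("model comparison runs the paired contrast end to end", {
  tab <- draw_contrast_sample("adjacent", n_healthy = 120, n_per_time = 60,
                              seed = 31)
  rep <- suppressWarnings(run_model_comparison(tab, "adjacent"))
  expect_setequal(rep$selected, c("Ecc", "Err", "Ell"))
  aucs <- vapply(rep$models, function(m) m$c_statistic, numeric(1))
  expect_true(all(aucs > 0.5 & aucs <= 1))
  # nested in-sample likelihood ordering shows up in the AUCs here
  expect_gte(aucs[["3D"]], aucs[["2D"]])
  expect_gte(aucs[["2D"]], aucs[["1D"]])
  # null contrast: same distribution in both classes
  null_tab <- tab
  null_tab[null_tab$class == "adjacent",
           c("Ecc", "Err", "Ell", "E1", "E2", "E3")] <-
    sample_segment_strains(120, seed = 99, classes = "healthy")[
      , c("Ecc", "Err", "Ell", "E1", "E2", "E3")]
  null_rep <- suppressWarnings(run_model_comparison(null_tab, "adjacent"))
  expect_lt(null_rep$models[["3D"]]$c_statistic, 0.65)

  expect_error(run_model_comparison(tab[tab$class == "healthy", ], "adjacent"),
               "no 'adjacent' rows")

  # JSON serialisation round-trips the key numbers
  js <- jsonlite::fromJSON(write_model_comparison(rep))
  expect_equal(js$models$`3D`$c_statistic, aucs[["3D"]], tolerance = 1e-12)
})

test_that("replicated c-statistics are reproducible under a fixed seed", {
  a <- replicate_cstatistics("adjacent", n_replicates = 3, seed = 5,
                             n_healthy = 60, n_per_time = 30)
  b <- replicate_cstatistics("adjacent", n_replicates = 3, seed = 5,
                             n_healthy = 60, n_per_time = 30)
  expect_identical(a, b)
  expect_named(a, c("replicate", "seed", "1D", "2D", "3D", "3D_principal"))
})
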