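model_fixture <- function(n = 200, seed = 30, beta = c(1, -0.5)) {
  withr::with_seed(seed, {
    x <- data.frame(a = rnorm(n), b = rnorm(n))
    p <- plogis(0.3 + as.matrix(x) %*% beta)
    list(x = x, y = as.numeric(runif(n) < p))
  })
}

test_that("odds ratios are exactly exp(coefficients) and match glm", {
  fx <- model_fixture()
  fit <- fit_logistic(fx$x, fx$y)
  ref <- glm(y ~ a + b, data = cbind(fx$x, y = fx$y), family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_identical(fit$or, exp(fit$coefficients))
  expect_identical(fit$ci_lo, exp(fit$coefficients - 1.959964 * fit$se))
  expect_false(fit$separation)
  expect_lt(fit$model_p, 0.05)
  expect_true(fit$r2_nagelkerke >= fit$r2_coxsnell)
})

test_that("trapezoidal AUC equals the Mann-Whitney U probability, ties included", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- 40
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(rnorm(n, mean = y), 1)          # rounding forces ties
      expect_equal(roc_auc(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
    }
  })
  # degenerate and perfect cases
  expect_error(roc_auc(1:5, c(1, 1, 1, 1, 1)), "both classes")
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0)
})

test_that("pROC agrees with the in-house AUC on a shared fixture", {
  skip_if_not_installed("pROC")
  withr::with_seed(32, {
    y <- rbinom(60, 1, 0.5)
    s <- rnorm(60, mean = 0.8 * y)
  })
  ours <- roc_auc(s, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("complete separation is flagged without penalizing the fit", {
  x <- data.frame(a = c(-3, -2, -1, 1, 2, 3, -1.5, 2.5, -2.2, 1.2))
  y <- as.numeric(x$a > 0)
  fit <- fit_logistic(x, y)
  expect_true(fit$separation)
  expect_error(fit_logistic(x, rep(1, 10)), "single class")
})

test_that("the sensitivity-specificity product test behaves at its boundaries", {
  fx <- model_fixture(n = 150, seed = 33)
  fit <- fit_logistic(fx$x, fx$y)
  roc <- roc_auc(fit$fitted, fx$y)
  out <- auc_comparison_test(roc)
  expect_lt(out$p, 0.05)                        # a real model beats chance
  expect_identical(auc_comparison_test(roc, roc)$p, 1)   # self-comparison
  bonf <- auc_comparison_test(roc, n_comparisons = 134)
  expect_equal(bonf$p, min(1, bonf$p_raw * 134))
})

test_that("leave-one-out is deterministic, out-of-sample and flags one-class folds", {
  fx <- model_fixture(n = 60, seed = 34)
  l1 <- loo_predict(fx$x, fx$y)
  l2 <- loo_predict(fx$x, fx$y)
  expect_identical(l1$probs, l2$probs)
  expect_true(all(l1$probs >= 0 & l1$probs <= 1, na.rm = TRUE))
  # fold i must not depend on observation i: predictions differ from fitted
  fit <- fit_logistic(fx$x, fx$y)
  expect_gt(max(abs(l1$probs - fit$fitted)), 1e-6)
  expect_error(loo_predict(fx$x[1:5, ], fx$y[1:5]), "n >= 10")
  # nearly-constant outcome: removing a lone success starves that fold,
  # and the cross-validated AUC becomes undefined rather than erroring
  y1 <- c(1, rep(0, 11))
  x1 <- data.frame(a = rnorm(12))
  starved <- suppressWarnings(loo_predict(x1, y1))
  expect_identical(starved$flagged_folds, 1L)
  expect_true(is.na(starved$auc))
})

test_that("calibration bins partition the probabilities and the rank test has the right sign", {
  withr::with_seed(35, {
    p <- runif(300)
    ilae <- ifelse(runif(300) < p, 1L, sample(2:6, 300, replace = TRUE))
  })
  cal <- calibration_and_rank(p, ilae)
  expect_equal(sum(cal$bins$n), 300)
  expect_equal(cal$high_conf$n, sum(p > 0.8))
  expect_equal(cal$low_conf$n, sum(p < 0.2))
  expect_true(all(cal$bins$freq >= 0 & cal$bins$freq <= 1, na.rm = TRUE))
  # higher predicted success must rank with better (lower) outcome class
  expect_lt(cal$spearman_rho, 0)
  expect_lt(cal$spearman_p, 0.001)
  expect_error(calibration_and_rank(c(0.5, 1.2), c(1, 2)), "probs")
})
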