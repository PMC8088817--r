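#' Fit a logistic outcome model
#'
#' Maximum-likelihood logistic regression of surgical success on a
#' covariate matrix, reporting per-covariate odds ratios with Wald 95%
#' confidence intervals and the Cox-Snell and Nagelkerke pseudo-R2.
#' Complete or quasi-separation is flagged (not penalized): the affected
#' odds ratios are reported as fitted, with their confidence intervals
#' marked unbounded.
#'
#' @param x numeric matrix or data.frame of covariates (no intercept
#'   column; one is added).
#' @param y logical or 0/1 success vector.
#' @return a `logistic_fit` list: `coefficients`, `se`, `or`, `ci_lo`,
#'   `ci_hi`, `r2_nagelkerke`, `r2_coxsnell`, `fitted`, `separation`,
#'   `model_p` (likelihood-ratio test), `n`.
#' @export
fit_logistic <- function(x, y) {
  x <- as.data.frame(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  dat <- cbind(x, .success = y)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.success ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  n <- length(y)
  dev <- fit$deviance; dev0 <- fit$null.deviance
  r2_cs <- 1 - exp((dev - dev0) / n)
  r2_nk <- r2_cs / (1 - exp(-dev0 / n))
  lrt_p <- stats::pchisq(dev0 - dev, df = fit$df.null - fit$df.residual,
                         lower.tail = FALSE)
  structure(list(
    coefficients = est, se = se,
    or = exp(est), ci_lo = exp(est - 1.959964 * se),
    ci_hi = exp(est + 1.959964 * se),
    r2_nagelkerke = r2_nk, r2_coxsnell = r2_cs,
    fitted = as.numeric(stats::fitted(fit)),
    separation = sep, model_p = lrt_p, n = n, glm = fit),
    class = "logistic_fit")
}

#' Predict success probabilities from a fitted logistic model
#' @param object a `logistic_fit`; `newdata` covariate data.frame.
#' @param newdata covariates for prediction.
#' @param ... unused.
#' @return numeric probabilities.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$glm, newdata = as.data.frame(newdata),
                            type = "response"))
}

#' ROC curve and trapezoidal AUC
#'
#' Thresholds are the unique scores (ties share a point); the curve is
#' completed with the (0,0) and (1,1) corners and the AUC is the
#' trapezoidal area, which equals the Mann-Whitney U probability
#' `P(score_pos > score_neg) + 0.5 P(equal)`.
#'
#' @param scores numeric classifier scores (higher = more likely
#'   positive).
#' @param labels logical or 0/1 class labels.
#' @return list `auc`, `curve` (data.frame `threshold`, `sensitivity`,
#'   `specificity`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / np, 0)
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / nn, 0)
  fpr <- c(0, 1 - spec, 1); tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = data.frame(threshold = thr, sensitivity = sens,
                          specificity = spec),
       n_pos = np, n_neg = nn)
}

#' Compare an ROC curve with chance or another curve
#'
#' Implements the per-threshold comparison of sensitivity-times-
#' specificity products: the products along curve A are tested with a
#' t-test against the constant chance value 0.25 (the product along the
#' diagonal), or with a paired t-test against the products of curve B.
#' Curves with unequal threshold grids are linearly resampled onto a
#' common grid (flagged).  The returned p-value is multiplied by
#' `n_comparisons` (Bonferroni), capped at 1.
#'
#' @param roc_a [roc_auc()] result.
#' @param roc_b optional second curve; when NULL the comparison is
#'   against chance.
#' @param n_comparisons Bonferroni family size (default 1).
#' @return list `p` (corrected), `p_raw`, `statistic`, `resampled`.
#' @export
auc_comparison_test <- function(roc_a, roc_b = NULL, n_comparisons = 1) {
  pa <- roc_a$curve$sensitivity * roc_a$curve$specificity
  resampled <- FALSE
  if (is.null(roc_b)) {
    tt <- stats::t.test(pa, mu = 0.25)
  } else {
    pb <- roc_b$curve$sensitivity * roc_b$curve$specificity
    if (length(pa) != length(pb)) {
      resampled <- TRUE
      m <- max(length(pa), length(pb))
      g <- seq(0, 1, length.out = m)
      pa <- stats::approx(seq(0, 1, length.out = length(pa)), pa, g)$y
      pb <- stats::approx(seq(0, 1, length.out = length(pb)), pb, g)$y
    }
    if (isTRUE(all.equal(pa, pb)))
      return(list(p = 1, p_raw = 1, statistic = 0, resampled = resampled))
    tt <- stats::t.test(pa, pb, paired = TRUE)
  }
  list(p = min(1, tt$p.value * n_comparisons), p_raw = tt$p.value,
       statistic = unname(tt$statistic), resampled = resampled)
}

#' Leave-one-out cross-validated success probabilities
#'
#' For each patient, the model is refitted on the remaining n-1 patients
#' and the held-out patient's success probability predicted; the pooled
#' out-of-sample probabilities give the cross-validated ROC/AUC.  Fitting
#' is deterministic, so identical inputs give identical probabilities.
#'
#' @param x covariate data.frame (no intercept).
#' @param y success vector.
#' @return list `probs` (per patient, NA for folds whose training
#'   outcome had a single class, flagged), `auc`, `roc`, `flagged_folds`.
#' @export
loo_predict <- function(x, y) {
  x <- as.data.frame(x)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("leave-one-out needs n >= 10")
  probs <- rep(NA_real_, n)
  flagged <- integer()
  for (i in seq_len(n)) {
    yt <- y[-i]
    if (length(unique(yt)) < 2) { flagged <- c(flagged, i); next }
    fit <- suppressWarnings(
      stats::glm(.success ~ ., data = cbind(x[-i, , drop = FALSE],
                                            .success = yt),
                 family = stats::binomial()))
    # rank-deficient folds (a covariate constant in the n-1 training set)
    # still predict via the estimable part; the warning is expected
    probs[i] <- suppressWarnings(
      as.numeric(stats::predict(fit, newdata = x[i, , drop = FALSE],
                                type = "response")))
  }
  ok <- !is.na(probs)
  if (length(unique(y[ok])) < 2) {
    # dropping the flagged folds left a single outcome class: the
    # cross-validated AUC is undefined, not an error
    return(list(probs = probs, auc = NA_real_, roc = NULL,
                flagged_folds = flagged))
  }
  roc <- roc_auc(probs[ok], y[ok])
  list(probs = probs, auc = roc$auc, roc = roc, flagged_folds = flagged)
}

#' Calibration bins and outcome-rank association
#'
#' Bins the cross-validated success probabilities into deciles and
#' reports the observed success frequency per bin, plus the summary
#' cells for predicted probability above 0.8 and below 0.2.  The Spearman
#' rank correlation between predicted probability and the ILAE outcome
#' class is reported; the class grows as the outcome worsens, so a
#' well-performing model has negative rho.
#'
#' @param probs predicted success probabilities in `[0, 1]`.
#' @param ilae_classes integer outcome classes 1-6 (success = class 1).
#' @return list `bins` (data.frame `lo`, `hi`, `n`, `n_success`,
#'   `freq` -- NA for empty bins), `high_conf`, `low_conf` (n, n_success,
#'   freq for probs > 0.8 / < 0.2), `spearman_rho`, `spearman_p`.
#' @export
calibration_and_rank <- function(probs, ilae_classes) {
  stopifnot(all(probs >= 0 & probs <= 1, na.rm = TRUE),
            all(ilae_classes %in% 1:6))
  success <- ilae_classes == 1
  br <- seq(0, 1, by = 0.1)
  bin <- cut(probs, breaks = br, include.lowest = TRUE, right = FALSE)
  levels(bin)[10] <- "[0.9,1]"
  tab <- data.frame(lo = utils::head(br, -1), hi = utils::tail(br, -1))
  tab$n <- as.integer(table(bin))
  tab$n_success <- as.integer(tapply(success, bin, sum, default = 0))
  tab$freq <- ifelse(tab$n > 0, tab$n_success / tab$n, NA_real_)
  cell <- function(sel) list(n = sum(sel, na.rm = TRUE),
                             n_success = sum(success & sel, na.rm = TRUE),
                             freq = if (sum(sel, na.rm = TRUE))
                               sum(success & sel, na.rm = TRUE) / sum(sel, na.rm = TRUE)
                             else NA_real_)
  sp <- suppressWarnings(
    stats::cor.test(probs, ilae_classes, method = "spearman"))
  list(bins = tab,
       high_conf = cell(probs > 0.8), low_conf = cell(probs < 0.2),
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}
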