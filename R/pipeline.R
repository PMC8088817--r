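#' Pipeline run configuration
#'
#' @param cohort a [cohort_spec()].
#' @param variants biomarker variants to model; any of `"rate"`
#'   (Subtraction-HFO), `"zrate"` (Subtraction-zHFO), `"mi"`
#'   (Subtraction-MI), `"zmi"` (Subtraction-zMI).
#' @param atlas_k normative-atlas neighbour count (default 60).
#' @param outlier_sd atlas one-sided outlier threshold (default 10).
#' @return a `run_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            variants = c("rate", "zrate", "mi", "zmi"),
                            atlas_k = 60, outlier_sd = 10) {
  stopifnot(inherits(cohort, "cohort_spec"),
            all(variants %in% c("rate", "zrate", "mi", "zmi")))
  structure(list(cohort = cohort, variants = variants,
                 atlas_k = atlas_k, outlier_sd = outlier_sd),
            class = "run_config")
}

# FNV-1a hash of the serialized config, for provenance stamping
config_hash <- function(config) {
  s <- utf8ToInt(as.character(jsonlite::toJSON(unclass_deep(config),
                                               auto_unbox = TRUE, digits = NA)))
  h <- 5381
  for (b in s) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

# nearest-neighbour order of pooled non-epileptic sites for every
# channel in the cohort, computed once (the order is independent of the
# neighbour count k and of the biomarker variant).  Leave-self-out:
# atlas sites never appear in their own neighbour list.
cohort_knn <- function(channels, max_k) {
  coords <- do.call(rbind, lapply(channels, function(ch)
    as.matrix(ch[, c("x_mm", "y_mm", "z_mm")])))
  in_atlas <- unlist(lapply(channels, function(ch)
    ch$non_epileptic & !ch$artifact), use.names = FALSE)
  sites <- coords[in_atlas, , drop = FALSE]
  m <- nrow(sites)
  if (m < max_k + 1) stop("atlas needs at least k = ", max_k,
                          " non-epileptic sites; got ", m)
  n <- nrow(coords)
  take <- min(m, max_k + 1L)
  nb <- matrix(0L, nrow = n, ncol = take)
  self_idx <- rep(NA_integer_, n)
  self_idx[in_atlas] <- seq_len(m)
  s2 <- rowSums(sites^2)
  chunk <- 1024L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    q <- coords[s:e, , drop = FALSE]
    D <- outer(rowSums(q^2), s2, `+`) - 2 * q %*% t(sites)
    for (i in seq_len(e - s + 1L)) {
      o <- order(D[i, ], seq_len(m))        # ties broken by site index
      nb[s + i - 1L, ] <- o[seq_len(take)]
    }
  }
  list(nb = nb, in_atlas = in_atlas, self_idx = self_idx,
       n_per_patient = vapply(channels, nrow, 0L))
}

# z-score all channels for one biomarker variant and neighbour count,
# reusing a cohort_knn result
knn_zscores <- function(knn, site_values, values, k, outlier_sd) {
  n <- nrow(knn$nb)
  z <- numeric(n)
  for (i in seq_len(n)) {
    nbi <- knn$nb[i, ]
    if (!is.na(knn$self_idx[i])) nbi <- nbi[nbi != knn$self_idx[i]]
    v <- site_values[nbi[seq_len(k)]]
    mu <- mean(v); sigma <- stats::sd(v)
    if (is.finite(sigma) && sigma > 0) {
      keep <- v <= mu + outlier_sd * sigma
      if (!all(keep)) {
        v <- v[keep]; mu <- mean(v)
        sigma <- if (length(v) > 1) stats::sd(v) else 0
      }
    } else sigma <- 0
    z[i] <- if (sigma > 0) (values[i] - mu) / sigma else NA_real_
  }
  split(z, rep(seq_along(knn$n_per_patient), knn$n_per_patient))
}

# pool non-epileptic, non-artifact sites across the cohort and z-score
# every analysed channel against the k closest ones (leave-self-out for
# channels that are themselves atlas sites)
cohort_zscores <- function(channels, value_col, k, outlier_sd,
                           knn = NULL) {
  if (is.null(knn)) knn <- cohort_knn(channels, k)
  vals <- unlist(lapply(channels, function(ch) ch[[value_col]]),
                 use.names = FALSE)
  knn_zscores(knn, vals[knn$in_atlas], vals, k, outlier_sd)
}

variant_column <- function(variant) {
  switch(variant, rate = "rate", zrate = "z_rate", mi = "mi", zmi = "z_mi")
}

#' Run the end-to-end biomarker pipeline on a synthetic cohort
#'
#' simulate -> normative atlas / z-scoring -> Subtraction biomarkers ->
#' standard and biomarker-augmented logistic models with in-sample and
#' leave-one-out AUC.  Deterministic given the cohort seed: rerunning
#' with the same config yields a byte-identical JSON payload.
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list: `config_hash`, `seed`, `warnings`,
#'   `standard` model summary, `models` (per variant), `na_log`, and the
#'   `bundle` (as attribute, not serialized).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- simulate_cohort(config$cohort)
  channels <- bundle$channels
  need_z <- any(c("zrate", "zmi") %in% config$variants)
  if (need_z) {
    knn <- cohort_knn(channels, config$atlas_k)
    z_rate <- cohort_zscores(channels, "rate", config$atlas_k,
                             config$outlier_sd, knn = knn)
    z_mi <- cohort_zscores(channels, "mi", config$atlas_k,
                           config$outlier_sd, knn = knn)
    for (i in seq_along(channels)) {
      channels[[i]]$z_rate <- z_rate[[i]]
      channels[[i]]$z_mi <- z_mi[[i]]
    }
  }
  cols <- vapply(config$variants, variant_column, "")
  bm <- patient_biomarker_matrix(channels, cols)
  clin <- bundle$clinical
  x0 <- model_design(clin)
  standard <- fit_logistic(x0, clin$success)
  roc0 <- roc_auc(standard$fitted, clin$success)
  loo0 <- loo_predict(x0, clin$success)
  summarize <- function(fit, roc, loo) list(
    auc = roc$auc, loo_auc = loo$auc,
    r2_nagelkerke = fit$r2_nagelkerke, model_p = fit$model_p,
    separation = fit$separation,
    or = as.list(fit$or), ci_lo = as.list(fit$ci_lo),
    ci_hi = as.list(fit$ci_hi))
  models <- list()
  for (j in seq_along(config$variants)) {
    v <- config$variants[j]
    b <- bm[, cols[j]]
    ok <- !is.na(b)
    if (sum(ok) < 20 || length(unique(clin$success[ok])) < 2) {
      models[[v]] <- list(auc = NA_real_, loo_auc = NA_real_,
                          note = "variant undefined (NA biomarker)")
      next
    }
    xv <- model_design(clin[ok, ], biomarker = b[ok])
    fit <- fit_logistic(xv, clin$success[ok])
    roc <- roc_auc(fit$fitted, clin$success[ok])
    loo <- loo_predict(xv, clin$success[ok])
    models[[v]] <- summarize(fit, roc, loo)
    models[[v]]$n_used <- sum(ok)
  }
  report <- list(config_hash = config_hash(config),
                 seed = config$cohort$seed,
                 n_patients = config$cohort$n_patients,
                 warnings = c(bundle$warnings, attr(bm, "na_log")),
                 standard = summarize(standard, roc0, loo0),
                 models = models)
  attr(report, "bundle") <- bundle
  class(report) <- "run_report"
  report
}

#' Serialize a run report to canonical JSON
#' @param report a `run_report`.
#' @return a JSON string (byte-stable across reruns with one seed).
#' @export
report_json <- function(report) {
  r <- unclass(report)
  attr(r, "bundle") <- NULL
  as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = 10,
                                na = "null"))
}

#' Classification-accuracy stability over the atlas neighbour count
#'
#' Recomputes the z-normalized biomarker models for each neighbour count
#' k and reports the in-sample AUC, mirroring the stability analysis of
#' the k choice (stable for k >= 60; degraded for very small k).
#'
#' @param config a [pipeline_config()] (z variants are forced on).
#' @param k_range neighbour counts to sweep (default 10-100 by 10).
#' @return data.frame with columns `k`, `auc_zrate`, `auc_zmi`.
#' @export
k_sweep_analysis <- function(config, k_range = seq(10, 100, by = 10)) {
  stopifnot(inherits(config, "run_config"))
  bundle <- simulate_cohort(config$cohort)
  channels <- bundle$channels
  clin <- bundle$clinical
  n_sites <- sum(vapply(channels, function(ch)
    sum(ch$non_epileptic & !ch$artifact), 0L))
  out <- data.frame(k = k_range, auc_zrate = NA_real_, auc_zmi = NA_real_)
  knn <- cohort_knn(channels, min(max(k_range), n_sites - 1L))
  for (r in seq_along(k_range)) {
    k <- k_range[r]
    if (k > n_sites - 1) {
      warning("k = ", k, " exceeds available non-epileptic sites; skipped")
      next
    }
    for (vc in c("rate", "mi")) {
      z <- cohort_zscores(channels, vc, k, config$outlier_sd, knn = knn)
      tabs <- channels
      for (i in seq_along(tabs)) tabs[[i]]$zv <- z[[i]]
      bm <- patient_biomarker_matrix(tabs, "zv")
      b <- bm[, 1]
      ok <- !is.na(b)
      col <- paste0("auc_z", vc)
      if (sum(ok) < 20 || length(unique(clin$success[ok])) < 2) next
      fit <- fit_logistic(model_design(clin[ok, ], biomarker = b[ok]),
                          clin$success[ok])
      out[[col]][r] <- roc_auc(fit$fitted, clin$success[ok])$auc
    }
  }
  out
}
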