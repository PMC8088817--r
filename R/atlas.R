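#' Build a normative atlas from non-epileptic sites
#'
#' Stores the coordinates and biomarker values of non-epileptic electrode
#' sites (outside the seizure-onset zone, cortical lesions and spiking
#' zones).  A query takes the `k` closest sites (default 60, Euclidean
#' distance in template mm), applies a one-sided outlier exclusion
#' (values greater than `outlier_sd` SDs above the neighbour mean are
#' dropped, single pass), and returns the recomputed mean and sample SD.
#'
#' @param coords numeric matrix (n x 3) of site coordinates (mm).
#' @param values numeric vector of biomarker values at the sites.
#' @param k neighbour count (>= 2, default 60).
#' @param outlier_sd one-sided exclusion threshold in SDs (default 10).
#' @return a `normative_atlas` object.
#' @export
build_atlas <- function(coords, values, k = 60, outlier_sd = 10) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, length(values) == nrow(coords))
  if (k < 2) stop("k must be >= 2")
  if (!all(is.finite(values))) stop("atlas values must be finite")
  if (nrow(coords) < k)
    stop("atlas needs at least k = ", k, " non-epileptic sites; got ",
         nrow(coords))
  structure(list(coords = coords, values = as.numeric(values),
                 k = as.integer(k), outlier_sd = outlier_sd,
                 metric = "euclidean_mm"),
            class = "normative_atlas")
}

#' Query the normative atlas at a coordinate
#'
#' @param atlas a [build_atlas()] result.
#' @param coord length-3 coordinate (mm).
#' @param exclude_site optional site index (into the atlas) to leave out,
#'   used for leave-self-out z-scoring of sites that are themselves in
#'   the atlas.
#' @return list `mu`, `sigma` (sample SD; 0 when all neighbour values are
#'   identical -- downstream z becomes NA), `n_used` (after outlier
#'   exclusion).
#' @export
query_atlas <- function(atlas, coord, exclude_site = NULL) {
  stopifnot(inherits(atlas, "normative_atlas"), length(coord) == 3)
  d <- sqrt(colSums((t(atlas$coords) - as.numeric(coord))^2))
  idx <- seq_along(d)
  if (!is.null(exclude_site)) {
    d <- d[-exclude_site]; idx <- idx[-exclude_site]
  }
  if (length(idx) < atlas$k)
    stop("atlas query needs ", atlas$k, " sites; only ", length(idx),
         " available")
  # deterministic tie-break: order by (distance, site index)
  sel <- idx[order(d, idx)][seq_len(atlas$k)]
  v <- atlas$values[sel]
  mu <- mean(v); sigma <- stats::sd(v)
  if (is.finite(sigma) && sigma > 0) {
    keep <- v <= mu + atlas$outlier_sd * sigma    # one-sided, single pass
    if (!all(keep)) {
      v <- v[keep]
      mu <- mean(v)
      sigma <- if (length(v) > 1) stats::sd(v) else 0
    }
  } else sigma <- 0
  list(mu = mu, sigma = sigma, n_used = length(v))
}

#' Z-score a biomarker value against a normative mean/SD
#'
#' @param x observed value.
#' @param mu,sigma normative mean and SD.
#' @return list `z` (NA when `sigma` is 0 -- e.g. no events detected in
#'   non-epileptic cortex for that detector/band), `mu`, `sigma`.
#' @export
zscore_value <- function(x, mu, sigma) {
  z <- if (is.na(sigma) || sigma <= 0) NA_real_ else (x - mu) / sigma
  list(z = z, mu = mu, sigma = sigma)
}

#' Z-score one channel set against an atlas
#'
#' Convenience wrapper: z-scores `values` at `coords` against `atlas`,
#' with leave-self-out handling for channels that are atlas sites.
#'
#' @param atlas a [build_atlas()] result.
#' @param coords n x 3 matrix of query coordinates.
#' @param values length-n vector of observed biomarker values.
#' @param self_index optional length-n integer vector: for rows that are
#'   themselves atlas sites, the atlas site index (NA otherwise).
#' @return data.frame with `z`, `mu`, `sigma`, `n_used`.
#' @export
zscore_channels <- function(atlas, coords, values, self_index = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(values) == n)
  out <- data.frame(z = numeric(n), mu = numeric(n), sigma = numeric(n),
                    n_used = integer(n))
  for (i in seq_len(n)) {
    ex <- if (!is.null(self_index) && !is.na(self_index[i])) self_index[i] else NULL
    q <- query_atlas(atlas, coords[i, ], exclude_site = ex)
    zs <- zscore_value(values[i], q$mu, q$sigma)
    out$z[i] <- zs$z; out$mu[i] <- q$mu; out$sigma[i] <- q$sigma
    out$n_used[i] <- q$n_used
  }
  out
}

#' Z tables over a sweep of neighbour counts
#'
#' Recomputes [zscore_channels()] for each k in `k_sweep` (the stability
#' analysis of the neighbour-count choice; 10-100 by default).
#'
#' @inheritParams zscore_channels
#' @param k_sweep integer vector of neighbour counts.
#' @return named list of per-k data.frames (names `"k<k>"`).
#' @export
zscore_cohort <- function(atlas, coords, values, self_index = NULL,
                          k_sweep = seq(10, 100, by = 10)) {
  out <- list()
  for (k in k_sweep) {
    a <- atlas; a$k <- as.integer(k)
    if (nrow(a$coords) < k + 1) {
      warning("k = ", k, " exceeds available sites; skipped")
      next
    }
    out[[paste0("k", k)]] <- zscore_channels(a, coords, values, self_index)
  }
  out
}
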