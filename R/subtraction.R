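#' Subtraction completeness-of-resection statistic
#'
#' The biomarker value averaged across all resected sites minus its
#' average across all preserved sites, computed over non-artifact
#' channels.  Higher values indicate more complete resection of the
#' region showing a focal biomarker increase.
#'
#' @param values per-channel biomarker values (rate per 5 min, z units,
#'   or MI uV).
#' @param resected logical vector, same length.
#' @param artifact logical vector; artifact channels are excluded
#'   entirely (default none).
#' @return list `value` (NA with `reason` when any contributing value is
#'   NA, e.g. undefined z), `n_resected`, `n_preserved`.
#' @export
subtraction_biomarker <- function(values, resected,
                                  artifact = rep(FALSE, length(values))) {
  stopifnot(length(resected) == length(values),
            length(artifact) == length(values))
  keep <- !artifact
  v <- values[keep]; r <- resected[keep]
  if (!any(r)) stop("no resected channels: Subtraction undefined")
  if (!any(!r)) stop("no preserved channels: Subtraction undefined")
  out <- list(value = NA_real_, n_resected = sum(r), n_preserved = sum(!r),
              reason = NULL)
  if (anyNA(v)) {
    out$reason <- "NA biomarker values (undefined z-normalization)"
    return(out)
  }
  out$value <- mean(v[r]) - mean(v[!r])
  out
}

#' Patient-by-variant biomarker matrix
#'
#' Assembles the Subtraction statistic for every patient and every
#' requested biomarker variant into the design-ready matrix consumed by
#' the outcome models.  Missing or undefined variants propagate as NA
#' (the affected patient is dropped listwise from that one model's fit).
#'
#' @param tables named list (one entry per patient) of channel tables;
#'   each must have columns `resected`, `artifact` and one column per
#'   variant name.
#' @param variants character vector of variant column names.
#' @return numeric matrix, patients x variants, with an `na_log`
#'   attribute listing patient/variant pairs that could not be computed.
#' @export
patient_biomarker_matrix <- function(tables, variants) {
  pts <- names(tables)
  m <- matrix(NA_real_, nrow = length(tables), ncol = length(variants),
              dimnames = list(pts, variants))
  na_log <- character()
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    art <- if ("artifact" %in% names(tab)) tab$artifact else rep(FALSE, nrow(tab))
    for (v in variants) {
      if (!v %in% names(tab)) {
        na_log <- c(na_log, paste0(pts[i], "/", v, ": variant missing"))
        next
      }
      s <- subtraction_biomarker(tab[[v]], tab$resected, art)
      if (is.na(s$value))
        na_log <- c(na_log, paste0(pts[i], "/", v, ": ", s$reason))
      m[i, v] <- s$value
    }
  }
  attr(m, "na_log") <- na_log
  m
}
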