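#' In-memory multichannel iEEG epoch
#'
#' @param samples channels x time numeric matrix (uV).
#' @param fs sampling rate in Hz.
#' @param channel_ids character vector of channel labels (row order).
#' @param reference `"as_recorded"` or `"common_average"`.
#' @return an `ieeg_epoch` object.
#' @export
ieeg_epoch <- function(samples, fs, channel_ids = rownames(samples),
                       reference = "as_recorded") {
  samples <- as.matrix(samples)
  if (is.null(channel_ids))
    channel_ids <- sprintf("CH%03d", seq_len(nrow(samples)))
  stopifnot(fs > 0, length(channel_ids) == nrow(samples),
            reference %in% c("as_recorded", "common_average"))
  rownames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs,
                 channel_ids = as.character(channel_ids),
                 reference = reference,
                 epoch_duration_s = ncol(samples) / fs),
            class = "ieeg_epoch")
}

#' @export
print.ieeg_epoch <- function(x, ...) {
  cat("<ieeg_epoch> ", nrow(x$samples), " channels x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz (",
      signif(x$epoch_duration_s, 4), " s), reference: ",
      x$reference, "\n", sep = "")
  invisible(x)
}

# ---- minimal EDF codec -----------------------------------------------------
# Standard 256-byte header + 256 bytes per signal, 16-bit little-endian
# samples.  Records are 1 s long when the epoch length is an integer number
# of seconds, otherwise a single record holds the whole epoch.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)                # left-justified, space padded
}

#' Write an epoch to an EDF file
#'
#' 16-bit encoding with per-channel physical scaling chosen to cover the
#' observed range; physical dimension recorded as uV.
#'
#' @param epoch an [ieeg_epoch()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(epoch, path) {
  stopifnot(inherits(epoch, "ieeg_epoch"))
  ns <- nrow(epoch$samples); n <- ncol(epoch$samples)
  fs <- epoch$fs
  if (n %% fs == 0 && fs == round(fs)) {
    n_rec <- n %/% fs; spr <- as.integer(fs); rec_dur <- 1
  } else {
    n_rec <- 1L; spr <- n; rec_dur <- n / fs
  }
  pmin_ <- apply(epoch$samples, 1, min)
  pmax_ <- apply(epoch$samples, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256L * (1L + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(format(rec_dur, trim = TRUE), 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(epoch$channel_ids, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(signif(pmin_, 7), pad_field, "", width = 8), collapse = ""),
    paste(vapply(signif(pmax_, 7), pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(spr, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)

  # digital conversion: d = round((p - pmin) / (pmax - pmin) * (dmax - dmin)) + dmin
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      d <- as.integer(round((epoch$samples[ch, idx] - pmin_[ch]) * scale[ch]) + dmin)
      writeBin(d, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_header_field <- function(raw, at, width) {
  trimws(rawToChar(raw[(at + 1):(at + width)]))
}

#' Read an EDF epoch
#'
#' Parses the header, decodes all signals to physical units (uV), and
#' checks the sampling rate against `expected_fs` -- the analysis assumes
#' a fixed rate, so a mismatch is a hard error.
#'
#' @param path EDF file.
#' @param expected_fs required sampling rate in Hz (default 1000).
#' @return an [ieeg_epoch()] with `reference = "as_recorded"`.
#' @export
read_epoch <- function(path, expected_fs = 1000) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  sz <- file.info(path)$size
  raw <- readBin(path, "raw", n = sz)
  if (length(raw) < 256) stop("not an EDF file (truncated header): ", path)
  n_rec <- as.integer(read_header_field(raw, 236, 8))
  rec_dur <- as.numeric(read_header_field(raw, 244, 8))
  ns <- as.integer(read_header_field(raw, 252, 4))
  off <- 256
  fld <- function(i, width, base) read_header_field(raw, base + (i - 1) * width, width)
  labels <- vapply(seq_len(ns), fld, "", width = 16, base = off)
  base <- off + ns * (16 + 80 + 8)
  pmin_ <- as.numeric(vapply(seq_len(ns), fld, "", width = 8, base = base))
  pmax_ <- as.numeric(vapply(seq_len(ns), fld, "", width = 8, base = base + ns * 8))
  dmin <- as.numeric(vapply(seq_len(ns), fld, "", width = 8, base = base + ns * 16))
  dmax <- as.numeric(vapply(seq_len(ns), fld, "", width = 8, base = base + ns * 24))
  spr <- as.integer(vapply(seq_len(ns), fld, "", width = 8, base = base + ns * (24 + 8 + 80)))
  if (length(unique(spr)) != 1)
    stop("EDF with per-signal sampling rates is not supported")
  fs <- spr[1] / rec_dur
  if (!isTRUE(all.equal(fs, expected_fs)))
    stop("sampling rate mismatch: file has ", fs, " Hz, expected ", expected_fs)
  data_off <- 256L + 256L * ns
  n_samp_tot <- n_rec * sum(spr)
  d <- readBin(raw[(data_off + 1):sz], "integer", n = n_samp_tot,
               size = 2, endian = "little", signed = TRUE)
  n <- n_rec * spr[1]
  samples <- matrix(0, nrow = ns, ncol = n)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
      samples[ch, idx] <- (d[(pos + 1L):(pos + spr[ch])] - dmin[ch]) * gain[ch] + pmin_[ch]
      pos <- pos + spr[ch]
    }
  }
  ieeg_epoch(samples, fs, channel_ids = labels, reference = "as_recorded")
}

# ---- referencing -----------------------------------------------------------

#' Re-reference an epoch to the common average
#'
#' Subtracts, at every sample, the mean over included channels from each
#' included channel.  Channels in `exclude` (typically artifact channels)
#' do not contribute to the average and are left untouched; excluding
#' artifacts before referencing prevents artifact leakage into every
#' channel.  Idempotent: the mean over included channels is zero
#' afterwards.
#'
#' @param epoch an [ieeg_epoch()].
#' @param exclude character vector of channel ids to leave out.
#' @return re-referenced `ieeg_epoch` with `reference = "common_average"`.
#' @export
apply_common_average <- function(epoch, exclude = character()) {
  stopifnot(inherits(epoch, "ieeg_epoch"))
  keep <- !(epoch$channel_ids %in% exclude)
  if (sum(keep) < 2) stop("common average needs >= 2 non-excluded channels")
  avg <- colMeans(epoch$samples[keep, , drop = FALSE])
  epoch$samples[keep, ] <- sweep(epoch$samples[keep, , drop = FALSE], 2, avg)
  epoch$reference <- "common_average"
  epoch
}

# ---- metadata tables -------------------------------------------------------

#' Read a channel-metadata table
#'
#' TSV with columns `channel, x_mm, y_mm, z_mm, artifact, soz, lesion,
#' spiking, resected` (flags 0/1).  Adds the derived `non_epileptic`
#' column: a site outside the seizure-onset zone, cortical lesions and
#' spiking zones.
#'
#' @param path TSV file path.
#' @return data.frame, one row per channel.
#' @export
read_channel_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_channel_table(tab)
}

#' Validate (and complete) a channel-metadata data.frame
#' @param tab data.frame with the columns of [read_channel_table()].
#' @return the validated data.frame with `non_epileptic` added.
#' @export
validate_channel_table <- function(tab) {
  req <- c("channel", "x_mm", "y_mm", "z_mm", "artifact", "soz",
           "lesion", "spiking", "resected")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("channel table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$channel))
    stop("duplicate channel labels in channel table")
  for (f in c("artifact", "soz", "lesion", "spiking", "resected"))
    tab[[f]] <- as.logical(tab[[f]])
  tab$non_epileptic <- !(tab$soz | tab$lesion | tab$spiking)
  tab
}

#' Read a patient-level clinical table
#'
#' CSV with one row per patient and the ten outcome-model covariates plus
#' the ILAE outcome class: `age, sex, daily_seizures, n_aeds,
#' left_hemisphere, mri_lesion, habitual_sz_captured, soz_fully_resected,
#' extratemporal_resection, resection_size_pct, ilae_class` (an optional
#' `patient` id column is preserved).  `success` is derived as ILAE
#' class 1.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_clinical_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical_table(tab)
}

#' Validate a clinical data.frame
#' @param tab data.frame with the columns of [read_clinical_table()].
#' @return the validated data.frame with `success` added.
#' @export
validate_clinical_table <- function(tab) {
  req <- c("age", "sex", "daily_seizures", "n_aeds", "left_hemisphere",
           "mri_lesion", "habitual_sz_captured", "soz_fully_resected",
           "extratemporal_resection", "resection_size_pct", "ilae_class")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(tab$ilae_class %in% 1:6))
    stop("ilae_class outside the 1-6 outcome scale")
  if (any(tab$resection_size_pct <= 0 | tab$resection_size_pct > 100))
    stop("resection_size_pct must lie in (0, 100]")
  tab$success <- tab$ilae_class == 1
  tab
}
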