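#' Write an EEG recording to disk
#'
#' Two container formats:
#' \describe{
#'   \item{`array_json`}{a flat little-endian float64 binary (`<base>.dat`,
#'     channel-major) plus a JSON sidecar (`<base>.json`) with labels, rate
#'     and metadata; round-trips bit-identically.}
#'   \item{`edf`}{European Data Format: 16-bit integers with per-channel
#'     physical scaling in 1-s data records; round-trips up to the 16-bit
#'     quantization step.}
#' }
#'
#' @param recording An `eeg_recording`.
#' @param path Output path; for `array_json` the base path (extensions are
#'   appended), for `edf` the `.edf` file path.
#' @param format `"array_json"` (default) or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(recording, path, format = c("array_json", "edf")) {
  format <- match.arg(format)
  if (any(!is.finite(recording$data))) stopf("refusing to write non-finite data")
  if (format == "array_json") {
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(recording$data)), con, size = 8, endian = "little")
    meta <- list(
      n_channels = nrow(recording$data),
      n_samples = ncol(recording$data),
      sample_rate = recording$sample_rate,
      channel_labels = recording$channel_labels,
      patient_id = recording$patient_id,
      group = recording$group,
      subject_id = if (is.null(recording$subject_id)) NA else
        recording$subject_id
    )
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_edf(recording, path)
  }
  invisible(path)
}

#' Read an EEG recording from disk
#'
#' Counterpart of [write_eeg()]. For `array_json`, `path` is the base path
#' without extension; patient/group metadata come from the JSON sidecar.
#' Channel order is canonicalized to the standard 27-label montage when the
#' label set matches it; otherwise file order is preserved.
#'
#' @param path Base path (`array_json`) or `.edf` file path.
#' @param format `"array_json"` (default) or `"edf"`.
#' @return An `eeg_recording`.
#' @export
read_eeg <- function(path, format = c("array_json", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  json_path <- paste0(path, ".json")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(json_path) || !file.exists(dat_path))
    stopf("missing container files for '%s'", path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if (is.null(meta$channel_labels)) stopf("sidecar lacks channel labels")
  n <- meta$n_channels * meta$n_samples
  con <- file(dat_path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, numeric(), n = n + 1, size = 8, endian = "little")
  if (length(raw_vals) != n)
    stopf("truncated or oversized data file '%s' (expected %d values, got %d)",
          dat_path, n, length(raw_vals))
  data <- matrix(raw_vals, nrow = meta$n_channels, byrow = TRUE)
  rec <- structure(list(
    data = data, sample_rate = as.numeric(meta$sample_rate),
    channel_labels = meta$channel_labels,
    patient_id = meta$patient_id, group = meta$group,
    subject_id = meta$subject_id
  ), class = "eeg_recording")
  canonicalize_channels(rec)
}

canonicalize_channels <- function(rec) {
  if (setequal(rec$channel_labels, EEG_CHANNELS_27) &&
      length(rec$channel_labels) == 27) {
    ord <- match(EEG_CHANNELS_27, rec$channel_labels)
    rec$data <- rec$data[ord, , drop = FALSE]
    rec$channel_labels <- EEG_CHANNELS_27
  }
  rec
}

# ---- EDF (European Data Format) ------------------------------------------
# Fixed-layout header (256 bytes + 256 per signal), 1-s data records of
# 16-bit little-endian integers with per-signal physical scaling.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

write_edf <- function(recording, path) {
  fs <- recording$sample_rate
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer needs an integer rate")
  fs <- as.integer(round(fs))
  n_ch <- nrow(recording$data)
  n_rec <- ncol(recording$data) %/% fs
  if (n_rec * fs != ncol(recording$data))
    stopf("EDF writer needs a whole number of 1-s records")
  data <- recording$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste("X X X", recording$patient_id), 80),
    edf_pad(paste("Startdate X X X X grp", recording$group), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + n_ch), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(n_ch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(recording$channel_labels, edf_pad, "", width = 16),
    rep(edf_pad("AgAgCl electrode", 80), n_ch),
    rep(edf_pad("uV", 8), n_ch),
    vapply(sprintf("%.8g", pmin_), edf_pad, "", width = 8),
    vapply(sprintf("%.8g", pmax_), edf_pad, "", width = 8),
    rep(edf_pad(dmin, 8), n_ch),
    rep(edf_pad(dmax, 8), n_ch),
    rep(edf_pad("", 80), n_ch),
    rep(edf_pad(fs, 8), n_ch),
    rep(edf_pad("", 32), n_ch)
  )
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(n_ch)) {
      dig <- round((data[ch, idx] - pmin_[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8) # version
  patient <- trimws(rd(80))
  rec_field <- trimws(rd(80))
  rd(8); rd(8) # date, time
  rd(8) # header bytes
  rd(44) # reserved
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  n_ch <- as.integer(trimws(rd(4)))
  if (is.na(n_ch) || n_ch < 2) stopf("malformed EDF header in %s", path)
  labels <- trimws(vapply(seq_len(n_ch), function(i) rd(16), ""))
  vapply(seq_len(n_ch), function(i) rd(80), "") # transducer
  vapply(seq_len(n_ch), function(i) rd(8), "")  # unit
  pmin_ <- as.numeric(trimws(vapply(seq_len(n_ch), function(i) rd(8), "")))
  pmax_ <- as.numeric(trimws(vapply(seq_len(n_ch), function(i) rd(8), "")))
  dmin <- as.numeric(trimws(vapply(seq_len(n_ch), function(i) rd(8), "")))
  dmax <- as.numeric(trimws(vapply(seq_len(n_ch), function(i) rd(8), "")))
  vapply(seq_len(n_ch), function(i) rd(80), "") # prefiltering
  spr <- as.integer(trimws(vapply(seq_len(n_ch), function(i) rd(8), "")))
  vapply(seq_len(n_ch), function(i) rd(32), "") # reserved
  if (length(unique(spr)) != 1)
    stopf("EDF reader supports a single sampling rate, got %s",
          paste(unique(spr), collapse = "/"))
  fs <- spr[1] / rec_dur
  data <- matrix(0, n_ch, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      dig <- readBin(con, integer(), n = spr[1], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[1]) stopf("truncated EDF data in %s", path)
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  group <- if (grepl("grp (epilepsy|pnes)", rec_field))
    sub(".*grp (epilepsy|pnes).*", "\\1", rec_field) else NA_character_
  pid <- utils::tail(strsplit(patient, " ")[[1]], 1)
  canonicalize_channels(structure(list(
    data = data, sample_rate = fs, channel_labels = labels,
    patient_id = pid, group = group
  ), class = "eeg_recording"))
}

# ---- feature tables ------------------------------------------------------

#' Write a feature table to CSV
#'
#' Refuses to write non-finite feature values; a table with zero rows
#' yields a valid header-only file.
#'
#' @param features A wide feature table (see [check_feature_table()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (nrow(features) > 0) check_feature_table(features)
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(FEATURE_ID_COLS, names(df))
  if (length(missing))
    stopf("feature CSV lacks columns: %s", paste(missing, collapse = ", "))
  df
}

#' Build and write a run manifest
#'
#' Records the full parameter snapshot, seed and package version that
#' produced a pipeline run, so outputs can be traced and reproduced.
#'
#' @param config A [generator_config()] (or arbitrary parameter list).
#' @param seed Integer master seed.
#' @param extra Optional named list of further settings.
#' @param path Optional JSON path to write to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(config, seed, extra = list(), path = NULL) {
  manifest <- list(
    package = "eegmicronet",
    version = as.character(utils::packageVersion("eegmicronet")),
    seed = seed,
    config = unclass(config),
    settings = extra
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}

# ---- analysis artifact writers -------------------------------------------

#' Write / read a microstate model as JSON
#'
#' Serializes the prototype maps (channels x K), the selected K, fit
#' diagnostics (CV, GEV, explained variance), band, channel labels and the
#' CV/GEV selection curve when present.
#'
#' @param model A `microstate_model`.
#' @param path JSON path.
#' @param channel_labels Optional channel labels stored alongside the maps.
#' @return `path`, invisibly.
#' @export
write_microstate_model <- function(model, path, channel_labels = NULL) {
  stopifnot(inherits(model, "microstate_model"))
  payload <- list(
    K = model$K,
    band = model$band,
    maps = unname(apply(model$maps, 2, as.numeric, simplify = FALSE)),
    cv = model$cv,
    gev = model$gev,
    explained_variance = model$explained_variance,
    channel_labels = channel_labels,
    selection = model$selection
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_microstate_model
#' @export
read_microstate_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # simplifyVector turns the list of per-class map vectors into a K x C
  # matrix; fall back to cbind when class lengths prevented simplification
  maps <- if (is.matrix(p$maps)) t(p$maps) else do.call(cbind, p$maps)
  structure(list(maps = maps, K = as.integer(p$K), band = p$band,
                 cv = p$cv, gev = p$gev,
                 explained_variance = p$explained_variance,
                 selection = p$selection),
            class = "microstate_model")
}

#' Write a connectivity matrix as labelled square CSV
#'
#' @param matrix A `connectivity_matrix` (or plain symmetric matrix).
#' @param path CSV path.
#' @param channel_labels Row/column labels; defaults to `Ch<i>`.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(matrix, path, channel_labels = NULL) {
  m <- as.matrix(matrix)
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(m)))
  dimnames(m) <- list(channel_labels, channel_labels)
  write.csv(m, path)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a segmentation as a run-length CSV
#'
#' Columns: `class`, `start_ms`, `duration_ms`.
#'
#' @param seg A `segmentation`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  df <- data.frame(
    class = seg$segments$class,
    start_ms = (seg$segments$start - 1) / seg$sample_rate * 1000,
    duration_ms = seg$segments$duration_ms
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
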