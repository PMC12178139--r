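# EEG containers and on-disk formats (delimited matrix + JSON sidecar, EDF).

ns_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "neurostate_error")))
}

#' Construct an EEG recording
#'
#' Container for a multichannel voltage time series: a channels x samples
#' matrix in microvolts plus sampling metadata. All downstream microstate
#' operations take this object.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one unique name per row of `data`.
#' @param positions optional n_channels x 2 matrix of 2-D layout coordinates.
#' @param subject_id,timepoint optional metadata; `timepoint` must be
#'   `"pre"` or `"post"` when given.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, positions = NULL,
                          subject_id = NA_character_, timepoint = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (!all(is.finite(data)))
    ns_stop("neurostate_error_nonfinite", "EEG data contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    ns_stop("neurostate_error_bad_fs", "sampling rate must be a single value > 0 (got %s)", fs)
  fs <- as.numeric(fs)
  if (length(channel_names) != nrow(data))
    ns_stop("neurostate_error_channel_mismatch",
            "%d channel names for %d data rows", length(channel_names), nrow(data))
  if (anyDuplicated(channel_names))
    ns_stop("neurostate_error_duplicate_channels", "duplicate channel names: %s",
            paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (ncol(data) < 1L)
    ns_stop("neurostate_error_empty", "recording has no samples")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == nrow(data), ncol(positions) == 2L)
  }
  if (!is.na(timepoint) && !timepoint %in% c("pre", "post"))
    ns_stop("neurostate_error_bad_timepoint", "timepoint must be 'pre' or 'post'")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 positions = positions, subject_id = subject_id,
                 timepoint = timepoint),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject %s, timepoint %s\n", x$subject_id, x$timepoint))
  invisible(x)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
}

#' Read an EEG recording from disk
#'
#' Accepts either an EDF file (extension `.edf`, case-insensitive) or a
#' delimited numeric matrix (rows = channels, columns = samples; TSV/CSV
#' autodetected from the first line) accompanied by a JSON sidecar giving at
#' least `fs` and optionally `channel_names`, `positions`, `subject_id`,
#' `timepoint`.
#'
#' @param path path to the EDF or matrix file.
#' @param sidecar_path path to the JSON sidecar; defaults to `path` with its
#'   extension replaced by `.json`. Ignored for EDF input.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, sidecar_path = NULL) {
  if (!file.exists(path))
    ns_stop("neurostate_error_missing_file", "no such file: %s", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(read_edf(path))
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.[^.]+$", "", path), ".json")
  if (!file.exists(sidecar_path))
    ns_stop("neurostate_error_missing_sidecar",
            "matrix EEG input requires a JSON sidecar; not found: %s", sidecar_path)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$fs))
    ns_stop("neurostate_error_missing_fs", "sidecar %s lacks required key 'fs'", sidecar_path)
  delim <- sniff_delim(path)
  # scan() + matrix: read.table degrades badly at this column count
  mat <- tryCatch({
    v <- scan(path, what = double(), sep = delim, quiet = TRUE)
    nr <- length(readLines(path, warn = FALSE))
    matrix(v, nrow = nr, byrow = TRUE)
  }, error = function(e) ns_stop("neurostate_error_nonnumeric",
                                 "non-numeric cells in matrix EEG file %s", path))
  eeg_recording(mat, fs = side$fs,
                channel_names = side$channel_names,
                positions = if (!is.null(side$positions)) matrix(unlist(side$positions), ncol = 2),
                subject_id = side$subject_id %||% NA_character_,
                timepoint = side$timepoint %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an EEG recording as a delimited matrix plus JSON sidecar
#'
#' @param rec an [eeg_recording()].
#' @param path output path for the tab-delimited channels x samples matrix.
#' @param sidecar_path output path for the JSON sidecar (default: `path` with
#'   extension replaced by `.json`).
#' @return `path`, invisibly.
#' @export
write_eeg_matrix <- function(rec, path, sidecar_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.[^.]+$", "", path), ".json")
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- list(fs = rec$fs, channel_names = rec$channel_names)
  if (!is.null(rec$positions)) side$positions <- rec$positions
  if (!is.na(rec$subject_id)) side$subject_id <- rec$subject_id
  if (!is.na(rec$timepoint)) side$timepoint <- rec$timepoint
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- EDF (European Data Format, 16-bit) ------------------------------------

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

# format a physical limit into <= 8 ASCII chars whose parsed value still
# brackets v from the required side (dir = -1 for minima, +1 for maxima)
edf_phys_field <- function(v, dir) {
  for (digits in 7:1) {
    cand <- v
    for (i in 1:20) {
      s <- formatC(cand, digits = digits, format = "g")
      if (nchar(s) <= 8 && ((dir < 0 && as.numeric(s) <= v) ||
                            (dir > 0 && as.numeric(s) >= v)))
        return(s)
      cand <- cand + dir * (abs(cand) * 1e-4 + 1e-12)
    }
  }
  ns_stop("neurostate_error_edf_range", "cannot encode physical limit %g", v)
}

#' Write an EEG recording as EDF
#'
#' Standard 16-bit European Data Format. Each channel is scaled linearly from
#' its physical range to the digital range -32768..32767; the quantization
#' step is `(phys_max - phys_min) / 65535` per channel. When the sample count
#' is a whole number of seconds at an integer sampling rate, 1-second data
#' records are used; otherwise the file holds a single record.
#'
#' @param rec an [eeg_recording()].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  nc <- nrow(x); ns <- ncol(x); fs <- rec$fs
  if (abs(fs - round(fs)) < 1e-9 && ns %% round(fs) == 0) {
    n_rec <- ns %/% round(fs); rec_dur <- 1; spr <- round(fs)
  } else {
    n_rec <- 1L; rec_dur <- ns / fs; spr <- ns
  }
  pmin_s <- pmax_s <- character(nc)
  dig <- matrix(0L, nc, ns)
  for (i in seq_len(nc)) {
    rng <- range(x[i, ])
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    pmin_s[i] <- edf_phys_field(rng[1], -1)
    pmax_s[i] <- edf_phys_field(rng[2], +1)
    pmin <- as.numeric(pmin_s[i]); pmax <- as.numeric(pmax_s[i])
    d <- round((x[i, ] - pmin) / (pmax - pmin) * 65535 - 32768)
    dig[i, ] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256L + 256L * nc
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(if (is.na(rec$subject_id)) "X" else rec$subject_id, 80),
    edf_field("neurostate export", 80),
    edf_field("01.01.20", 8), edf_field("00.00.00", 8),
    edf_field(hdr_bytes, 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(format(rec_dur, digits = 7), 8),
    edf_field(nc, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste(vapply(vals, edf_field, "", width = w),
                                           collapse = ""), con, eos = NULL)
  fld(rec$channel_names, 16)
  fld(rep("", nc), 80)
  fld(rep("uV", nc), 8)
  fld(pmin_s, 8)
  fld(pmax_s, 8)
  fld(rep("-32768", nc), 8)
  fld(rep("32767", nc), 8)
  fld(rep("", nc), 80)
  fld(rep(spr, nc), 8)
  fld(rep("", nc), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nc))
      writeBin(dig[i, idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); subj <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)          # transducer
  for (i in seq_len(nc)) rd(8)           # phys dim
  pmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1L)
    ns_stop("neurostate_error_edf_mixed_rates",
            "EDF files with per-signal sampling rates are not supported")
  spr <- spr[1]
  out <- matrix(0, nc, n_rec * spr)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nc)) {
      d <- readBin(con, integer(), n = spr, size = 2L, endian = "little")
      out[i, idx] <- (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    }
  }
  eeg_recording(out, fs = spr / rec_dur, channel_names = labels,
                subject_id = if (nzchar(subj)) subj else NA_character_)
}
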