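#' Construct a continuous multichannel EEG recording
#'
#' An `eeg_recording` holds a channels-by-samples signal matrix (microvolts),
#' its sampling rate and channel names, plus optional subject and stage-label
#' metadata. The stage label uses the study convention `0` = DROWS (drowsy),
#' `1` = TAV3 (most awake), `2` = TAVX (neutral).
#'
#' @param signal numeric matrix, `n_channels x n_samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector of length `n_channels`; defaults to
#'   `ch1..chN`.
#' @param subject_id subject identifier string.
#' @param stage_label integer class id in `{0, 1, 2}`, or `NA` if unlabeled.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 512), 2), fs = 256)
#' rec
#' @export
eeg_recording <- function(signal, fs, channel_names = NULL,
                          subject_id = "s1", stage_label = NA_integer_) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (nrow(signal) < 2L)
    stop("a recording needs at least 2 channels, got ", nrow(signal))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive scalar sampling rate in Hz")
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(signal))
    stop(sprintf("non-finite value in signal at channel %d, sample %d",
                 ij[1L], ij[2L]))
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop("'channel_names' length (", length(channel_names),
         ") != number of channels (", nrow(signal), ")")
  if (!is.na(stage_label) && !stage_label %in% 0:2)
    stop("'stage_label' must be 0 (DROWS), 1 (TAV3), 2 (TAVX) or NA")
  structure(list(signal = signal, fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 subject_id = as.character(subject_id),
                 stage_label = as.integer(stage_label)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  subject:", x$subject_id, " stage:",
      if (is.na(x$stage_label)) "unlabeled" else
        paste0(x$stage_label, " (", stage_name(x$stage_label), ")"), "\n")
  invisible(x)
}

#' The 15-channel montage used for driver mental-state recordings
#'
#' @return Character vector of the 15 electrode names.
#' @export
standard_montage_15 <- function() {
  c("Fz", "Pz", "Oz", "Fp1", "Fp2", "F7", "F3", "F4", "F8",
    "C3", "C4", "P7", "P3", "P4", "P8")
}

stage_name <- function(label) {
  c("0" = "DROWS", "1" = "TAV3", "2" = "TAVX")[as.character(label)]
}

#' Read a continuous recording from disk
#'
#' Two formats are supported. `matrix_csv` is a plain-text matrix: one
#' comma-separated row per channel, preceded by a single header line
#' `# fs=<Hz>, channels=<comma-separated names>`. `edf` reads a standard
#' European Data Format file (16-bit integer records scaled to physical
#' units); all signals must share one sampling rate.
#'
#' @param path file path.
#' @param format `"matrix_csv"` (default) or `"edf"`.
#' @param subject_id,stage_label metadata attached to the result (the file
#'   formats carry neither).
#' @return An [eeg_recording()].
#' @seealso [write_matrix_csv()]
#' @export
load_recording <- function(path, format = c("matrix_csv", "edf"),
                           subject_id = "s1", stage_label = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- switch(format,
                   matrix_csv = read_matrix_csv(path),
                   edf = read_edf(path))
  eeg_recording(parsed$signal, parsed$fs, parsed$channel_names,
                subject_id = subject_id, stage_label = stage_label)
}

read_matrix_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1L], "#"))
    stop("matrix_csv format error: missing '# fs=..., channels=...' header")
  hdr <- sub("^#\\s*", "", lines[1L])
  fs_m <- regmatches(hdr, regexec("fs\\s*=\\s*([0-9.eE+-]+)", hdr))[[1L]]
  if (length(fs_m) < 2L)
    stop("matrix_csv format error: sampling rate 'fs=' missing from header")
  fs <- as.numeric(fs_m[2L])
  ch_m <- regmatches(hdr, regexec("channels\\s*=\\s*([^;]*)$", hdr))[[1L]]
  channel_names <- if (length(ch_m) >= 2L)
    trimws(strsplit(ch_m[2L], ",")[[1L]]) else NULL
  body <- lines[-1L]
  rows <- lapply(strsplit(body, ","), function(r) as.numeric(trimws(r)))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("matrix_csv format error: ragged rows (row ",
         which(lens != lens[1L])[1L], " has ", lens[lens != lens[1L]][1L],
         " values, expected ", lens[1L], ")")
  signal <- do.call(rbind, rows)
  if (!is.null(channel_names) && length(channel_names) != nrow(signal))
    stop("matrix_csv format error: header lists ", length(channel_names),
         " channels but file has ", nrow(signal), " rows")
  list(signal = signal, fs = fs, channel_names = channel_names)
}

#' Write a recording (or plain matrix) in matrix_csv format
#'
#' @param x an [eeg_recording()] or a numeric matrix.
#' @param path output file path.
#' @param fs,channel_names required when `x` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, fs = NULL, channel_names = NULL) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs; channel_names <- x$channel_names; x <- x$signal
  }
  if (is.null(fs)) stop("'fs' required when writing a bare matrix")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(x)))
  hdr <- sprintf("# fs=%s, channels=%s", format(fs, digits = 15),
                 paste(channel_names, collapse = ","))
  body <- apply(x, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Minimal EDF reader: fixed-layout ASCII header, per-signal subheaders, then
# data records of 2-byte little-endian integers mapped to physical units.
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  afield <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  afield(8L)                         # version
  afield(80L); afield(80L)           # patient / recording id
  afield(8L); afield(8L)             # start date / time
  afield(8L)                         # header length (recomputed below)
  afield(44L)                        # reserved
  n_records <- as.integer(afield(8L))
  rec_dur <- as.numeric(afield(8L))
  ns <- as.integer(afield(4L))
  if (is.na(ns) || ns < 1L) stop("EDF format error: bad signal count")
  labels <- vapply(seq_len(ns), function(i) afield(16L), "")
  for (i in seq_len(ns)) afield(80L)                       # transducer
  for (i in seq_len(ns)) afield(8L)                        # physical dim
  pmin <- vapply(seq_len(ns), function(i) as.numeric(afield(8L)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(afield(8L)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(afield(8L)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(afield(8L)), 0)
  for (i in seq_len(ns)) afield(80L)                       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(afield(8L)), 0L)
  for (i in seq_len(ns)) afield(32L)                       # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF: signals with differing sampling rates are not supported")
  if (rec_dur <= 0) stop("EDF format error: non-positive record duration")
  fs <- spr[1L] / rec_dur
  sig <- matrix(0, ns, n_records * spr[1L])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L,
                   signed = TRUE, endian = "little")
      if (length(d) < spr[i]) stop("EDF format error: truncated data record")
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
    }
  }
  list(signal = sig, fs = fs, channel_names = labels)
}
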