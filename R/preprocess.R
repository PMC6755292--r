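#' Band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass channel-wise, forward and
#' backward (zero phase), so that the phase structure feeding the spatial
#' covariance estimates downstream is undistorted. The DC component is
#' removed by the filter's stop band.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges in Hz; require
#'   `0 < low_hz < high_hz < fs/2`. Defaults 1 and 40 Hz, the conventional
#'   EEG analysis band.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return A filtered [eeg_recording()] of the same shape.
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 40, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("need 0 < low_hz < high_hz")
  if (high_hz >= nyq)
    stop(sprintf("high_hz (%g) must be below the Nyquist frequency (%g Hz)",
                 high_hz, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # demean, then filter with odd-reflection padding so the forward-backward
  # pass carries no edge transients into the retained samples
  n <- ncol(rec$signal)
  pad <- min(n - 1L, ceiling(3 * rec$fs / low_hz))
  filtered <- t(apply(rec$signal, 1L, function(x) {
    x <- x - mean(x)
    xp <- c(2 * x[1L] - rev(x[seq_len(pad) + 1L]), x,
            2 * x[n] - rev(x[n - seq_len(pad)]))
    signal::filtfilt(bf, xp)[pad + seq_len(n)]
  }))
  eeg_recording(filtered, rec$fs, rec$channel_names,
                subject_id = rec$subject_id, stage_label = rec$stage_label)
}

#' Epoch collection
#'
#' An `eeg_epochs` object stores epochs as a 3-D array
#' `n_channels x n_window_samples x n_epochs` with per-epoch class labels and
#' subject ids. With the defaults of this package (256 Hz, 0.5 s windows,
#' 15 channels) each epoch slice is the 15 x 128 trial matrix used throughout.
#'
#' @param data 3-D numeric array `channels x samples x epochs`.
#' @param labels integer vector of per-epoch class ids in `{0, 1, 2}`.
#' @param subject_ids character vector of per-epoch subject ids (recycled if
#'   scalar).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, subject_ids, fs, channel_names = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n_ep <- dim(data)[3L]
  labels <- as.integer(labels)
  if (length(labels) != n_ep)
    stop("labels length != number of epochs")
  if (any(!labels %in% 0:2))
    stop("labels must be drawn from {0, 1, 2}")
  if (length(subject_ids) == 1L) subject_ids <- rep(subject_ids, n_ep)
  if (length(subject_ids) != n_ep)
    stop("subject_ids length != number of epochs")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[1L]))
  structure(list(data = data, labels = labels,
                 subject_ids = as.character(subject_ids),
                 fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 label_map = c("0" = "DROWS", "1" = "TAV3", "2" = "TAVX")),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d epochs of %d channels x %d samples @ %g Hz\n",
              d[3L], d[1L], d[2L], x$fs))
  tab <- table(factor(x$labels, levels = 0:2,
                      labels = unname(x$label_map)))
  cat("  labels: ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  cat("  subjects:", paste(unique(x$subject_ids), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.eeg_epochs <- function(x) dim(x$data)[3L]

#' Subset an epoch collection
#'
#' @param x an `eeg_epochs` object.
#' @param i epoch index (logical or integer).
#' @param ... unused.
#' @return An `eeg_epochs` with the selected epochs.
#' @export
`[.eeg_epochs` <- function(x, i, ...) {
  eeg_epochs(x$data[, , i, drop = FALSE], x$labels[i], x$subject_ids[i],
             x$fs, x$channel_names)
}

#' Combine epoch collections
#'
#' @param ... `eeg_epochs` objects sharing channel count, window length and
#'   sampling rate.
#' @return A single `eeg_epochs`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "eeg_epochs"))
    xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L)
  dims <- vapply(xs, function(e) dim(e$data)[1:2], numeric(2L))
  if (any(dims != dims[, 1L]))
    stop("epoch collections have mismatched channel/window dimensions")
  eeg_epochs(array(unlist(lapply(xs, function(e) e$data)),
                   c(dims[1L, 1L], dims[2L, 1L],
                     sum(vapply(xs, length, 0L)))),
             unlist(lapply(xs, function(e) e$labels)),
             unlist(lapply(xs, function(e) e$subject_ids)),
             xs[[1L]]$fs, xs[[1L]]$channel_names)
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts consecutive, non-overlapping windows of
#' `round(fs * window_seconds)` samples; a trailing partial window is
#' discarded. Each epoch inherits the recording's stage label and subject id.
#' At 256 Hz with the default 0.5 s window every epoch is a
#' `channels x 128` matrix.
#'
#' @param rec a labeled [eeg_recording()].
#' @param window_seconds window length in seconds (default 0.5).
#' @return An [eeg_epochs()] collection.
#' @export
segment_epochs <- function(rec, window_seconds = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.na(rec$stage_label))
    stop("recording carries no stage label; label it before segmenting")
  win <- round(rec$fs * window_seconds)
  if (win < 1L) stop("window shorter than one sample")
  n <- ncol(rec$signal)
  n_ep <- n %/% win
  if (n_ep < 1L)
    stop(sprintf("recording (%d samples) shorter than one %d-sample window",
                 n, win))
  dat <- array(rec$signal[, seq_len(n_ep * win)],
               c(nrow(rec$signal), win, n_ep))
  pow <- apply(dat, 3L, function(w) sum(w * w))
  keep <- pow > 0
  if (!all(keep)) {
    warning(sum(!keep), " all-zero epoch(s) dropped")
    dat <- dat[, , keep, drop = FALSE]
  }
  eeg_epochs(dat, rep(rec$stage_label, sum(keep)), rec$subject_id,
             rec$fs, rec$channel_names)
}
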