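# Shared fixture builders: everything is generated in code at test time.

# Random symmetric positive-definite matrix, optionally trace-normalized.
rand_spd <- function(n, unit_trace = FALSE, jitter = 0.1) {
  a <- matrix(rnorm(n * n), n)
  s <- crossprod(a) / n + jitter * diag(n)
  s <- (s + t(s)) / 2
  if (unit_trace) s / sum(diag(s)) else s
}

# Epochs drawn from per-class spatial covariances (zero mean, white in time).
rand_epochs <- function(covs, n_per_class, win = 32L, subject_id = "s1") {
  n_ch <- nrow(covs[[1]])
  n_tot <- n_per_class * length(covs)
  dat <- array(0, c(n_ch, win, n_tot))
  labels <- integer(n_tot)
  i <- 0L
  for (c_ in seq_along(covs)) {
    cht <- t(chol(covs[[c_]]))
    for (e in seq_len(n_per_class)) {
      i <- i + 1L
      dat[, , i] <- cht %*% matrix(rnorm(n_ch * win), n_ch, win)
      labels[i] <- c_ - 1L
    }
  }
  eeg_epochs(dat, labels, subject_id, fs = 2 * win)
}

# Minimal EDF writer (identity physical/digital mapping) for round-trip tests.
write_tiny_edf <- function(path, digital, fs, labels = NULL) {
  ns <- nrow(digital)
  stopifnot(ncol(digital) %% fs == 0)
  n_rec <- ncol(digital) / fs
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) writeChar(formatC(as.character(x), width = -w),
                                  con, nchars = w, eos = NULL)
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(256 + ns * 256, 8); pad("", 44)
  pad(n_rec, 8); pad("1", 8); pad(ns, 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(ns)) pad("transducer", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(-32768, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad(-32768, 8)
  for (i in seq_len(ns)) pad(32767, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(fs, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_rec))
    for (i in seq_len(ns))
      writeBin(as.integer(digital[i, ((r - 1) * fs + 1):(r * fs)]),
               con, size = 2L, endian = "little")
  invisible(path)
}

# Two-class mixing-model data with one discriminative source: class A's
# source j has variance `ratio`, class B's has variance 1; all other
# sources share unit variance (the undiscriminative "noise" floor).
two_class_mixing <- function(n_ch = 15L, n_epochs = 200L, win = 128L,
                             ratio = 10, source = 1L) {
  a <- qr.Q(qr(matrix(rnorm(n_ch^2), n_ch)))
  gen <- function(var_j) {
    dat <- array(0, c(n_ch, win, n_epochs))
    sd_vec <- rep(1, n_ch); sd_vec[source] <- sqrt(var_j)
    for (e in seq_len(n_epochs))
      dat[, , e] <- a %*% (sd_vec * matrix(rnorm(n_ch * win), n_ch, win))
    dat
  }
  list(a = a, true_filter = solve(a)[source, ],
       class_a = gen(ratio), class_b = gen(1))
}

# Epochs container from two 3-D arrays (labels 0/1) for binary CSP tests.
epochs_from_arrays <- function(arr0, arr1, fs = 256) {
  n0 <- dim(arr0)[3]; n1 <- dim(arr1)[3]
  eeg_epochs(array(c(arr0, arr1), c(dim(arr0)[1], dim(arr0)[2], n0 + n1)),
             c(rep(0L, n0), rep(1L, n1)), "s1", fs)
}

# Exhaustive presorted exact-split oracle: enumerate every threshold between
# consecutive distinct raw values over all features; used against the
# histogram search when bins cover all distinct values.
exact_best_split <- function(x, g, h, lambda = 0, min_leaf = 1L) {
  best <- NULL
  score <- function(gs, hs) gs^2 / (hs + lambda)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2L) next
    for (t in seq_len(length(v) - 1L)) {
      thr <- (v[t] + v[t + 1L]) / 2
      left <- x[, j] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- score(sum(g[left]), sum(h[left])) +
        score(sum(g[!left]), sum(h[!left])) - score(sum(g), sum(h))
      if (gain > 0 && (is.null(best) || gain > best$gain + 1e-12))
        best <- list(feature = j, threshold = thr, gain = gain)
    }
  }
  best
}

# Dummy pipeline factories for protocol tests.
constant_pipeline <- function(label = 0L) {
  function() {
    self <- list(fit = function(epochs) invisible(self),
                 predict = function(epochs) rep(label, length(epochs)),
                 state = function() list())
    self
  }
}

oracle_pipeline <- function() {
  function() {
    self <- list(fit = function(epochs) invisible(self),
                 predict = function(epochs) epochs$labels,
                 state = function() list())
    self
  }
}
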