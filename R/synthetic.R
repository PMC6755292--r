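# Synthetic multi-subject EEG with class-conditional spatial covariance:
# exactly the second-order structure CSP assumes, so the full pipeline can be
# exercised without access-restricted recordings.

#' Generator configuration for synthetic studies
#'
#' Defaults emulate the recording setup the package targets: 15 channels at
#' 256 Hz, 0.5 s windows (so epochs are 15 x 128), three mental-state
#' classes whose covariance templates share one orthogonal spatial basis but
#' boost disjoint directions. `subject_jitter` scales a random congruence
#' transform applied per subject (electrode-placement / anatomy variability);
#' `noise_std` is the standard deviation of additive white sensor noise, on
#' the template scale of unit mean channel variance.
#'
#' @param n_channels number of electrodes (default 15).
#' @param fs sampling rate in Hz (default 256).
#' @param window_seconds epoch length in seconds (default 0.5).
#' @param epochs_per_class epochs per class per subject (default 200).
#' @param separation class-covariance separation in `(0, 1]`; 0 limit makes
#'   the three templates identical (default 0.8).
#' @param subject_jitter scale of the per-subject congruence perturbation
#'   (default 0.1).
#' @param noise_std additive sensor-noise SD (default 0.3).
#' @param oscillatory if `TRUE`, sources carry a 10 Hz (alpha-band)
#'   amplitude modulation instead of being white in time.
#' @param seed integer master seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_channels = 15L, fs = 256, window_seconds = 0.5,
                             epochs_per_class = 200L, separation = 0.8,
                             subject_jitter = 0.1, noise_std = 0.3,
                             oscillatory = FALSE, seed = 1L) {
  stopifnot(n_channels >= 2L, fs > 0, window_seconds > 0,
            epochs_per_class >= 1L, separation >= 0, separation <= 1,
            subject_jitter >= 0, noise_std >= 0)
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 window_seconds = window_seconds,
                 epochs_per_class = as.integer(epochs_per_class),
                 separation = separation, subject_jitter = subject_jitter,
                 noise_std = noise_std, oscillatory = isTRUE(oscillatory),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Class covariance templates with controllable separation
#'
#' Builds three SPD templates `Sigma_c = A D_c A'` sharing a random
#' orthogonal basis `A`. The eigenvalue profiles `D_c` decay geometrically
#' (a coarse stand-in for the 1/f-like EEG spectrum) and each class boosts a
#' disjoint block of three basis directions by a factor growing with
#' `separation`; at `separation = 0` the three templates coincide, at
#' `separation = 1` each class's dominant direction is orthogonal to the
#' others'. Templates are scaled to trace `n_channels` (unit mean channel
#' variance).
#'
#' @param n_channels number of channels (>= 2; blocks shrink below 9).
#' @param separation separation strength in `[0, 1]`.
#' @param seed integer seed for the shared basis.
#' @return List of three SPD matrices `sigma0`, `sigma1`, `sigma2`, with the
#'   basis `A` and per-class boosted-direction indices as attributes.
#' @export
make_class_covariances <- function(n_channels, separation = 0.8, seed = 1L) {
  stopifnot(n_channels >= 2L, separation >= 0, separation <= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  a <- qr.Q(qr(matrix(stats::rnorm(n_channels^2), n_channels)))
  base <- 2 * 0.9^(seq_len(n_channels) - 1)
  block <- max(1L, min(3L, n_channels %/% 3L))
  blocks <- lapply(0:2, function(c_)
    seq.int(c_ * block + 1L, min((c_ + 1L) * block, n_channels)))
  out <- lapply(0:2 + 1L, function(c_) {
    d <- base
    d[blocks[[c_]]] <- d[blocks[[c_]]] * (1 + 6 * separation)
    s <- a %*% diag(d) %*% t(a)
    s <- (s + t(s)) / 2
    s * n_channels / sum(diag(s))
  })
  names(out) <- paste0("sigma", 0:2)
  attr(out, "basis") <- a
  attr(out, "boosted") <- blocks
  out
}

# Scoped RNG helpers: the generator sets seeds internally without clobbering
# the caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# Draw one epoch: spatially colored Gaussian (optionally alpha-modulated in
# time) plus white sensor noise.
draw_epoch <- function(chol_t, win, noise_std, oscillatory, fs) {
  n_ch <- ncol(chol_t)
  z <- matrix(stats::rnorm(n_ch * win), n_ch, win)
  if (oscillatory) {
    tt <- seq_len(win) / fs
    env <- 1 + 0.7 * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi))
    z <- z * matrix(env / sqrt(mean(env^2)), n_ch, win, byrow = TRUE)
  }
  x <- chol_t %*% z
  if (noise_std > 0)
    x <- x + noise_std * matrix(stats::rnorm(n_ch * win), n_ch, win)
  x
}

#' Simulate one subject's labeled epochs
#'
#' For each class `c` the subject's covariance is the congruence-perturbed
#' template `Sigma_c^(s) = J Sigma_c J'` with `J = I + jitter * R`
#' (`R` standard normal), which preserves positive definiteness whenever `J`
#' is nonsingular; in the measure-zero singular case `J` is redrawn with the
#' jitter halved and a message is emitted. Epochs are zero-mean Gaussian in
#' time with that spatial covariance, plus white noise.
#'
#' @param config a [generator_config()].
#' @param subject_id subject identifier string.
#' @param templates optional template list from [make_class_covariances()];
#'   generated from the config when missing.
#' @param subject_index integer used to derive the subject's seed from the
#'   master seed (defaults to a hash of `subject_id`).
#' @return An [eeg_epochs()] with `config$epochs_per_class` epochs per class,
#'   ordered class 0, 1, 2.
#' @export
simulate_subject <- function(config, subject_id = "s1", templates = NULL,
                             subject_index = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(templates))
    templates <- make_class_covariances(config$n_channels, config$separation,
                                        config$seed)
  if (is.null(subject_index))
    subject_index <- sum(utf8ToInt(subject_id)) %% 1000L
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed((config$seed + 10007L * as.integer(subject_index)) %% .Machine$integer.max)
  n_ch <- config$n_channels
  win <- round(config$fs * config$window_seconds)
  jit <- config$subject_jitter
  j_s <- diag(n_ch) + jit * matrix(stats::rnorm(n_ch^2), n_ch)
  while (abs(det(j_s)) < 1e-12) {
    jit <- jit / 2
    message("singular subject transform; redrawing with jitter ", jit)
    j_s <- diag(n_ch) + jit * matrix(stats::rnorm(n_ch^2), n_ch)
  }
  n_per <- config$epochs_per_class
  dat <- array(0, c(n_ch, win, 3L * n_per))
  labels <- integer(3L * n_per)
  i <- 0L
  for (c_ in 0:2) {
    sig_s <- j_s %*% templates[[c_ + 1L]] %*% t(j_s)
    cht <- t(chol((sig_s + t(sig_s)) / 2))
    for (e in seq_len(n_per)) {
      i <- i + 1L
      dat[, , i] <- draw_epoch(cht, win, config$noise_std,
                               config$oscillatory, config$fs)
      labels[i] <- c_
    }
  }
  eeg_epochs(dat, labels, subject_id, config$fs,
             if (n_ch == 15L) standard_montage_15() else NULL)
}

#' Simulate a multi-subject study
#'
#' Independent subject streams derived from one master seed, sharing the
#' class templates; mirrors a 10-subject recording campaign by default.
#'
#' @param config a [generator_config()].
#' @param n_subjects number of subjects (default 10).
#' @return A `synthetic_study`: list with `subjects` (named list of
#'   [eeg_epochs()]), `templates` (ground-truth covariances) and `config`.
#' @export
simulate_study <- function(config, n_subjects = 10L) {
  stopifnot(inherits(config, "generator_config"), n_subjects >= 1L)
  templates <- make_class_covariances(config$n_channels, config$separation,
                                      config$seed)
  ids <- paste0("s", seq_len(n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(config, ids[i], templates, subject_index = i))
  names(subjects) <- ids
  structure(list(subjects = subjects, templates = templates, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects x %d epochs/class, %d channels @ %g Hz\n",
              length(x$subjects), x$config$epochs_per_class,
              x$config$n_channels, x$config$fs))
  cat(sprintf("  separation=%g jitter=%g noise_std=%g seed=%d\n",
              x$config$separation, x$config$subject_jitter,
              x$config$noise_std, x$config$seed))
  invisible(x)
}

#' Write a synthetic study to disk as matrix_csv recordings
#'
#' One file per subject and class (epochs concatenated back into a
#' continuous strip) plus a `manifest.csv` with subject, label, file and
#' shape columns, consumable by the preprocessing and evaluation tools.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (sid in names(study$subjects)) {
    ep <- study$subjects[[sid]]
    for (c_ in 0:2) {
      idx <- which(ep$labels == c_)
      strip <- matrix(ep$data[, , idx], dim(ep$data)[1L])
      f <- file.path(dir, sprintf("%s_class%d.csv", sid, c_))
      write_matrix_csv(strip, f, fs = ep$fs, channel_names = ep$channel_names)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, label = c_, file = basename(f),
        n_channels = dim(ep$data)[1L], n_epochs = length(idx),
        window_samples = dim(ep$data)[2L])
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a study back from a directory written by [write_study()]
#'
#' @param dir directory containing `manifest.csv` and the per-subject files.
#' @return A list of per-subject [eeg_epochs()] (a `synthetic_study` without
#'   ground-truth templates).
#' @export
read_study <- function(dir) {
  mp <- file.path(dir, "manifest.csv")
  if (!file.exists(mp)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(mp, stringsAsFactors = FALSE)
  subjects <- lapply(split(manifest, manifest$subject), function(rows) {
    parts <- lapply(seq_len(nrow(rows)), function(i) {
      rec <- load_recording(file.path(dir, rows$file[i]),
                            subject_id = rows$subject[i],
                            stage_label = rows$label[i])
      eeg_epochs(array(rec$signal, c(rows$n_channels[i],
                                     rows$window_samples[i],
                                     rows$n_epochs[i])),
                 rep(rows$label[i], rows$n_epochs[i]), rows$subject[i],
                 rec$fs, rec$channel_names)
    })
    bind_epochs(parts)
  })
  subjects <- subjects[unique(manifest$subject)]
  structure(list(subjects = subjects, templates = NULL, config = NULL),
            class = "synthetic_study")
}
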