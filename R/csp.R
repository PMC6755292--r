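#' Trace-normalized spatial covariance of one epoch
#'
#' For a channel-centered trial matrix `W` (channels x samples) the
#' normalized spatial covariance is `C = W W' / trace(W W')`: a symmetric
#' positive semi-definite matrix of unit trace. Channels are mean-centered
#' within the epoch before the product so that `C` is a covariance proper
#' (band-pass filtering already removes DC over long stretches, centering
#' closes the gap within a short window).
#'
#' @param w numeric matrix `channels x samples` (one epoch's data).
#' @param center mean-center each channel first (default); set `FALSE` when
#'   the input is already centered and the raw second-moment form is wanted.
#' @return Unit-trace symmetric PSD matrix `channels x channels`.
#' @export
normalized_covariance <- function(w, center = TRUE) {
  w <- as.matrix(w)
  if (center) w <- w - rowMeans(w)
  s <- tcrossprod(w)
  tr <- sum(diag(s))
  if (tr <= 0)
    stop("degenerate epoch: zero total power, covariance undefined")
  c_ <- s / tr
  (c_ + t(c_)) / 2
}

#' Class-mean spatial covariance over an epoch set
#'
#' Arithmetic mean of the per-epoch normalized covariances of every epoch
#' carrying `target_label`; unit trace is preserved by the average.
#'
#' @param epochs an [eeg_epochs()] collection.
#' @param target_label integer class id, or a vector of ids to pool (used by
#'   the one-vs-rest triclass construction).
#' @return Unit-trace symmetric PSD matrix.
#' @export
class_mean_covariance <- function(epochs, target_label) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- which(epochs$labels %in% target_label)
  if (!length(idx))
    stop("no epochs with label(s) ", paste(target_label, collapse = ","))
  d <- dim(epochs$data)
  # center each epoch per channel, scale by 1/sqrt(trace) so one flattened
  # cross-product accumulates the sum of trace-normalized covariances
  x <- matrix(epochs$data[, , idx], d[1L], d[2L] * length(idx))
  grp <- rep(seq_along(idx), each = d[2L])
  mu <- rowsum(t(x), grp) / d[2L]                 # n_sel x n_ch epoch means
  x <- x - t(mu)[, grp, drop = FALSE]
  tr <- rowsum(colSums(x * x), grp)
  if (any(tr <= 0))
    stop("degenerate epoch: zero total power, covariance undefined")
  x <- x * rep(1 / sqrt(tr[grp]), each = d[1L])
  acc <- tcrossprod(x) / length(idx)
  (acc + t(acc)) / 2
}

#' Whitening transform of a composite covariance
#'
#' From the symmetric eigendecomposition `C_c = E diag(lambda) E'` with
#' eigenvalues in descending order, returns `P = diag(lambda^(-1/2)) E'`,
#' so that `P C_c P' = I`.
#'
#' @param c_composite symmetric positive-definite matrix.
#' @param tol relative eigenvalue tolerance below which the composite is
#'   declared singular (duplicated or silent channels).
#' @return The whitening matrix `P` (same dimension as the input).
#' @export
whitening_transform <- function(c_composite, tol = 1e-10) {
  c_composite <- as.matrix(c_composite)
  if (max(abs(c_composite - t(c_composite))) > 1e-8)
    stop("composite covariance is not symmetric")
  e <- eigen(c_composite, symmetric = TRUE)   # values descending
  if (any(e$values <= tol * max(e$values)))
    stop("singular composite covariance (rank-deficient or duplicated ",
         "channels): smallest eigenvalue ", format(min(e$values)))
  diag(1 / sqrt(e$values)) %*% t(e$vectors)
}

#' Binary common spatial pattern projection
#'
#' Implements the two-class CSP: the composite covariance
#' `C_c = C_target + C_other` is whitened by `P`; the whitened target
#' covariance `S_d = P C_target P'` is diagonalized, `S_d = B diag(l_d) B'`,
#' and because `S_d + S_t = I` the same `B` diagonalizes
#' `S_t = P C_other P'` with eigenvalues `1 - l_d`. The returned filters are
#' the rows of `B' P`, ordered by descending target-class eigenvalue, each
#' row's sign fixed so that its largest-magnitude coefficient is positive
#' (eigenvectors are sign-ambiguous; the convention makes sums of
#' projections well defined).
#'
#' @param c_target,c_other unit-trace class-mean covariances.
#' @param n_pairs optionally keep only the `n_pairs` top and `n_pairs`
#'   bottom filters (most discriminative for each class); default keeps all.
#' @return A `csp_projection`: list with `filters`
#'   (`n_components x n_channels`), `eigenvalues` (target-class, descending)
#'   and `source = "binary"`.
#' @export
csp_binary <- function(c_target, c_other, n_pairs = NULL) {
  c_target <- as.matrix(c_target); c_other <- as.matrix(c_other)
  if (max(abs(c_target - t(c_target))) > 1e-8 ||
      max(abs(c_other - t(c_other))) > 1e-8)
    stop("class covariances must be symmetric")
  if (!all(dim(c_target) == dim(c_other)))
    stop("class covariances have mismatched dimensions")
  p <- whitening_transform(c_target + c_other)
  s_d <- p %*% c_target %*% t(p)
  s_d <- (s_d + t(s_d)) / 2
  e <- eigen(s_d, symmetric = TRUE)           # lambda_d descending
  lam_d <- e$values
  # S_d + S_t = P C_c P' = I, so the other-class eigenvalues are 1 - lam_d
  s_t <- p %*% c_other %*% t(p)
  lam_t <- diag(t(e$vectors) %*% s_t %*% e$vectors)
  if (max(abs(lam_d + lam_t - 1)) > 1e-8)
    stop("eigenvalue complementarity lambda_d + lambda_t = 1 violated; ",
         "inputs are not a consistent covariance pair")
  filt <- t(e$vectors) %*% p
  filt <- canonicalize_rows(filt)
  if (!is.null(n_pairs)) {
    m <- nrow(filt)
    if (2L * n_pairs > m) stop("n_pairs too large for ", m, " components")
    keep <- c(seq_len(n_pairs), (m - n_pairs + 1L):m)
    filt <- filt[keep, , drop = FALSE]
    lam_d <- lam_d[keep]
  }
  structure(list(filters = filt, eigenvalues = lam_d, source = "binary"),
            class = "csp_projection")
}

# Fix the sign of each filter row: largest-|coefficient| entry positive.
canonicalize_rows <- function(m) {
  sgn <- apply(m, 1L, function(r) {
    s <- sign(r[which.max(abs(r))]); if (s == 0) 1 else s
  })
  m * sgn
}

#' Triclass CSP projection for drowsy / awake / neutral EEG
#'
#' The three-class extension builds two one-vs-rest binary CSP problems —
#' the fatigue class (`DROWS`, label 0) against everything else, and the
#' neutral class (`TAVX`, label 2) against everything else; the awake state
#' is the easiest to separate and needs no projection of its own — and sums
#' the two canonicalized filter matrices: `P_N = P_A + P_B`. An alternative
#' contrast pits each target class against the awake class only
#' (`contrast = "awake"`).
#'
#' @param train an [eeg_epochs()] training collection containing all three
#'   labels.
#' @param fatigue_label,neutral_label class ids of the two projected states
#'   (defaults 0 and 2).
#' @param contrast `"rest"` (one-vs-rest, default) or `"awake"`
#'   (target vs the remaining third class only).
#' @param n_pairs retain only the `n_pairs` extreme filters per binary
#'   problem; default keeps all `n_channels` components.
#' @return A `csp_projection` with `source = "triclass"`, whose `filters`
#'   matrix is the element-wise sum of the two binary projections.
#' @export
csp_triclass <- function(train, fatigue_label = 0L, neutral_label = 2L,
                         contrast = c("rest", "awake"), n_pairs = NULL) {
  stopifnot(inherits(train, "eeg_epochs"))
  contrast <- match.arg(contrast)
  labs <- sort(unique(train$labels))
  for (l in 0:2)
    if (!l %in% labs)
      stop("class ", l, " (", stage_name(l), ") absent from training set")
  other_a <- if (contrast == "rest") setdiff(labs, fatigue_label) else
    setdiff(labs, c(fatigue_label, neutral_label))
  other_b <- if (contrast == "rest") setdiff(labs, neutral_label) else
    setdiff(labs, c(fatigue_label, neutral_label))
  p_a <- csp_binary(class_mean_covariance(train, fatigue_label),
                    class_mean_covariance(train, other_a), n_pairs = n_pairs)
  p_b <- csp_binary(class_mean_covariance(train, neutral_label),
                    class_mean_covariance(train, other_b), n_pairs = n_pairs)
  structure(list(filters = p_a$filters + p_b$filters,
                 eigenvalues = cbind(fatigue = p_a$eigenvalues,
                                     neutral = p_b$eigenvalues),
                 source = "triclass", contrast = contrast,
                 p_a = p_a, p_b = p_b),
            class = "csp_projection")
}

#' @export
print.csp_projection <- function(x, ...) {
  cat(sprintf("<csp_projection> %s: %d filters x %d channels\n",
              x$source, nrow(x$filters), ncol(x$filters)))
  invisible(x)
}

#' Project an epoch and reduce to per-component variances
#'
#' Computes the projected trial `F = P W` and returns the variance of each
#' row of `F` (population convention, divide by the sample count). Plain
#' variance is used, not the conventional log-variance. Variance is
#' invariant to the sign ambiguity of spatial filters.
#'
#' @param projection a `csp_projection` (or bare filter matrix).
#' @param w one epoch matrix `channels x samples`.
#' @return Numeric vector of length `n_components`, all entries >= 0.
#' @export
project_features <- function(projection, w) {
  filt <- if (inherits(projection, "csp_projection"))
    projection$filters else as.matrix(projection)
  w <- as.matrix(w)
  if (ncol(filt) != nrow(w))
    stop("projection expects ", ncol(filt), " channels, epoch has ", nrow(w))
  f <- filt %*% w
  rowMeans(f * f) - rowMeans(f)^2
}

#' Variance features for every epoch in a collection
#'
#' @param projection a `csp_projection`.
#' @param epochs an [eeg_epochs()] collection.
#' @return Numeric matrix `n_epochs x n_components`, with the epoch labels
#'   and subject ids attached as attributes `"labels"` / `"subject_ids"`.
#' @export
epoch_features <- function(projection, epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n_ep <- length(epochs)
  filt <- if (inherits(projection, "csp_projection"))
    projection$filters else as.matrix(projection)
  d <- dim(epochs$data)
  if (ncol(filt) != d[1L])
    stop("projection expects ", ncol(filt), " channels, epochs have ", d[1L])
  k <- nrow(filt)
  # project all epochs in one product, then per-component moments via
  # grouped row sums over the k x win blocks of each epoch
  f <- filt %*% matrix(epochs$data, d[1L], d[2L] * d[3L])
  blk <- matrix(f, k * d[2L], d[3L])
  grp <- rep.int(seq_len(k), d[2L])
  s1 <- rowsum(blk, grp) / d[2L]
  s2 <- rowsum(blk * blk, grp) / d[2L]
  out <- t(s2 - s1^2)
  colnames(out) <- paste0("f", seq_len(ncol(out)))
  attr(out, "labels") <- epochs$labels
  attr(out, "subject_ids") <- epochs$subject_ids
  out
}

#' Write a projection matrix as matrix_csv
#'
#' The header records the source mode and channel names so the projection
#' can be re-applied elsewhere.
#'
#' @param projection a `csp_projection`.
#' @param path output path.
#' @param channel_names optional channel names recorded in the header.
#' @return `path`, invisibly.
#' @export
write_projection <- function(projection, path, channel_names = NULL) {
  stopifnot(inherits(projection, "csp_projection"))
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(projection$filters)))
  write_matrix_csv(projection$filters, path,
                   fs = 0, channel_names = channel_names)
  invisible(path)
}

#' Read a projection matrix written by [write_projection()]
#'
#' @param path a matrix_csv file of spatial filters (rows = components).
#' @return A bare filter matrix usable with [project_features()] and
#'   [epoch_features()].
#' @export
read_projection <- function(path) {
  read_matrix_csv(path)$signal
}
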