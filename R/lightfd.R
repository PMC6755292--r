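# Histogram-based, leafwise, depth-limited multiclass gradient boosting.
#
# The booster discretizes each feature into at most k bins (quantile edges
# fixed once at fit time), accumulates per-bin gradient/hessian/count sums at
# every tree node, and scans bin boundaries for the split maximizing
#   gain = G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda).
# Trees grow leafwise: the leaf with the globally highest positive gain is
# split next, until num_leaves leaves exist, no positive gain remains, or the
# depth cap stops every candidate. Multiclass uses the softmax objective with
# one tree per class per round (gradient p - y, hessian p(1-p)).

#' Default LightFD training parameters
#'
#' `num_trees` boosting rounds (each fits one tree per class),
#' `num_leaves` maximum leaves per tree, `learning_rate` shrinkage on leaf
#' weights, `max_depth` depth cap for leafwise growth, `k_bins` histogram
#' width, `lambda_l2` L2 penalty on leaf weights, `min_leaf` minimum samples
#' per leaf. Smaller learning rates with more trees trade accuracy against
#' time; the depth cap keeps leafwise growth from producing pathologically
#' deep trees.
#'
#' @param ... overrides for any of the defaults.
#' @return Named list of parameters.
#' @export
lightfd_params <- function(...) {
  p <- list(num_trees = 100L, num_leaves = 31L, learning_rate = 0.1,
            max_depth = 8L, k_bins = 255L, lambda_l2 = 0, min_leaf = 20L,
            seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p$num_trees <- as.integer(p$num_trees)
  p$num_leaves <- as.integer(p$num_leaves)
  p$max_depth <- as.integer(p$max_depth)
  p$k_bins <- as.integer(p$k_bins)
  p$min_leaf <- as.integer(p$min_leaf)
  stopifnot(p$num_trees >= 0L, p$num_leaves >= 1L, p$k_bins >= 2L,
            p$learning_rate > 0, p$learning_rate <= 1, p$max_depth >= 1L)
  p
}

#' Per-feature histogram bin edges
#'
#' Quantile-based edges giving at most `k` bins per feature. A feature with
#' fewer than `k` distinct values gets one bin per distinct value (edges at
#' midpoints), so binned split search is then exact. A sample falls in bin
#' `b` iff `edges[b-1] < x <= edges[b]` (open left, closed right; the
#' outermost bins are unbounded).
#'
#' @param features numeric matrix `n x d`.
#' @param k maximum bins per feature (>= 2).
#' @return List of `d` numeric vectors of strictly increasing interior edges
#'   (length = bins - 1).
#' @export
build_bins <- function(features, k = 255L) {
  features <- as.matrix(features)
  if (any(!is.finite(features)))
    stop("non-finite feature values")
  stopifnot(nrow(features) >= 1L, k >= 2L)
  lapply(seq_len(ncol(features)), function(j) {
    v <- sort(unique(features[, j]))
    if (length(v) <= 1L) return(numeric(0L))
    if (length(v) <= k) return((v[-length(v)] + v[-1L]) / 2)
    q <- stats::quantile(features[, j], probs = seq_len(k - 1L) / k,
                         names = FALSE, type = 7L)
    unique(q)
  })
}

#' Map features to bin indices
#'
#' @param features numeric matrix `n x d`.
#' @param edges per-feature edge list from [build_bins()].
#' @return Integer matrix `n x d` of 1-based bin indices.
#' @export
bin_features <- function(features, edges) {
  features <- as.matrix(features)
  if (ncol(features) != length(edges))
    stop("feature dimension (", ncol(features),
         ") does not match bin edges (", length(edges), ")")
  out <- matrix(1L, nrow(features), ncol(features))
  for (j in seq_along(edges))
    if (length(edges[[j]]))
      out[, j] <- findInterval(features[, j], edges[[j]],
                               left.open = TRUE) + 1L
  out
}

#' Accumulate a gradient/hessian histogram for a tree node
#'
#' For each feature, sums gradients, hessians and sample counts per bin over
#' the node's samples; one data pass per feature, bin index as accumulator
#' address. The accumulation is partitionable: histograms of disjoint sample
#' subsets merge by bin-wise addition (see the conservation test), which is
#' what makes sample-parallel construction exact.
#'
#' @param binned integer bin matrix from [bin_features()].
#' @param idx integer indices of the node's samples.
#' @param grad,hess numeric vectors aligned with the full sample set.
#' @param n_bins per-feature bin counts (length-`d` integer).
#' @return List of matrices `grad`, `hess`, `count`, each `max_bins x d`.
#' @export
accumulate_histogram <- function(binned, idx, grad, hess, n_bins) {
  storage.mode(binned) <- "integer"
  .hist_accumulate_cpp(binned, as.integer(idx), as.numeric(grad),
                       as.numeric(hess), as.integer(max(n_bins)))
}

#' Best histogram split for a node
#'
#' Scans every feature's bin boundaries for the gain-maximizing split of the
#' node's histogram, subject to both children holding at least `min_leaf`
#' samples. Ties break to the lowest feature index, then the lowest bin.
#'
#' @param hist node histogram from [accumulate_histogram()].
#' @param n_bins per-feature bin counts.
#' @param lambda_l2 L2 regularization added to hessian sums.
#' @param min_leaf minimum child sample count.
#' @return `NULL` if no positive-gain split exists, else a list
#'   `(feature, bin, gain)` — samples with bin index `<= bin` go left.
#' @export
best_split <- function(hist, n_bins, lambda_l2 = 0, min_leaf = 1L) {
  mb <- nrow(hist$grad)
  d <- length(n_bins)
  # column-wise prefix sums over bins; rows at/after each feature's last bin
  # are not valid split boundaries
  gl <- apply(hist$grad, 2L, cumsum)
  hl <- apply(hist$hess, 2L, cumsum)
  cl <- apply(hist$count, 2L, cumsum)
  if (is.null(dim(gl))) { gl <- rbind(gl); hl <- rbind(hl); cl <- rbind(cl) }
  gt <- rep(gl[mb, ], each = mb); ht <- rep(hl[mb, ], each = mb)
  ct <- rep(cl[mb, ], each = mb)
  valid <- (row(gl) < matrix(n_bins, mb, d, byrow = TRUE)) &
    cl >= min_leaf & (ct - cl) >= min_leaf
  gain <- gl^2 / (hl + lambda_l2) + (gt - gl)^2 / (ht - hl + lambda_l2) -
    gt^2 / (ht + lambda_l2)
  gain[!valid] <- -Inf
  b <- which.max(gain)       # column-major: lowest feature then lowest bin
  if (!length(b) || gain[b] <= 0) return(NULL)
  list(feature = ((b - 1L) %/% mb) + 1L, bin = ((b - 1L) %% mb) + 1L,
       gain = gain[b])
}

# Grow one regression tree leafwise on (grad, hess). Returns a data.frame of
# nodes: is_leaf, feature, bin, threshold, weight, left, right, depth, gain.
grow_tree <- function(binned, edges, grad, hess, params) {
  n_bins <- vapply(edges, function(e) length(e) + 1L, 0L)
  lam <- params$lambda_l2
  nodes <- list()
  new_node <- function(idx, depth) {
    id <- length(nodes) + 1L
    h <- accumulate_histogram(binned, idx, grad, hess, n_bins)
    g_sum <- sum(grad[idx]); h_sum <- sum(hess[idx])
    cand <- if (depth < params$max_depth &&
                length(idx) >= 2L * params$min_leaf)
      best_split(h, n_bins, lam, params$min_leaf) else NULL
    nodes[[id]] <<- list(id = id, idx = idx, depth = depth, hist = h,
                         weight = -g_sum / (h_sum + lam), cand = cand,
                         is_leaf = TRUE, feature = NA_integer_,
                         bin = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         gain = NA_real_)
    id
  }
  new_node(seq_along(grad), 0L)
  n_leaves <- 1L
  repeat {
    if (n_leaves >= params$num_leaves) break
    gains <- vapply(nodes, function(nd)
      if (nd$is_leaf && !is.null(nd$cand)) nd$cand$gain else -Inf, 0)
    if (all(gains == -Inf)) break
    s <- which.max(gains)                     # lowest node id on ties
    nd <- nodes[[s]]
    f <- nd$cand$feature; b <- nd$cand$bin
    go_left <- binned[nd$idx, f] <= b
    lid <- new_node(nd$idx[go_left], nd$depth + 1L)
    rid <- new_node(nd$idx[!go_left], nd$depth + 1L)
    nodes[[s]]$is_leaf <- FALSE
    nodes[[s]]$feature <- f
    nodes[[s]]$bin <- b
    nodes[[s]]$threshold <- edges[[f]][b]
    nodes[[s]]$left <- lid
    nodes[[s]]$right <- rid
    nodes[[s]]$gain <- nd$cand$gain
    n_leaves <- n_leaves + 1L
  }
  data.frame(
    is_leaf = vapply(nodes, `[[`, TRUE, "is_leaf"),
    feature = vapply(nodes, `[[`, 1L, "feature"),
    threshold = vapply(nodes, `[[`, 1, "threshold"),
    bin = vapply(nodes, `[[`, 1L, "bin"),
    weight = vapply(nodes, `[[`, 1, "weight"),
    left = vapply(nodes, `[[`, 1L, "left"),
    right = vapply(nodes, `[[`, 1L, "right"),
    depth = vapply(nodes, `[[`, 1L, "depth"),
    gain = vapply(nodes, `[[`, 1, "gain"))
}

# Tree evaluation on a raw feature matrix (compiled traversal).
predict_tree <- function(tree, features) {
  thr <- tree$threshold
  thr[is.na(thr)] <- 0
  .tree_predict_cpp(tree$is_leaf,
                    ifelse(is.na(tree$feature), 1L, tree$feature), thr,
                    tree$weight,
                    ifelse(is.na(tree$left), 1L, tree$left),
                    ifelse(is.na(tree$right), 1L, tree$right), features)
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}

#' Fit a LightFD gradient-boosted tree classifier
#'
#' Trains `num_trees` rounds of `K` depth-limited leafwise trees (one per
#' class) on the softmax objective. Base scores are the log class priors,
#' so an empty ensemble predicts the prior frequencies. Training is
#' deterministic: full-sample boosting with no subsampling, so identical
#' inputs always give identical models.
#'
#' @param features numeric matrix `n x d` (e.g. from [epoch_features()]).
#' @param labels integer class ids in `0..K-1`.
#' @param params parameter list from [lightfd_params()].
#' @return A `lightfd_model`: bin edges, per-class base scores, tree list,
#'   and the per-round training log-loss trace.
#' @export
lightfd_fit <- function(features, labels, params = lightfd_params()) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (any(!is.finite(features))) stop("non-finite feature values")
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(features))
  classes <- sort(unique(labels))
  k_cls <- length(classes)
  if (k_cls < 2L) stop("training needs at least 2 classes, got ", k_cls)
  n <- nrow(features)
  y <- matrix(0, n, k_cls)
  for (k in seq_len(k_cls)) y[labels == classes[k], k] <- 1
  edges <- build_bins(features, params$k_bins)
  binned <- bin_features(features, edges)
  base <- log(colMeans(y))
  scores <- matrix(base, n, k_cls, byrow = TRUE)
  trees <- vector("list", params$num_trees)
  loss <- numeric(params$num_trees + 1L)
  p <- softmax_rows(scores)
  loss[1L] <- -mean(log(pmax(p[y == 1], 1e-15)))
  if (params$num_trees > 0L) for (t in seq_len(params$num_trees)) {
    p <- softmax_rows(scores)
    grad <- p - y
    hess <- p * (1 - p)
    round_trees <- vector("list", k_cls)
    for (k in seq_len(k_cls)) {
      tr <- grow_tree(binned, edges, grad[, k], hess[, k], params)
      round_trees[[k]] <- tr
      scores[, k] <- scores[, k] + params$learning_rate *
        predict_tree(tr, features)
    }
    trees[[t]] <- round_trees
    p <- softmax_rows(scores)
    loss[t + 1L] <- -mean(log(pmax(p[y == 1], 1e-15)))
  }
  structure(list(trees = trees, classes = classes, base_scores = base,
                 bin_edges = edges, params = params, n_features = ncol(features),
                 train_logloss = loss),
            class = "lightfd_model")
}

#' @export
print.lightfd_model <- function(x, ...) {
  cat(sprintf("<lightfd_model> %d rounds x %d classes, %d features\n",
              length(x$trees), length(x$classes), x$n_features))
  cat(sprintf("  num_leaves=%d max_depth=%d learning_rate=%g k_bins=%d\n",
              x$params$num_leaves, x$params$max_depth,
              x$params$learning_rate, x$params$k_bins))
  cat(sprintf("  final training log-loss: %.5f\n",
              x$train_logloss[length(x$train_logloss)]))
  invisible(x)
}

#' Class probabilities from a fitted model
#'
#' Softmax of the base scores plus the learning-rate-scaled sum of leaf
#' weights over every tree; each row lies on the probability simplex.
#'
#' @param model a `lightfd_model`.
#' @param features numeric matrix with `model$n_features` columns.
#' @return Matrix `n x K` of probabilities, columns named by class id.
#' @export
lightfd_predict_proba <- function(model, features) {
  stopifnot(inherits(model, "lightfd_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("model expects ", model$n_features, " features, got ",
         ncol(features))
  k_cls <- length(model$classes)
  scores <- matrix(model$base_scores, nrow(features), k_cls, byrow = TRUE)
  for (round_trees in model$trees)
    for (k in seq_len(k_cls))
      scores[, k] <- scores[, k] + model$params$learning_rate *
        predict_tree(round_trees[[k]], features)
  p <- softmax_rows(scores)
  colnames(p) <- model$classes
  p
}

#' Predicted class labels
#'
#' @inheritParams lightfd_predict_proba
#' @return Integer vector of class ids (argmax of the probabilities).
#' @export
lightfd_predict <- function(model, features) {
  p <- lightfd_predict_proba(model, features)
  model$classes[max.col(p, ties.method = "first")]
}

#' Serialize a model to self-describing JSON text
#'
#' The full ensemble (bin edges, trees, weights, parameters) round-trips
#' through text with full double precision, so a reloaded model reproduces
#' predictions exactly.
#'
#' @param model a `lightfd_model`.
#' @param path output path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
lightfd_save <- function(model, path = NULL) {
  stopifnot(inherits(model, "lightfd_model"))
  obj <- list(
    format = "lightfd-1",
    classes = model$classes,
    base_scores = model$base_scores,
    n_features = model$n_features,
    params = model$params,
    bin_edges = model$bin_edges,
    train_logloss = model$train_logloss,
    trees = lapply(model$trees, function(rt) lapply(rt, as.list)))
  # 17 significant digits: doubles round-trip bit-exactly through the text
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Reload a serialized model
#'
#' @param path path to a file written by [lightfd_save()].
#' @return A `lightfd_model` giving identical predictions to the original.
#' @export
lightfd_load <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(obj$format, "lightfd-1"))
    stop("not a lightfd model file")
  trees <- lapply(obj$trees, function(rt)
    lapply(rt, function(tr) {
      df <- as.data.frame(tr)
      df$feature <- as.integer(df$feature)
      df$bin <- as.integer(df$bin)
      df$left <- as.integer(df$left)
      df$right <- as.integer(df$right)
      df$depth <- as.integer(df$depth)
      df
    }))
  prm <- obj$params
  prm$num_trees <- as.integer(prm$num_trees)
  prm$num_leaves <- as.integer(prm$num_leaves)
  prm$max_depth <- as.integer(prm$max_depth)
  prm$k_bins <- as.integer(prm$k_bins)
  prm$min_leaf <- as.integer(prm$min_leaf)
  structure(list(trees = trees, classes = as.integer(obj$classes),
                 base_scores = as.numeric(obj$base_scores),
                 bin_edges = lapply(obj$bin_edges, as.numeric),
                 params = prm, n_features = as.integer(obj$n_features),
                 train_logloss = as.numeric(obj$train_logloss)),
            class = "lightfd_model")
}
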