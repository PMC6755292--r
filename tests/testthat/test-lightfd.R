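test_that("bin construction respects distinct values and quantiles", {
  x <- matrix(rep(c(1, 5, 9), length.out = 30), ncol = 1)
  edges <- build_bins(x, k = 255)
  expect_equal(length(edges[[1]]), 2L)           # 3 bins
  b <- bin_features(x, edges)
  expect_equal(as.vector(b), rep(c(1L, 2L, 3L), 10))

  const <- matrix(4, 20, 1)
  expect_equal(length(build_bins(const, 10)[[1]]), 0L)
  expect_true(all(bin_features(const, build_bins(const, 10)) == 1L))

  set.seed(41)
  u <- matrix(runif(10000), ncol = 1)
  edges <- build_bins(u, k = 10)
  occ <- table(bin_features(u, edges))
  # quantile edges: each of the 10 bins holds about n/10 samples
  expect_equal(length(occ), 10L)
  expect_true(all(abs(occ - 1000) / 1000 < 0.2))
  # each edge lies between the bracketing order statistics of its decile
  sorted <- sort(u[, 1])
  for (i in 1:9) {
    expect_gte(edges[[1]][i], sorted[1000 * i])
    expect_lte(edges[[1]][i], sorted[1000 * i + 1])
  }

  expect_error(build_bins(matrix(c(1, NA), 2, 1), 4), "non-finite")
})

test_that("histogram accumulation matches direct summation and conserves", {
  set.seed(42)
  n <- 500
  x <- matrix(c(rnorm(n), sample(1:8, n, TRUE) * 1.0), n, 2)
  g <- rnorm(n); h <- runif(n)
  edges <- build_bins(x, 16)
  binned <- bin_features(x, edges)
  n_bins <- lengths(edges) + 1L
  hist <- accumulate_histogram(binned, seq_len(n), g, h, n_bins)
  for (j in 1:2)
    for (b in seq_len(n_bins[j])) {
      sel <- binned[, j] == b
      expect_equal(hist$grad[b, j], sum(g[sel]), tolerance = 1e-12)
      expect_equal(hist$hess[b, j], sum(h[sel]), tolerance = 1e-12)
      expect_equal(hist$count[b, j], sum(sel))
    }
  expect_true(all(colSums(hist$count)[1:2] == n))

  # single sample: its bin carries the whole statistic
  h1 <- accumulate_histogram(binned, 7L, g, h, n_bins)
  expect_equal(sum(h1$grad), 2 * g[7], tolerance = 1e-12)  # both features

  # conservation: child histograms sum bin-wise to the parent
  left <- sample(n, 213)
  right <- setdiff(seq_len(n), left)
  hl <- accumulate_histogram(binned, left, g, h, n_bins)
  hr <- accumulate_histogram(binned, right, g, h, n_bins)
  expect_equal(hl$grad + hr$grad, hist$grad, tolerance = 1e-12)
  expect_equal(hl$hess + hr$hess, hist$hess, tolerance = 1e-12)
  expect_equal(hl$count + hr$count, hist$count)
})

test_that("split finding handles degenerate and separable nodes", {
  x <- matrix(seq_len(20) * 1.0, ncol = 1)
  edges <- build_bins(x, 255)
  binned <- bin_features(x, edges)
  nb <- lengths(edges) + 1L
  zero <- accumulate_histogram(binned, 1:20, rep(0, 20), rep(1, 20), nb)
  expect_null(best_split(zero, nb))

  # gradients perfectly separated at x = 10.5
  g <- c(rep(-1, 10), rep(1, 10))
  hist <- accumulate_histogram(binned, 1:20, g, rep(1, 20), nb)
  sp <- best_split(hist, nb, min_leaf = 1L)
  expect_equal(sp$feature, 1L)
  expect_equal(sp$bin, 10L)
})

test_that("histogram split equals the exact presorted oracle on small nodes", {
  set.seed(43)
  for (rep in 1:30) {
    n <- sample(10:64, 1)
    d <- sample(1:4, 1)
    x <- matrix(sample(seq(-3, 3, 0.5), n * d, TRUE), n, d)
    g <- rnorm(n); h <- runif(n, 0.2, 1)
    lam <- sample(c(0, 0.5), 1)
    edges <- build_bins(x, 255)           # covers all distinct values
    binned <- bin_features(x, edges)
    nb <- lengths(edges) + 1L
    got <- best_split(accumulate_histogram(binned, seq_len(n), g, h, nb),
                      nb, lambda_l2 = lam, min_leaf = 2L)
    want <- exact_best_split(x, g, h, lambda = lam, min_leaf = 2L)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(edges[[got$feature]][got$bin], want$threshold,
                   tolerance = 1e-9)
      expect_equal(got$gain, want$gain, tolerance = 1e-9)
    }
  }
})

test_that("leafwise growth obeys leaf and depth budgets", {
  set.seed(44)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3)
  g <- x[, 1] + rnorm(n, sd = 0.1); h <- rep(1, n)
  prm <- lightfd_params(min_leaf = 5L)
  edges <- build_bins(x, 64)
  binned <- bin_features(x, edges)

  one <- mindstate:::grow_tree(binned, edges, g, h,
                               lightfd_params(num_leaves = 1L, min_leaf = 5L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$weight, -sum(g) / sum(h), tolerance = 1e-12)

  shallow <- mindstate:::grow_tree(binned, edges, g, h,
                                   lightfd_params(num_leaves = 8L,
                                                  max_depth = 1L,
                                                  min_leaf = 5L))
  expect_lte(sum(shallow$is_leaf), 2L)

  deep <- mindstate:::grow_tree(binned, edges, g, h,
                                lightfd_params(num_leaves = 10L,
                                               max_depth = 3L,
                                               min_leaf = 5L))
  expect_lte(sum(deep$is_leaf), 10L)
  expect_lte(max(deep$depth), 3L)
  expect_true(all(deep$gain[!deep$is_leaf] > 0))
})

test_that("leafwise growth solves an XOR gradient pattern in 4 leaves", {
  # 2-D XOR with unequal quadrant counts (a perfectly balanced XOR gives
  # every root split zero gain and greedy growth cannot start)
  quadrant <- function(sx, sy, n) cbind(rep(sx, n), rep(sy, n))
  x <- rbind(quadrant(1, 1, 7), quadrant(-1, -1, 4),
             quadrant(1, -1, 6), quadrant(-1, 1, 5))
  g <- c(rep(1, 7), rep(1, 4), rep(-1, 6), rep(-1, 5))
  h <- rep(1, nrow(x))
  edges <- build_bins(x, 255)
  binned <- bin_features(x, edges)
  tree <- mindstate:::grow_tree(binned, edges, g, h,
                                lightfd_params(num_leaves = 4L,
                                               max_depth = 3L,
                                               min_leaf = 1L, lambda_l2 = 0))
  expect_equal(sum(tree$is_leaf), 4L)
  pred <- mindstate:::predict_tree(tree, x)
  expect_equal(pred, -g, tolerance = 1e-12)   # pure leaves: weight = -G/H

  # exhaustive oracle over axis-aligned 2-level trees: the best achievable
  # 4-leaf partition drives the within-leaf gradient variance to zero, and
  # greedy leafwise growth attains that optimum here
  thresholds <- lapply(1:2, function(j) {
    v <- sort(unique(x[, j])); (v[-length(v)] + v[-1]) / 2
  })
  part_loss <- function(root_j, root_t, lj, lt, rj, rt) {
    left <- x[, root_j] <= root_t
    grp <- ifelse(left, ifelse(x[, lj] <= lt, 1, 2),
                  ifelse(x[, rj] <= rt, 3, 4))
    sum(vapply(split(g, grp), function(v) sum((v - mean(v))^2), 0))
  }
  best <- Inf
  for (j in 1:2) for (t in thresholds[[j]])
    for (lj in 1:2) for (lt in thresholds[[lj]])
      for (rj in 1:2) for (rt in thresholds[[rj]])
        best <- min(best, part_loss(j, t, lj, lt, rj, rt))
  expect_equal(best, 0)
  expect_equal(sum((g + pred)^2), best)   # greedy matches the oracle optimum
})

test_that("an empty ensemble predicts the class priors", {
  set.seed(45)
  x <- matrix(rnorm(60), 30, 2)
  y <- c(rep(0L, 15), rep(1L, 9), rep(2L, 6))
  m <- lightfd_fit(x, y, lightfd_params(num_trees = 0L))
  p <- lightfd_predict_proba(m, x[1:5, ])
  expect_equal(unname(p[1, ]), c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_error(lightfd_fit(x, rep(0L, 30)), "2 classes")
})

test_that("boosting separates Gaussian blobs and matches a reference booster", {
  set.seed(46)
  n <- 100
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(n * 2, sd = 0.5), n, 2), 2, centers[k, ], `+`)))
  y <- rep(0:2, each = n)
  m <- lightfd_fit(x, y, lightfd_params(num_trees = 50L, min_leaf = 5L))
  expect_equal(mean(lightfd_predict(m, x) == y), 1.0)

  # independent reference: xgboost on the same data reaches the same accuracy
  d <- xgboost::xgb.DMatrix(x, label = y)
  ref <- xgboost::xgb.train(params = list(objective = "multi:softmax",
                                          num_class = 3, max_depth = 8,
                                          eta = 0.1),
                            d, nrounds = 50)
  expect_equal(mean(predict(ref, d) == y), 1.0)
})

test_that("training log-loss never increases across rounds", {
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(60:120, 1)
    d <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(0:2, n, replace = TRUE,
                prob = runif(3, 0.2, 1))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    m <- lightfd_fit(x, y, lightfd_params(num_trees = 15L, min_leaf = 5L))
    expect_true(all(diff(m$train_logloss) <= 1e-10))
  }
})

test_that("models are deterministic and serialize losslessly", {
  set.seed(48)
  x <- matrix(rnorm(300), 100, 3)
  y <- sample(0:2, 100, replace = TRUE)
  m1 <- lightfd_fit(x, y, lightfd_params(num_trees = 10L, min_leaf = 5L))
  m2 <- lightfd_fit(x, y, lightfd_params(num_trees = 10L, min_leaf = 5L))
  expect_identical(lightfd_save(m1), lightfd_save(m2))

  path <- withr::local_tempfile(fileext = ".json")
  lightfd_save(m1, path)
  m3 <- lightfd_load(path)
  xt <- matrix(rnorm(60), 20, 3)
  expect_identical(lightfd_predict_proba(m1, xt),
                   lightfd_predict_proba(m3, xt))
})

test_that("score accumulation equals per-tree traversal", {
  set.seed(49)
  x <- matrix(rnorm(200), 50, 4)
  y <- sample(0:1, 50, replace = TRUE)
  m <- lightfd_fit(x, y, lightfd_params(num_trees = 5L, min_leaf = 5L))
  xt <- matrix(rnorm(40), 10, 4)
  # naive traversal oracle, one sample and one tree at a time
  walk <- function(tree, row) {
    node <- 1L
    while (!tree$is_leaf[node])
      node <- if (row[tree$feature[node]] <= tree$threshold[node])
        tree$left[node] else tree$right[node]
    tree$weight[node]
  }
  scores <- matrix(m$base_scores, 10, 2, byrow = TRUE)
  for (rt in m$trees)
    for (k in 1:2)
      for (i in 1:10)
        scores[i, k] <- scores[i, k] +
          m$params$learning_rate * walk(rt[[k]], xt[i, ])
  p <- exp(scores) / rowSums(exp(scores))
  expect_equal(unname(lightfd_predict_proba(m, xt)), unname(p),
               tolerance = 1e-12)
  expect_error(lightfd_predict_proba(m, xt[, 1:2]), "features")
})

test_that("leafwise beats or ties levelwise at equal leaf budget", {
  # levelwise comparator: split every splittable leaf of the current depth
  levelwise_loss <- function(x, y, depth, min_leaf = 2L) {
    edges <- build_bins(x, 255)
    binned <- bin_features(x, edges)
    nb <- lengths(edges) + 1L
    p0 <- mean(y)
    g <- rep(p0, length(y)) - y
    h <- rep(p0 * (1 - p0), length(y))
    frontier <- list(seq_along(y))
    for (d_ in seq_len(depth)) {
      nxt <- list()
      for (idx in frontier) {
        sp <- if (length(idx) >= 2L * min_leaf)
          best_split(accumulate_histogram(binned, idx, g, h, nb), nb,
                     min_leaf = min_leaf) else NULL
        if (is.null(sp)) { nxt[[length(nxt) + 1L]] <- idx; next }
        go <- binned[idx, sp$feature] <= sp$bin
        nxt[[length(nxt) + 1L]] <- idx[go]
        nxt[[length(nxt) + 1L]] <- idx[!go]
      }
      frontier <- nxt
    }
    sum(vapply(frontier, function(idx)
      sum((g[idx] - mean(g[idx]))^2), 0))
  }
  set.seed(50)
  for (rep in 1:20) {
    n <- 80
    x <- matrix(rnorm(n * 3), n, 3)
    y <- as.numeric(x[, 1] * x[, 2] > 0)
    depth <- 3L
    edges <- build_bins(x, 255)
    binned <- bin_features(x, edges)
    p0 <- mean(y)
    g <- rep(p0, n) - y
    h <- rep(p0 * (1 - p0), n)
    tree <- mindstate:::grow_tree(binned, edges, g, h,
                                  lightfd_params(num_leaves = 2L^depth,
                                                 max_depth = 16L,
                                                 min_leaf = 2L))
    leaves <- which(tree$is_leaf)
    # squared-error proxy of training loss over leaf partitions
    assign_leaf <- function(row) {
      node <- 1L
      while (!tree$is_leaf[node])
        node <- if (row[tree$feature[node]] <= tree$threshold[node])
          tree$left[node] else tree$right[node]
      node
    }
    part <- vapply(seq_len(n), function(i) assign_leaf(x[i, ]), 0L)
    leaf_loss <- sum(vapply(split(seq_len(n), part), function(idx)
      sum((g[idx] - mean(g[idx]))^2), 0))
    expect_lte(leaf_loss, levelwise_loss(x, y, depth) + 1e-9)
  }
})
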