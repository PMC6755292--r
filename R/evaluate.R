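# Evaluation protocols: intra-subject 80/20 splits, pooled inter-subject
# split, and leave-subjects-out transfer. Every protocol fits the spatial
# projection, feature bins and classifier on training epochs only.

#' Pipeline factory: triclass CSP + LightFD
#'
#' Returns a factory producing fresh fit/predict pipelines. Each pipeline
#' fits the triclass CSP projection on its training epochs, extracts
#' per-component variance features, trains the boosted-tree classifier, and
#' predicts labels for new epochs through the same (frozen) projection.
#'
#' @param params classifier parameters from [lightfd_params()].
#' @param n_pairs optional filter-pair retention for the CSP step.
#' @param contrast CSP contrast mode, see [csp_triclass()].
#' @return A function of no arguments returning a list with `fit(epochs)`
#'   and `predict(epochs)` closures (`fit` returns the pipeline invisibly;
#'   `predict` returns integer labels).
#' @export
csp_lightfd_pipeline <- function(params = lightfd_params(), n_pairs = NULL,
                                 contrast = "rest") {
  force(params); force(n_pairs); force(contrast)
  function() {
    proj <- NULL; model <- NULL
    self <- list(
      fit = function(epochs) {
        proj <<- csp_triclass(epochs, contrast = contrast, n_pairs = n_pairs)
        feats <- epoch_features(proj, epochs)
        model <<- lightfd_fit(feats, attr(feats, "labels"), params)
        invisible(self)
      },
      predict = function(epochs) {
        if (is.null(model)) stop("pipeline not fitted")
        lightfd_predict(model, epoch_features(proj, epochs))
      },
      state = function() list(projection = proj, model = model))
    self
  }
}

# Stratified train/test index split: per class, round(test_fraction * n_c)
# test epochs (at least 1), so the train:test ratio is 4:1 up to rounding at
# the default fraction.
stratified_split <- function(labels, test_fraction = 0.2) {
  test_idx <- integer(0)
  for (c_ in sort(unique(labels))) {
    idx <- which(labels == c_)
    n_test <- max(1L, round(test_fraction * length(idx)))
    if (n_test >= length(idx))
      stop("class ", c_, " too small to split (", length(idx), " epochs)")
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(labels), test_idx), test = sort(test_idx))
}

accuracy_stats <- function(truth, predicted, classes = 0:2) {
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  per_class <- diag(cm) / pmax(rowSums(cm), 1L)
  list(accuracy = sum(diag(cm)) / sum(cm),
       per_class = stats::setNames(as.numeric(per_class),
                                   as.character(classes)),
       confusion = unclass(cm))
}

pop_var <- function(x) mean((x - mean(x))^2)

new_eval_report <- function(protocol, unit_acc, per_class, confusion,
                            seed, extra = list()) {
  structure(c(list(protocol = protocol,
                   unit_accuracies = unit_acc,
                   mean_accuracy = mean(unit_acc),
                   var_accuracy = pop_var(unit_acc),
                   per_class_accuracy = per_class,
                   confusion = confusion,
                   seed = seed), extra),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> protocol=%s  mean accuracy %.4f (var %.6f over %d units)\n",
              x$protocol, x$mean_accuracy, x$var_accuracy,
              length(x$unit_accuracies)))
  cat("  per-class accuracy:",
      paste(names(x$per_class_accuracy),
            sprintf("%.4f", x$per_class_accuracy), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}

#' Intra-subject evaluation (per-subject 80/20 splits)
#'
#' For every subject independently: a stratified-by-class random 80/20
#' split (train:test 4:1 per class up to rounding), pipeline fit on the
#' training split only, accuracy scored on the held-out split. Reports the
#' per-subject accuracies, their mean, and their population variance — the
#' across-subject stability measure. With `n_repeats > 1` the whole
#' procedure re-splits and the per-repeat means are averaged.
#'
#' @param study a `synthetic_study` or named list of per-subject
#'   [eeg_epochs()].
#' @param pipeline_factory factory from [csp_lightfd_pipeline()] (or any
#'   function returning a `fit`/`predict` pair).
#' @param seed integer seed controlling the random splits.
#' @param n_repeats number of independent re-splits (default 1).
#' @param test_fraction held-out fraction (default 0.2).
#' @return An `eval_report` with per-subject accuracies (averaged over
#'   repeats), mean, variance, pooled per-class accuracies and confusion
#'   matrix.
#' @export
intra_subject_eval <- function(study, pipeline_factory = csp_lightfd_pipeline(),
                               seed = 1L, n_repeats = 1L,
                               test_fraction = 0.2) {
  subjects <- study_subjects(study)
  set.seed(seed)
  acc <- matrix(NA_real_, length(subjects), n_repeats,
                dimnames = list(names(subjects), NULL))
  cm_total <- matrix(0, 3L, 3L, dimnames = list(0:2, 0:2))
  kept <- character(0)
  for (sid in names(subjects)) {
    ep <- subjects[[sid]]
    if (length(unique(ep$labels)) < 3L ||
        min(table(ep$labels)) < 5L) {
      warning("subject ", sid, " lacks enough epochs per class; excluded")
      next
    }
    kept <- c(kept, sid)
    for (r in seq_len(n_repeats)) {
      sp <- stratified_split(ep$labels, test_fraction)
      pl <- pipeline_factory()
      pl$fit(ep[sp$train])
      pred <- pl$predict(ep[sp$test])
      st <- accuracy_stats(ep$labels[sp$test], pred)
      acc[sid, r] <- st$accuracy
      cm_total <- cm_total + st$confusion
    }
  }
  if (!length(kept)) stop("no subject had enough epochs to evaluate")
  unit <- rowMeans(acc[kept, , drop = FALSE])
  per_class <- diag(cm_total) / pmax(rowSums(cm_total), 1L)
  new_eval_report("intra", unit, per_class, cm_total, seed,
                  list(n_repeats = n_repeats, excluded = setdiff(names(subjects), kept)))
}

#' Inter-subject evaluation (pooled 80/20 split)
#'
#' Pools every subject's epochs, draws a single stratified 80/20 split,
#' fits the pipeline on the training side and reports overall and per-class
#' accuracy on the held-out 20%.
#'
#' @inheritParams intra_subject_eval
#' @return An `eval_report` (one unit accuracy: the pooled split).
#' @export
inter_subject_eval <- function(study, pipeline_factory = csp_lightfd_pipeline(),
                               seed = 1L, test_fraction = 0.2) {
  subjects <- study_subjects(study)
  pooled <- bind_epochs(subjects)
  set.seed(seed)
  sp <- stratified_split(pooled$labels, test_fraction)
  pl <- pipeline_factory()
  pl$fit(pooled[sp$train])
  pred <- pl$predict(pooled[sp$test])
  st <- accuracy_stats(pooled$labels[sp$test], pred)
  new_eval_report("inter", st$accuracy, st$per_class, st$confusion, seed,
                  list(n_train = length(sp$train), n_test = length(sp$test)))
}

#' Leave-subjects-out transfer evaluation
#'
#' Fits the entire pipeline (CSP projection included) on the training
#' subjects only and scores on subjects never seen during training. Either
#' give a fixed `held_out` schedule (list of subject-id vectors, one per
#' fold — e.g. `list("s10")` for a single train-on-s1..s9 / test-on-s10
#' fold) or ask for `n_folds` random folds of `held_out_size` subjects each.
#'
#' @inheritParams intra_subject_eval
#' @param held_out list of character vectors of held-out subject ids (one
#'   element per fold); overrides `n_folds`.
#' @param n_folds number of random folds (default 10).
#' @param held_out_size subjects held out per random fold (default 2).
#' @return An `eval_report` with per-fold accuracies, mean and variance.
#' @export
transfer_eval <- function(study, pipeline_factory = csp_lightfd_pipeline(),
                          held_out = NULL, n_folds = 10L, held_out_size = 2L,
                          seed = 1L) {
  subjects <- study_subjects(study)
  ids <- names(subjects)
  set.seed(seed)
  if (is.null(held_out)) {
    if (held_out_size >= length(ids))
      stop("held_out_size must leave at least one training subject")
    held_out <- lapply(seq_len(n_folds), function(i)
      sample(ids, held_out_size))
  } else {
    held_out <- lapply(held_out, as.character)
  }
  acc <- numeric(length(held_out))
  cm_total <- matrix(0, 3L, 3L, dimnames = list(0:2, 0:2))
  for (f in seq_along(held_out)) {
    ho <- held_out[[f]]
    if (!all(ho %in% ids)) stop("unknown held-out subject(s): ",
                                paste(setdiff(ho, ids), collapse = ", "))
    tr_ids <- setdiff(ids, ho)
    if (!length(tr_ids)) stop("held-out set leaves no training subjects")
    train <- bind_epochs(subjects[tr_ids])
    test <- bind_epochs(subjects[ho])
    if (length(unique(train$labels)) < 3L)
      stop("held-out set exhausts a class in the training data")
    pl <- pipeline_factory()
    pl$fit(train)
    pred <- pl$predict(test)
    st <- accuracy_stats(test$labels, pred)
    acc[f] <- st$accuracy
    cm_total <- cm_total + st$confusion
  }
  per_class <- diag(cm_total) / pmax(rowSums(cm_total), 1L)
  new_eval_report("transfer", acc, per_class, cm_total, seed,
                  list(held_out = held_out))
}

study_subjects <- function(study) {
  subjects <- if (inherits(study, "synthetic_study")) study$subjects else study
  if (!is.list(subjects) || !length(subjects) ||
      !all(vapply(subjects, inherits, TRUE, "eeg_epochs")))
    stop("'study' must be a synthetic_study or a named list of eeg_epochs")
  if (is.null(names(subjects)))
    names(subjects) <- paste0("s", seq_along(subjects))
  subjects
}

#' Export an evaluation report as JSON (plus confusion-matrix CSV)
#'
#' @param report an `eval_report`.
#' @param path output JSON path; a sibling `<path>_confusion.csv` is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- unclass(report)
  obj$confusion <- as.data.frame.matrix(report$confusion)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   paste0(sub("\\.json$", "", path), "_confusion.csv"))
  invisible(path)
}
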