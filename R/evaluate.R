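#' Repeated stratified 80/20 evaluation of a PLS-DA workflow
#'
#' The full evaluation loop: for each of `n_repeats` repeats the samples
#' are split 80/20 into training and test, stratified by class; the number
#' of components is chosen by 2-fold cross-validation on the training split
#' only; the model is fitted and scored on the held-out test split; test
#' metrics and the model's VIP profile are recorded. Per-repeat seeds are
#' derived from the master seed by fixed offsets, so the whole summary is
#' reproducible bit-for-bit.
#'
#' Stratification guarantees at least one training and (class size
#' permitting) one test sample per class; a class with fewer than 2 members
#' cannot be stratified and raises an error naming it.
#'
#' @param x Numeric matrix (samples x features).
#' @param labels Class labels.
#' @param n_repeats Number of random splits (default 50).
#' @param train_fraction Training proportion (default 0.8).
#' @param max_components Cap for the component search (default 10).
#' @param seed Master seed.
#' @return List of class `plsda_evaluation`: `summary` (data.frame of
#'   per-repeat accuracy/precision/recall/f1 and chosen components),
#'   `means` (averages over repeats), `vip` (repeats x features matrix),
#'   `vip_mean`, `vip_median`, `n_repeats`, `train_fraction`, `seed`.
#' @export
repeated_evaluation <- function(x, labels, n_repeats = 50,
                                train_fraction = 0.8, max_components = 10,
                                seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  small <- table(labels) < 2
  if (any(small))
    stop("cannot stratify: class ", names(which(small))[1],
         " has fewer than 2 samples", call. = FALSE)

  p <- ncol(x)
  metrics <- data.frame(repeat_id = seq_len(n_repeats), accuracy = NA_real_,
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, n_components = NA_integer_)
  vip <- matrix(NA_real_, n_repeats, p,
                dimnames = list(NULL, colnames(x)))
  for (r in seq_len(n_repeats)) {
    seed_r <- .derive_seed(seed, 40L) + r
    set.seed(seed_r)
    test <- logical(nrow(x))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
      test[setdiff(idx, sample(idx, n_tr))] <- TRUE
    }
    a <- select_n_components(x[!test, , drop = FALSE], labels[!test],
                             max_components, n_folds = 2, seed = seed_r + 1L)
    m <- fit_plsda(x[!test, , drop = FALSE], labels[!test], a)
    pr <- predict(m, x[test, , drop = FALSE])
    conf <- table(factor(labels[test], levels(labels)),
                  factor(pr, levels(labels)))
    cm <- classification_metrics(conf)
    metrics[r, -1] <- c(cm$accuracy, cm$precision, cm$recall, cm$f1, a)
    vip[r, ] <- vip_scores(m)
  }
  structure(list(
    summary = metrics,
    means = colMeans(metrics[, c("accuracy", "precision", "recall", "f1")]),
    vip = vip, vip_mean = colMeans(vip),
    vip_median = apply(vip, 2, stats::median),
    n_repeats = n_repeats, train_fraction = train_fraction, seed = seed
  ), class = "plsda_evaluation")
}

#' @export
print.plsda_evaluation <- function(x, ...) {
  cat("PLS-DA repeated evaluation: ", x$n_repeats, " stratified ",
      round(100 * x$train_fraction), "/", round(100 * (1 - x$train_fraction)),
      " splits\n", sep = "")
  cat(sprintf("  mean accuracy %.3f, precision %.3f, recall %.3f, f1 %.3f\n",
              x$means["accuracy"], x$means["precision"], x$means["recall"],
              x$means["f1"]))
  invisible(x)
}

#' Select features by VIP across repeated models
#'
#' Refinement rule for the second-stage model: keep the features whose VIP
#' mean AND median over the repeated models are both strictly greater
#' than 1 (features carrying more than their share of the projection).
#'
#' @param evaluation A `plsda_evaluation`, or a list with `vip_mean` and
#'   `vip_median` vectors.
#' @return Integer vector of selected feature indices (named when the
#'   features are named). An empty selection is an error suggesting the
#'   thresholds be reviewed.
#' @export
refine_by_vip <- function(evaluation) {
  vm <- evaluation$vip_mean
  vd <- evaluation$vip_median
  sel <- which(vm > 1 & vd > 1)
  if (length(sel) == 0)
    stop("no feature has VIP mean and median > 1; review the VIP thresholds",
         call. = FALSE)
  sel
}

#' Pooled one-vs-rest ROC over the repeated test splits
#'
#' Re-runs the repeated splits with a fixed feature subset, collecting the
#' held-out continuous class score of `positive_class` for every test
#' sample, and pools them into a single ROC curve — the
#' reduced-to-binary view (positive class against the rest) of the
#' multi-class model.
#'
#' @param x,labels,n_repeats,train_fraction,max_components,seed As in
#'   [repeated_evaluation()].
#' @param features Column indices to keep (e.g. from [refine_by_vip()]).
#' @param positive_class Class treated as positive (default `"FL"`).
#' @return A `roc_curve` (see [roc_auc()]), with the pooled scores/truth
#'   attached as attributes.
#' @export
pooled_roc <- function(x, labels, features = seq_len(ncol(x)),
                       positive_class = "FL", n_repeats = 50,
                       train_fraction = 0.8, max_components = 10, seed = 1) {
  x <- as.matrix(x)[, features, drop = FALSE]
  labels <- factor(labels)
  stopifnot(positive_class %in% levels(labels))
  all_scores <- numeric(0); all_truth <- logical(0)
  for (r in seq_len(n_repeats)) {
    seed_r <- .derive_seed(seed, 60L) + r
    set.seed(seed_r)
    test <- logical(nrow(x))
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- min(length(idx) - 1L, max(1L, round(train_fraction * length(idx))))
      test[setdiff(idx, sample(idx, n_tr))] <- TRUE
    }
    a <- select_n_components(x[!test, , drop = FALSE], labels[!test],
                             max_components, n_folds = 2, seed = seed_r + 1L)
    m <- fit_plsda(x[!test, , drop = FALSE], labels[!test], a)
    sc <- predict(m, x[test, , drop = FALSE], type = "score")
    all_scores <- c(all_scores, sc[, positive_class])
    all_truth <- c(all_truth, labels[test] == positive_class)
  }
  out <- roc_auc(all_scores, all_truth)
  attr(out, "scores") <- all_scores
  attr(out, "truth") <- all_truth
  attr(out, "positive_class") <- positive_class
  out
}
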