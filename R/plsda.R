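#' Fit a PLS-DA model
#'
#' Partial least squares discriminant analysis: class labels are one-hot
#' encoded into an indicator matrix Y, X is mean-centred and unit-variance
#' scaled (zero-variance columns get unit scale and hence zero weight), Y
#' is centred, and a PLS2 latent-variable decomposition is extracted by
#' NIPALS. Prediction projects new samples through the regression
#' coefficients `B = W (P'W)^-1 Q'` and assigns the class with the largest
#' continuous class score.
#'
#' @param x Numeric matrix (samples x variables).
#' @param labels Factor or character vector of class labels, length
#'   `nrow(x)`; at least 2 classes.
#' @param n_components Number of latent components; capped with a warning
#'   at `min(n_samples - 1, n_variables)`.
#' @param tol NIPALS convergence tolerance on the X-scores (default 1e-10).
#' @param max_iter NIPALS iteration cap per component (default 500).
#' @return Object of class `plsda_model` with `x_weights` (W), `x_loadings`
#'   (P), `x_scores` (T, mutually orthogonal columns), `y_loadings` (Q),
#'   `coefficients` (variables x classes), `ssy` (Y-variance captured per
#'   component), `class_order`, and the centring/scaling vectors.
#' @export
fit_plsda <- function(x, labels, n_components = 2, tol = 1e-10,
                      max_iter = 500) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  if (length(labels) != nrow(x)) stop("one label per row required", call. = FALSE)
  n <- nrow(x); p <- ncol(x); q <- nlevels(labels)
  cap <- min(n - 1, p)
  if (n_components > cap) {
    warning("n_components reduced to ", cap)
    n_components <- cap
  }
  a_max <- n_components

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  e <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  y <- stats::model.matrix(~ labels - 1)
  colnames(y) <- levels(labels)
  ybar <- colMeans(y)
  f <- sweep(y, 2, ybar)

  w_mat <- matrix(0, p, a_max); p_mat <- matrix(0, p, a_max)
  t_mat <- matrix(0, n, a_max); q_mat <- matrix(0, q, a_max)
  ssy <- numeric(a_max)
  for (a in seq_len(a_max)) {
    u <- f[, which.max(colSums(f^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(e, u)
      w <- w / sqrt(sum(w^2))
      tt <- e %*% w
      qq <- crossprod(f, tt) / sum(tt^2)
      u <- f %*% qq / sum(qq^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    pp <- crossprod(e, tt) / sum(tt^2)
    e <- e - tt %*% t(pp)
    f <- f - tt %*% t(qq)
    w_mat[, a] <- w; p_mat[, a] <- pp
    t_mat[, a] <- tt; q_mat[, a] <- qq
    ssy[a] <- sum(tt^2) * sum(qq^2)
  }
  rot <- w_mat %*% solve(crossprod(p_mat, w_mat))
  coef <- rot %*% t(q_mat)
  dimnames(coef) <- list(colnames(x), levels(labels))
  structure(list(
    n_components = a_max, x_weights = w_mat, x_loadings = p_mat,
    x_scores = t_mat, y_loadings = q_mat, coefficients = coef, ssy = ssy,
    class_order = levels(labels), center = ctr, scale = scl, y_mean = ybar
  ), class = "plsda_model")
}

#' Predict from a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Numeric matrix with the training variables.
#' @param type `"class"` (default) for hard labels, `"score"` for the
#'   continuous per-class scores, `"latent"` for projected X-scores.
#' @param ... Unused.
#' @return Factor of classes, or a numeric matrix.
#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "score", "latent"),
                                ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  if (type == "latent")
    return(xs %*% object$x_weights %*%
             solve(crossprod(object$x_loadings, object$x_weights)))
  sc <- sweep(xs %*% object$coefficients, 2, object$y_mean, "+")
  if (type == "score") return(sc)
  factor(object$class_order[max.col(sc, ties.method = "first")],
         levels = object$class_order)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP scores:
#' `VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a )`
#' where `p` is the number of variables and `SSY_a` the Y-variance
#' explained by component `a`. By construction the mean of the squared VIPs
#' over variables is exactly 1 for every fitted model.
#'
#' @param model A `plsda_model`.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  w <- model$x_weights
  w2 <- sweep(w^2, 2, colSums(w^2), "/")
  p <- nrow(w)
  v <- sqrt(p * as.vector(w2 %*% model$ssy) / sum(model$ssy))
  names(v) <- rownames(model$coefficients)
  v
}

#' Choose the number of PLS-DA components by 2-fold cross-validation
#'
#' Stratified 2-fold cross-validated misclassification error is computed
#' for 1..`max_components` components; the smallest component count
#' attaining the minimum error is returned (ties always resolve to the
#' simpler model). Classes with fewer members than folds stay in the
#' training half of every fold and are flagged with a message.
#'
#' @param x Numeric matrix.
#' @param labels Class labels.
#' @param max_components Largest component count tried (default 10).
#' @param n_folds Folds (default 2).
#' @param seed Integer seed controlling the fold assignment.
#' @return Integer component count.
#' @export
select_n_components <- function(x, labels, max_components = 10, n_folds = 2,
                                seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(x)
  fold <- integer(n)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_folds) {
      message("class ", cl, " has fewer members than folds; kept in training")
      fold[idx] <- 0L
    } else {
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  }
  cap <- min(max_components,
             min(vapply(seq_len(n_folds), function(k) sum(fold != k), 0L)) - 1,
             ncol(x))
  cap <- max(cap, 1)
  err <- vapply(seq_len(cap), function(a) {
    bad <- 0L; tot <- 0L
    for (k in seq_len(n_folds)) {
      te <- fold == k
      if (!any(te)) next
      if (nlevels(droplevels(labels[!te])) < 2) next
      m <- fit_plsda(x[!te, , drop = FALSE], labels[!te], a)
      pr <- predict(m, x[te, , drop = FALSE])
      bad <- bad + sum(pr != labels[te]); tot <- tot + sum(te)
    }
    bad / max(tot, 1)
  }, 0)
  which.min(err)  # first index attaining the minimum = smallest k
}

#' ROC curve and AUC from continuous scores
#'
#' Threshold sweep over the unique scores (descending); the curve starts at
#' (0, 0), ends at (1, 1), and the area under it is computed by the
#' trapezoid rule, which for a score-rank sweep equals the Mann-Whitney
#' rank statistic formulation.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Logical/0-1 vector; `TRUE` = positive class. Both classes
#'   must be present.
#' @return Object of class `roc_curve`: `fpr`, `tpr` (monotone), `auc`,
#'   `thresholds`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- truth[ord]
  npos <- sum(y); nneg <- sum(!y)
  keep <- c(diff(s) != 0, TRUE)  # collapse tied scores into one operating point
  tpr <- c(0, cumsum(y)[keep] / npos)
  fpr <- c(0, cumsum(!y)[keep] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 thresholds = c(Inf, s[keep])),
            class = "roc_curve")
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total; precision, recall and F1 are
#' macro-averaged over classes. A class never predicted (or never present)
#' would divide by zero; its metric is set to 0 and the class is flagged in
#' the `zero_division` attribute.
#'
#' @param confusion Square class x class count matrix, rows = truth,
#'   columns = predicted.
#' @return Named list `accuracy`, `precision`, `recall`, `f1` (macro), plus
#'   per-class vectors.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(confusion)
  pred <- colSums(confusion); truth <- rowSums(confusion)
  prec <- ifelse(pred > 0, tp / pred, 0)
  rec <- ifelse(truth > 0, tp / truth, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  out <- list(accuracy = sum(tp) / total,
              precision = mean(prec), recall = mean(rec), f1 = mean(f1),
              per_class = data.frame(class = rownames(confusion) %||%
                                       as.character(seq_along(tp)),
                                     precision = prec, recall = rec, f1 = f1))
  attr(out, "zero_division") <- (pred == 0) | (truth == 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
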