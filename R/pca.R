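#' PCA exploration of a feature table
#'
#' Principal component analysis on mean-centred, unit-variance-scaled data
#' via [stats::prcomp()]. Zero-variance columns are given unit scale (so
#' they contribute nothing rather than dividing by zero). Component signs
#' follow a deterministic convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param x Numeric matrix or data.frame of numeric columns (samples x
#'   variables).
#' @param center,scale Centre / scale the columns (default both TRUE,
#'   matching the standard chemometric treatment of mixed-unit variables).
#' @return List of class `pca_result`: `scores` (samples x components),
#'   `loadings` (variables x components, orthonormal columns),
#'   `explained_variance_ratio`.
#' @export
pca_explore <- function(x, center = TRUE, scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 samples and 2 variables", call. = FALSE)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr,
                 center = ctr, scale = scl),
            class = "pca_result")
}

#' Variables contributing most to the leading principal components
#'
#' Ranks variables by the magnitude of their loadings on the first
#' `n_components` components (weighted by explained variance) and returns
#' those above `cutoff` times the maximum — the "important contributors"
#' that downstream group testing focuses on.
#'
#' @param pca A `pca_result`.
#' @param n_components Components considered (default 2).
#' @param cutoff Fraction of the top weighted-loading magnitude (default
#'   0.5).
#' @return Character vector of variable names, most important first.
#' @export
important_loadings <- function(pca, n_components = 2, cutoff = 0.5) {
  stopifnot(inherits(pca, "pca_result"))
  k <- min(n_components, ncol(pca$loadings))
  w <- pca$explained_variance_ratio[seq_len(k)]
  score <- sqrt((pca$loadings[, seq_len(k), drop = FALSE]^2) %*% w)[, 1]
  sel <- score >= cutoff * max(score)
  names(sort(score[sel], decreasing = TRUE))
}
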