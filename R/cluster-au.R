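#' Ward hierarchical clustering of a sample matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `"ward.D2"`, which applies Ward's
#' rule to the distances themselves). Merge heights are non-decreasing.
#'
#' @param x Numeric matrix (samples x features); row names become leaf
#'   labels.
#' @return An `hclust` object.
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples to cluster", call. = FALSE)
  stats::hclust(stats::dist(x), method = "ward.D2")
}

# leaf index sets of every internal node of an hclust tree, in merge order
.node_leafsets <- function(hc) {
  n <- length(hc$height) + 1L
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    take <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- sort(c(take(hc$merge[i, 1]), take(hc$merge[i, 2])))
  }
  sets
}

.leafset_keys <- function(sets) vapply(sets, paste, "", collapse = ",")

# WLS fit of the multiscale-bootstrap signed distance / curvature model
# z(r) = v*sqrt(r) + c/sqrt(r), z(r) = qnorm(1 - BP_r); AU = 1 - Phi(v - c).
# Only scales with informative BP (neither 0 nor 1) constrain the two
# parameters; a node recovered in (almost) every replicate at (almost)
# every scale carries no curvature information, and its AU falls back to
# the mean bootstrap proportion (1 for fully saturated support, 0 for a
# node never recovered), flagged by fit_ok = FALSE.
.au_fit <- function(bp, scales, n_boot) {
  use <- bp > 0 & bp < 1
  if (sum(use) < 3)
    return(list(v = NA_real_, c = NA_real_, au = mean(bp), fit_ok = FALSE))
  z <- stats::qnorm(1 - bp[use])
  X <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
  w <- n_boot * stats::dnorm(z)^2 / (bp[use] * (1 - bp[use]))
  fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients)))
    return(list(v = NA_real_, c = NA_real_, au = mean(bp), fit_ok = FALSE))
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  list(v = unname(v), c = unname(cc),
       au = unname(1 - stats::pnorm(v - cc)), fit_ok = TRUE)
}

#' Multiscale bootstrap support for a Ward dendrogram
#'
#' Assesses the uncertainty of every cluster (internal node) of the Ward
#' tree by multiscale bootstrap resampling of the feature dimension, the
#' scheme pvclust uses: the clustered samples stay fixed while, for each
#' scale `r`, `n_boot` bootstrap datasets of `round(p * r)` feature columns
#' are drawn with replacement and the samples re-clustered. The bootstrap
#' probability BP of a node is the fraction of replicates whose tree
#' contains the node's exact leaf set. Across scales the normal quantiles
#' `qnorm(1 - BP_r)` are fitted by weighted least squares to
#' `v*sqrt(r) + c/sqrt(r)`, separating the signed distance `v` of the
#' cluster boundary from its curvature `c`; the approximately unbiased
#' p-value is `AU = 1 - Phi(v - c)`. BP values are clipped to
#' `[1/(2 n_boot), 1 - 1/(2 n_boot)]` before the probit transform, and the
#' WLS weights come from the binomial variance of BP.
#'
#' Resampling columns with multiplicities `cnt` changes each squared
#' Euclidean distance to `sum(cnt * (x_i - x_j)^2)`, so replicate distance
#' matrices are exact linear maps of a precomputed pair-by-feature matrix
#' of squared differences — no per-replicate matrix subsetting is needed.
#'
#' @param x Numeric matrix (samples x features).
#' @param scales Resampling-size multipliers spanning values below and
#'   above 1 (default `seq(0.5, 1.4, 0.1)`, the conventional grid).
#' @param n_boot Bootstrap replicates per scale (default 1000; >= 100
#'   required).
#' @param seed Integer seed.
#' @return Object of class `node_support`: data.frame `support` with one
#'   row per internal node (`node`, `size`, `bp` at the scale nearest 1,
#'   `au`, `v`, `c`, `fit_ok`), plus the `hclust` tree, the BP matrix
#'   (nodes x scales), `scales`, `n_boot` and `seed`.
#' @export
multiscale_bootstrap <- function(x, scales = seq(0.5, 1.4, by = 0.1),
                                 n_boot = 1000, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  if (min(scales) >= 1 || max(scales) <= 1)
    stop("scales must span values below and above 1", call. = FALSE)

  hc <- ward_cluster(x)
  sets <- .node_leafsets(hc)
  keys <- .leafset_keys(sets)
  p <- ncol(x)

  # squared per-feature differences for every sample pair, in the pair
  # order of a "dist" object (columnwise lower triangle)
  pair_i <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  pair_j <- rep(seq_len(n - 1), times = (n - 1):1)
  S <- (x[pair_i, , drop = FALSE] - x[pair_j, , drop = FALSE])^2

  set.seed(seed %% .Machine$integer.max)
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, sprintf("r%.1f", scales)))
  for (si in seq_along(scales)) {
    m <- max(2L, as.integer(round(p * scales[si])))
    hits <- numeric(length(keys))
    for (b in seq_len(n_boot)) {
      cnt <- tabulate(sample.int(p, m, replace = TRUE), nbins = p)
      dvec <- sqrt(as.vector(S %*% cnt))
      db <- structure(dvec, Size = n, Diag = FALSE, Upper = FALSE,
                      class = "dist")
      hb <- stats::hclust(db, method = "ward.D2")
      bkeys <- .leafset_keys(.node_leafsets(hb))
      hits <- hits + (keys %in% bkeys)
    }
    bp[, si] <- hits / n_boot
  }

  near1 <- which.min(abs(scales - 1))
  fits <- lapply(seq_along(keys), function(i) .au_fit(bp[i, ], scales, n_boot))
  support <- data.frame(
    node = seq_along(keys),
    size = vapply(sets, length, 0L),
    bp = bp[, near1],
    au = vapply(fits, `[[`, 0, "au"),
    v = vapply(fits, `[[`, 0, "v"),
    c = vapply(fits, `[[`, 0, "c"),
    fit_ok = vapply(fits, `[[`, TRUE, "fit_ok")
  )
  structure(list(support = support, hclust = hc, bp_matrix = bp,
                 leafsets = sets, scales = scales, n_boot = n_boot,
                 seed = seed),
            class = "node_support")
}

#' @export
print.node_support <- function(x, ...) {
  cat("Multiscale bootstrap support (", x$n_boot, " replicates x ",
      length(x$scales), " scales)\n", sep = "")
  print(format(x$support, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Stable clusters at an AU threshold
#'
#' Selects the maximal internal nodes whose approximately unbiased p-value
#' strictly exceeds `threshold` (default 0.90, the conventional cut for a
#' "true" cluster), walking the tree top-down so the reported clusters are
#' disjoint. The root (the node holding every leaf) is not a candidate.
#' Leaves not covered by any supported node are reported as singletons.
#'
#' @param support A `node_support` from [multiscale_bootstrap()].
#' @param threshold AU threshold (strict; default 0.90).
#' @return Object of class `cluster_assignment`: `assignment` (integer
#'   cluster id per leaf, supported clusters numbered first, singletons
#'   after), `n_clusters` (supported nodes selected), `n_singletons`,
#'   `nodes` (selected node ids), `threshold`.
#' @export
stable_clusters <- function(support, threshold = 0.90) {
  stopifnot(inherits(support, "node_support"))
  hc <- support$hclust
  n <- length(hc$order)
  s <- support$support
  cand <- s[s$node < n - 1L & s$au > threshold, , drop = FALSE]  # exclude root
  cand <- cand[order(-cand$size, cand$node), , drop = FALSE]
  assigned <- integer(n)
  picked <- integer(0)
  for (i in seq_len(nrow(cand))) {
    leaves <- support$leafsets[[cand$node[i]]]
    if (all(assigned[leaves] == 0)) {
      picked <- c(picked, cand$node[i])
      assigned[leaves] <- length(picked)
    }
  }
  k <- length(picked)
  singles <- which(assigned == 0)
  assigned[singles] <- k + seq_along(singles)
  names(assigned) <- hc$labels %||% as.character(seq_len(n))
  structure(list(assignment = assigned, n_clusters = k,
                 n_singletons = length(singles), nodes = picked,
                 threshold = threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(x$n_clusters, " stable cluster(s) at AU > ", x$threshold,
      if (x$n_singletons) paste0(" (+", x$n_singletons, " singleton leaves)"),
      "\n", sep = "")
  invisible(x)
}
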