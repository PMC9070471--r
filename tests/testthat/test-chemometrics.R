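test_that("PCA matches a closed-form eigendecomposition on a tiny matrix", {
  x <- matrix(c(1, 0, -1, 0, 2, -2), 3, 2)  # centred 3 x 2
  res <- pca_explore(x, center = TRUE, scale = FALSE)
  # independent oracle: eigendecomposition of the covariance matrix
  ev <- eigen(cov(x))
  expect_equal(res$explained_variance_ratio,
               ev$values / sum(ev$values), tolerance = 1e-12)
  for (j in 1:2)
    expect_equal(abs(res$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-12)
  # deterministic sign convention: top-magnitude loading positive
  for (j in seq_len(ncol(res$loadings))) {
    l <- res$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("collinear data put all variance on the first component", {
  x <- cbind(1:6, 2 * (1:6))
  res <- pca_explore(x, scale = FALSE)
  expect_equal(res$explained_variance_ratio[1], 1)
})

test_that("scaled PCA is invariant to per-column unit changes", {
  set.seed(2)
  x <- matrix(rnorm(40), 10, 4)
  res1 <- pca_explore(x)
  res2 <- pca_explore(sweep(x, 2, c(1000, 0.01, 3, 42), "*"))
  expect_equal(abs(res1$scores), abs(res2$scores), tolerance = 1e-9)
})

test_that("PLS-DA separates separable classes and handles duplication", {
  set.seed(4)
  x <- rbind(matrix(rnorm(20, 0), 5), matrix(rnorm(20, 4), 5))
  y <- rep(c("a", "b"), each = 5)
  m <- fit_plsda(x, y, 1)
  expect_equal(as.character(predict(m, x)), y)
  # duplicating every sample changes nothing material
  m2 <- fit_plsda(rbind(x, x), c(y, y), 1)
  expect_equal(predict(m2, x, type = "score"), predict(m, x, type = "score"),
               tolerance = 1e-6)
  expect_error(fit_plsda(x, rep("a", 10), 1), "2 classes")
  expect_warning(fit_plsda(x, y, 50), "reduced")
})

test_that("X-scores are mutually orthogonal", {
  set.seed(7)
  x <- matrix(rnorm(200), 20, 10)
  y <- rep(c("a", "b", "c"), length.out = 20)
  m <- fit_plsda(x, y, 4)
  g <- crossprod(m$x_scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("full-rank PLS reproduces least-squares fitted values", {
  set.seed(9)
  n <- 8; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  y <- rep(c("a", "b"), each = 4)
  m <- fit_plsda(x, y, p)  # n_components = rank(X)
  fitted_pls <- predict(m, x, type = "score")
  # oracle: ordinary least squares of the centred indicator on scaled X
  xs <- scale(x)
  yy <- stats::model.matrix(~ factor(y) - 1)
  fitted_ls <- xs %*% qr.solve(xs, scale(yy, scale = FALSE)) +
    matrix(colMeans(yy), n, 2, byrow = TRUE)
  expect_equal(unname(fitted_pls), unname(fitted_ls), tolerance = 1e-6)
})

test_that("agreement with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(2)
  n <- 18; p <- 12
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rep(c("A", "B", "C"), each = 6)
  x[y == "A", 1:3] <- x[y == "A", 1:3] + 2
  x[y == "B", 4:6] <- x[y == "B", 4:6] + 2
  m1 <- fit_plsda(x, y, 2)
  m2 <- mixOmics::plsda(x, factor(y), ncomp = 2)
  for (a in 1:2)
    expect_gt(abs(cor(m1$x_scores[, a], m2$variates$X[, a])), 1 - 1e-9)
  expect_equal(unname(vip_scores(m1)), unname(mixOmics::vip(m2)[, 2]),
               tolerance = 1e-8)
})

test_that("VIP normalization and ordering hold", {
  set.seed(5)
  x <- matrix(rnorm(300), 30, 10)
  x[, 3] <- x[, 3] + 3 * rep(c(0, 1), each = 15)  # one dominant variable
  y <- rep(c("a", "b"), each = 15)
  for (a in 1:3) {
    m <- fit_plsda(x, y, a)
    v <- vip_scores(m)
    expect_equal(mean(v^2), 1, tolerance = 1e-10)  # sum VIP^2 = p
    expect_true(all(v >= 0))
  }
  v1 <- vip_scores(fit_plsda(x, y, 2))
  expect_gt(v1[3], 1)
  expect_equal(unname(which.max(v1)), 3)
  # equal weights on every variable give VIP identically 1
  xeq <- matrix(rnorm(40), 20, 2)
  xeq[, 2] <- xeq[, 1] + rnorm(20, sd = 1e-6)
  veq <- vip_scores(fit_plsda(xeq, rep(c("a", "b"), 10), 1))
  expect_equal(unname(veq), c(1, 1), tolerance = 1e-2)
})

test_that("component selection finds a single informative direction", {
  set.seed(6)
  n <- 100
  cls <- rep(c(-1, 1), each = n / 2)
  noise <- matrix(rnorm(n * 4, sd = 0.3), n, 4)
  noise <- noise - outer(cls, colSums(noise * cls) / n)  # orthogonal to the contrast
  x <- cbind(2 * cls + rnorm(n, sd = 0.2), noise)
  y <- rep(c("a", "b"), each = n / 2)
  expect_equal(select_n_components(x, y, max_components = 5, seed = 3), 1)
  # pure-noise labels: all k tie at high error -> smallest k returned
  set.seed(8)
  xn <- matrix(rnorm(24 * 4), 24, 4)
  yn <- rep(c("a", "b"), 12)
  ks <- vapply(1:5, function(s) select_n_components(xn, yn, 4, seed = s), 0L)
  expect_true(all(ks >= 1 & ks <= 4))
  # deterministic given the seed
  expect_identical(select_n_components(x, y, 5, seed = 11),
                   select_n_components(x, y, 5, seed = 11))
})

test_that("repeated evaluation is reproducible and errors on tiny classes", {
  cfg <- cohort_config(n_fl = 4, n_fp = 4, n_tl = 4, seed = 3)
  ss <- simulate_spectrum_set(cfg, n_bins = 150)
  e1 <- repeated_evaluation(ss$spectra, ss$labels$tissue_type, n_repeats = 5,
                            seed = 2)
  e2 <- repeated_evaluation(ss$spectra, ss$labels$tissue_type, n_repeats = 5,
                            seed = 2)
  expect_identical(e1, e2)
  expect_true(all(unlist(e1$summary[, c("accuracy", "precision", "recall", "f1")]) >= 0))
  expect_true(all(unlist(e1$summary[, c("accuracy", "precision", "recall", "f1")]) <= 1))
  expect_error(repeated_evaluation(ss$spectra[1:5, ], c("a", "a", "a", "a", "b")),
               "fewer than 2")
})

test_that("VIP refinement selects planted markers and rejects the boundary", {
  cfg <- cohort_config(seed = 5)
  ss <- simulate_spectrum_set(cfg, n_bins = 300)
  ev <- repeated_evaluation(ss$spectra, ss$labels$tissue_type, n_repeats = 8,
                            seed = 4)
  sel <- refine_by_vip(ev)
  markers <- sort(unique(unlist(ss$markers$class)))
  expect_true(all(markers %in% sel))
  # all-ones VIP profile selects nothing (strict inequality) -> error path
  fake <- list(vip_mean = rep(1, 5), vip_median = rep(1, 5))
  expect_error(refine_by_vip(fake), "VIP")
  # single repeat: mean = median = that repeat
  ev1 <- repeated_evaluation(ss$spectra, ss$labels$tissue_type, n_repeats = 1,
                             seed = 4)
  expect_equal(ev1$vip_mean, ev1$vip_median)
})

test_that("ROC follows the rank statistic and matches pROC", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # random scores: AUC equals the Mann-Whitney probability (pROC oracle)
  skip_if_not_installed("pROC")
  set.seed(10)
  sc <- rnorm(40); tr <- rbinom(40, 1, 0.5)
  r2 <- roc_auc(sc, tr)
  expect_equal(r2$auc,
               as.numeric(suppressMessages(pROC::auc(tr, sc, direction = "<"))),
               tolerance = 1e-12)
  expect_true(all(diff(r2$tpr) >= 0) && all(diff(r2$fpr) >= 0))
})

test_that("metrics from a hand-computed confusion matrix", {
  conf <- matrix(c(2, 1, 0, 0, 3, 0, 1, 0, 3), 3, 3, byrow = TRUE)
  m <- classification_metrics(conf)
  expect_equal(m$accuracy, 0.8)  # trace 8 / total 10
  expect_equal(unname(m$per_class$recall), c(2/3, 1, 3/4))
  expect_equal(unname(m$per_class$precision), c(2/3, 3/4, 1))
  # diagonal confusion: everything 1
  md <- classification_metrics(diag(c(3, 4, 5)))
  expect_equal(unlist(md[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # a class never predicted gets precision 0 and is flagged
  conf2 <- matrix(c(2, 0, 2, 0, 0, 0, 0, 0, 4), 3, 3, byrow = TRUE)
  m2 <- classification_metrics(conf2)
  expect_equal(unname(m2$per_class$precision[2]), 0)
  expect_true(any(attr(m2, "zero_division")))
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})
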