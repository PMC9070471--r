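.test_result <- function(statistic, p_raw, p_adjusted, method, groups,
                         n_per_group, df = NA_real_) {
  data.frame(statistic = unname(statistic), df = df, p_raw = p_raw,
             p_adjusted = p_adjusted, method = method,
             groups = paste(groups, collapse = " vs "),
             n = paste(n_per_group, collapse = "/"),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees
#' of freedom, via [stats::kruskal.test()]. When every observation is tied
#' the tie correction degenerates; H is then 0 with p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; at least 2 non-empty groups.
#' @return One-row data.frame: `statistic` (H), `df`, `p_raw`,
#'   `p_adjusted` (= `p_raw`; no multiplicity at this stage), `method`,
#'   `groups`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0) || nlevels(droplevels(groups)) < 2)
    stop("every group needs at least one observation", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 observations", call. = FALSE)
  if (diff(range(values)) == 0) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic); p <- kt$p.value
  }
  .test_result(h, p, p, "Kruskal-Wallis", levels(groups), table(groups),
               df = nlevels(groups) - 1)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise mean-rank comparisons on the joint ranking of all groups, with
#' the tie-corrected z statistic
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`,
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided
#' p-values are adjusted across the pairwise family (Holm by default),
#' matching the usual per-variable presentation of three-group box plots.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param adjust Adjustment method passed to [stats::p.adjust()] (default
#'   `"holm"`).
#' @return Data.frame with one row per group pair: `statistic` (z),
#'   `p_raw`, `p_adjusted`, `method`, `groups`, `n`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  rk <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ns <- table(groups)
  pairs <- utils::combn(levels(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  padj <- stats::p.adjust(p, method = adjust)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j)
    .test_result(z[j], p[j], padj[j], paste0("Dunn (", adjust, ")"),
                 pairs[, j], ns[pairs[, j]])))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of
# the pooled values; U counts pairs (a > b) + 0.5 * ties
.mw_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))

.mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- min(.mw_u(x, y), .mw_u(y, x))
  prod_n <- n1 * length(y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ii) .mw_u(pooled[ii], pooled[-ii]))
  # symmetric two-sided tail around n1*n2/2
  mean(us <= u_obs | us >= prod_n - u_obs)
}

#' Mann-Whitney U test
#'
#' Reports `U = min(U_a, U_b)`. For small samples (both groups at most
#' `exact_max`) the two-sided p-value is exact, by full enumeration of the
#' `choose(n_a + n_b, n_a)` group assignments of the pooled values (ties
#' contribute half-counts to U, so tied data are handled exactly).
#' Otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return One-row data.frame: `statistic` (U), `p_raw`, `p_adjusted`
#'   (= `p_raw`), `method`, `groups`, `n`.
#' @export
mann_whitney <- function(values_a, values_b, exact_max = 8) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(values_a); n2 <- length(values_b)
  ua <- .mw_u(values_a, values_b)
  ub <- n1 * n2 - ua
  u <- min(ua, ub)
  if (max(n1, n2) <= exact_max) {
    p <- .mw_exact_p(values_a, values_b)
    method <- "Mann-Whitney (exact)"
  } else {
    N <- n1 + n2
    ties <- table(c(values_a, values_b))
    tie_corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_corr))
    z <- (abs(u - n1 * n2 / 2) - 0.5) / sigma  # continuity correction
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "Mann-Whitney (normal approx.)"
  }
  .test_result(u, p, p, method, c("a", "b"), c(n1, n2))
}

#' Holm step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th by `m - i + 1`,
#' enforces monotonicity, caps at 1 and restores the input order — i.e.
#' [stats::p.adjust()] with `method = "holm"`.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}
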