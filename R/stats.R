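#' Cohort test statistics
#'
#' Thin, contract-stable wrappers over the standard tests used at cohort
#' level — Pearson chi-squared, Fisher's exact, Wilcoxon rank sum, a
#' logistic group model and Benjamini-Hochberg FDR — plus the noncentral
#' chi-squared power function used for two-group design.
#'
#' @name cohort-stats
NULL

#' Pearson chi-squared test on a 2x2 table
#'
#' @param table 2x2 non-negative count matrix.
#' @param correction Apply Yates continuity correction (off by default).
#' @return A list: `statistic`, `p`, `degenerate` (TRUE when a margin is
#'   zero, in which case `statistic = 0`, `p = 1`).
#' @export
chi_squared_test <- function(table, correction = FALSE) {
  assert_that(all(table >= 0) && sum(table) > 0,
              "`table` must hold non-negative counts with positive total")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correction))
  list(statistic = unname(ct$statistic), p = ct$p.value, degenerate = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p as the total probability of all tables (at fixed margins) no
#' more likely than the observed one.
#'
#' @param table 2x2 non-negative count matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(table) {
  assert_that(all(table >= 0), "`table` must hold non-negative counts")
  if (sum(table) == 0) return(1)
  stats::fisher.test(table)$p.value
}

#' Wilcoxon rank-sum test with small-sample exact enumeration
#'
#' Uses mid-ranks for ties. When `n + m <= exact_max`, the two-sided p-value
#' is computed by exhaustive enumeration over all `choose(n+m, n)` group
#' assignments of the pooled values (so ties are handled exactly);
#' otherwise the normal approximation with tie correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Largest pooled size for enumeration.
#' @return A list: `statistic` (rank-sum W of `x` minus its minimum, as in
#'   Mann-Whitney U), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  assert_that(length(x) > 0 && length(y) > 0, "both samples must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n + m <= exact_max) {
    idx <- utils::combn(n + m, n)
    us <- apply(idx, 2, function(ii) sum(r[ii])) - n * (n + 1) / 2
    mu <- n * m / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p = p, method = "exact enumeration"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  list(statistic = u_obs, p = wt$p.value, method = "normal approximation")
}

#' Logistic regression of group on a covariate
#'
#' Single-covariate logistic fit with a Wald test on the slope. Perfect
#' separation is detected (fitted probabilities collapsing to 0/1) and the
#' p-value suppressed.
#'
#' @param covariate Numeric vector.
#' @param group Two-level factor/character vector aligned with `covariate`.
#' @return A list: `coefficient`, `se`, `p`, `separated`.
#' @export
logistic_group_test <- function(covariate, group) {
  g <- as.factor(group)
  assert_that(nlevels(g) == 2, "`group` must have exactly two levels")
  assert_that(min(table(g)) >= 3, "need >= 3 samples per group")
  y <- as.integer(g) - 1L
  fit <- suppressWarnings(stats::glm(y ~ covariate, family = stats::binomial()))
  co <- summary(fit)$coefficients
  eps <- 1e-8
  separated <- all(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    !fit$converged || co["covariate", "Std. Error"] > 100
  list(coefficient = unname(co["covariate", "Estimate"]),
       se = unname(co["covariate", "Std. Error"]),
       p = if (separated) NA_real_ else unname(co["covariate", "Pr(>|z|)"]),
       separated = separated)
}

#' Benjamini-Hochberg q-values
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Step-up adjusted q-values (monotone in sorted p order).
#' @export
bh_fdr <- function(pvalues) {
  assert_that(all(pvalues >= 0 & pvalues <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Power of a chi-squared test at effect size w
#'
#' Power of the df-degree chi-squared test at significance `alpha` for
#' Cohen's effect size `w` and total sample size `n_total`: the upper tail
#' of the noncentral chi-squared with noncentrality `n_total * w^2` beyond
#' the central critical value.
#'
#' @param w Cohen's w (>= 0).
#' @param alpha Significance level.
#' @param n_total Total sample size.
#' @param df Degrees of freedom.
#' @return The power (a probability).
#' @export
chi_squared_power <- function(w, alpha = 0.05, n_total, df = 1) {
  assert_that(w >= 0, "`w` must be >= 0")
  assert_that(alpha > 0 && alpha < 1, "`alpha` must be in (0, 1)")
  assert_that(n_total >= 2, "`n_total` must be >= 2")
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n_total * w^2, lower.tail = FALSE)
}
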