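#' Median difference with percentile bootstrap CI
#'
#' median(b) - median(a) with a 95% percentile bootstrap confidence interval
#' under a fixed seed.
#'
#' @param group_a,group_b numeric vectors, non-empty.
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `difference`, `ci`, `n_a`, `n_b`.
#' @export
median_difference <- function(group_a, group_b, n_boot = 1000, conf = 0.95,
                              seed = 1) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  diff_obs <- stats::median(group_b) - stats::median(group_a)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(group_b, replace = TRUE)) -
      stats::median(sample(group_a, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(difference = diff_obs,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_a = length(group_a), n_b = length(group_b))
}

#' Sample-size-weighted pooled estimate across cohorts
#'
#' pooled = sum(w_i * estimate_i) with w_i proportional to cohort size,
#' normalized to sum to 1.
#'
#' @param estimates per-cohort estimates.
#' @param sizes per-cohort sample sizes, >= 0, not all zero.
#' @return list with `pooled` and `weights`.
#' @export
weighted_meta_median <- function(estimates, sizes) {
  if (length(estimates) == 0) stop("need >= 1 cohort")
  if (length(estimates) != length(sizes)) stop("length mismatch")
  if (all(sizes == 0)) stop("all cohort sizes are zero")
  w <- sizes / sum(sizes)
  list(pooled = sum(w * estimates), weights = w)
}

#' Fisher's combined probability test
#'
#' X^2 = -2 sum(log p_i), compared with the chi-squared distribution on 2k
#' degrees of freedom (upper tail). Inputs must lie in (0, 1]; callers should
#' floor tiny p-values (e.g. at 1e-300) before combining.
#'
#' @param p vector of p-values in (0, 1].
#' @return list with `statistic` (X^2), `df`, `p`.
#' @export
fisher_combined <- function(p) {
  if (length(p) == 0) stop("no p-values")
  if (any(p <= 0) || any(p > 1))
    stop("p-values must be in (0, 1]; floor zeros before combining")
  x2 <- -2 * sum(log(p))
  list(statistic = x2, df = 2 * length(p),
       p = stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE))
}

#' Cross-cohort meta-analysis of core-gene methylation differences
#'
#' For each cohort, computes the median difference in the methylation index
#' between a risk group and the low-risk reference together with a
#' Mann-Whitney p-value, then pools differences with sample-size weights and
#' combines cohort p-values by Fisher's method (p floored at 1e-300).
#'
#' @param index methylation index values (all cohorts).
#' @param cohort cohort label per subject.
#' @param risk risk group label per subject.
#' @param risk_group the contrasted risk level (e.g. "very_high").
#' @param reference the reference risk level (default "low").
#' @param seed seed for the bootstrap CIs.
#' @return list of class `MetaResult`: `per_cohort` data.frame, `pooled`,
#'   `weights`, `fisher` (statistic/df/p).
#' @export
meta_analyze_cohorts <- function(index, cohort, risk, risk_group,
                                 reference = "low", seed = 1) {
  cohort <- as.character(cohort); risk <- as.character(risk)
  rows <- list()
  for (co in unique(cohort)) {
    a <- index[cohort == co & risk == reference]
    b <- index[cohort == co & risk == risk_group]
    if (length(a) == 0 || length(b) == 0) next
    md <- median_difference(a, b, seed = seed)
    mw <- mann_whitney_u(b, a)
    rows[[co]] <- data.frame(cohort = co, n = length(a) + length(b),
                             median_difference = md$difference,
                             ci_lo = md$ci[1], ci_hi = md$ci[2], p = mw$p)
  }
  if (length(rows) == 0) stop("no cohort has both risk groups")
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  pooled <- weighted_meta_median(per$median_difference, per$n)
  fc <- fisher_combined(pmax(per$p, 1e-300))
  structure(list(per_cohort = per, pooled = pooled$pooled,
                 weights = pooled$weights, fisher = fc),
            class = "MetaResult")
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf("MetaResult: pooled median difference %.3f%%, Fisher X2 = %.2f (df %d), p = %.3g\n",
              x$pooled, x$fisher$statistic, x$fisher$df, x$fisher$p))
  print(x$per_cohort)
  invisible(x)
}
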