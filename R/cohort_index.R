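#' Combined core-gene methylation index by PCA loadings
#'
#' Column-centers the subject x gene percentage matrix, takes the first
#' principal-component loadings (unit norm, sign fixed so the loading sum is
#' non-negative), forms the loading-weighted gene sum per subject on the raw
#' percentages, and rescales so the reference group's mean index is exactly
#' 100%. Subjects with any missing core gene are excluded (complete case).
#' A constant matrix (PC1 undefined) falls back to equal weights with a
#' warning.
#'
#' @param meth subject x gene matrix (or data.frame) of methylation
#'   percentages in [0, 100].
#' @param groups group label per subject.
#' @param reference reference group label whose mean is pinned to 100%.
#' @return list of class `MethylationIndex`: `index` (% per retained subject),
#'   `weights`, `kept` (row indices used), `reference`.
#' @export
combine_core_genes <- function(meth, groups, reference) {
  meth <- as.matrix(meth)
  groups <- as.character(groups)
  keep <- stats::complete.cases(meth)
  meth <- meth[keep, , drop = FALSE]
  groups <- groups[keep]
  if (nrow(meth) < 2) stop("need >= 2 complete-case subjects")
  if (!reference %in% groups) stop("reference group is empty")

  xc <- sweep(meth, 2, colMeans(meth))
  sv <- svd(xc)
  if (sv$d[1] < 1e-10) {
    warning("constant methylation matrix: PC1 undefined, using equal weights")
    w <- rep(1 / sqrt(ncol(meth)), ncol(meth))
  } else {
    w <- sv$v[, 1]
    if (sum(w) < 0) w <- -w
  }
  raw <- drop(meth %*% w)
  ref_mean <- mean(raw[groups == reference])
  if (abs(ref_mean) < 1e-12) stop("reference group mean index is zero")
  structure(list(index = raw * (100 / ref_mean), weights = w,
                 kept = which(keep), reference = reference, groups = groups),
            class = "MethylationIndex")
}

#' @export
print.MethylationIndex <- function(x, ...) {
  cat(sprintf("MethylationIndex: %d subjects, reference '%s' (mean 100%%)\n",
              length(x$index), x$reference))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Mann-Whitney U test with midrank ties
#'
#' U statistic with midrank tie handling. Exact p-value by complete
#' enumeration of group assignments when n1 + n2 <= 20 (two-sided: the
#' proportion of assignments at least as far from the null mean n1*n2/2 as
#' observed); tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors for the two groups.
#' @return list with `U` (for `x`), `p` and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty group")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 20) {
    vals <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    rr <- rank(vals)
    us <- apply(combs, 2, function(ix) sum(rr[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    nt <- table(r)
    tie_term <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}

#' Group-wise Mann-Whitney contrasts against a reference group
#'
#' Compares the methylation index of each non-reference group with the
#' reference group.
#'
#' @param index numeric values (e.g. `MethylationIndex$index`).
#' @param groups group label per value.
#' @param reference reference group label.
#' @return data.frame per contrasted group: n, median, `U`, `p`, `method`.
#' @export
group_compare_mannwhitney <- function(index, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) stop("empty reference group")
  ref <- index[groups == reference]
  others <- setdiff(unique(groups), reference)
  rows <- lapply(others, function(g) {
    v <- index[groups == g]
    r <- mann_whitney_u(v, ref)
    data.frame(group = g, n = length(v), median = stats::median(v),
               U = r$U, p = r$p, method = r$method)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "reference_median") <- stats::median(ref)
  out
}

#' Pearson correlation of the index with a clinical covariate
#'
#' Product-moment correlation with the t-distribution p-value
#' (t = r sqrt((n-2)/(1-r^2)) on n-2 df) and the least-squares fitted line.
#'
#' @param index,covariate numeric vectors of equal length, n >= 3, finite.
#' @return list with `r`, `p`, `slope`, `intercept`, `n`.
#' @export
correlate_covariate <- function(index, covariate) {
  ok <- is.finite(index) & is.finite(covariate)
  x <- covariate[ok]; y <- index[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  slope <- sxy / sum((x - mean(x))^2)
  list(r = r, p = p, slope = slope, intercept = mean(y) - slope * mean(x),
       n = n)
}

#' Convert HbA1c between NGSP percent and IFCC mmol/mol
#'
#' Standard linear relation: mmol/mol = 10.929 * (% - 2.15).
#'
#' @param value numeric HbA1c value(s).
#' @param from unit of `value`: "percent" or "mmol_mol".
#' @return converted value(s).
#' @export
convert_hba1c <- function(value, from = c("percent", "mmol_mol")) {
  from <- match.arg(from)
  if (from == "percent") 10.929 * (value - 2.15)
  else value / 10.929 + 2.15
}
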