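#' log-CPM normalization of region counts
#'
#' Counts-per-million on the per-sample library size, log2 with a pseudocount:
#' `log2(count / library_size * 1e6 + pseudocount)`.
#'
#' @param x RegionCountMatrix.
#' @param pseudocount positive offset added before the log (default 0.5).
#' @return numeric matrix of the same shape as `x$counts`.
#' @export
normalize_log_cpm <- function(x, pseudocount = 0.5) {
  stopifnot(inherits(x, "RegionCountMatrix"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(x$library_sizes <= 0)) stop("zero library size")
  cpm <- sweep(x$counts, 2, x$library_sizes / 1e6, "/")
  log2(cpm + pseudocount)
}

# Scale counts toward a common library size (arithmetic mean), rounding to
# integers. The exact test conditions on group sums of these pseudo-counts.
equalize_counts <- function(x) {
  target <- mean(x$library_sizes)
  round(sweep(x$counts, 2, target / x$library_sizes, "*"))
}

#' Pooled method-of-moments NB dispersion
#'
#' Estimates a common negative-binomial dispersion phi (Var = mu + phi mu^2)
#' by pooling within-group means and variances over all regions on
#' library-size-equalized counts, clipped at zero.
#'
#' @param x RegionCountMatrix with at least 2 samples in every group.
#' @return scalar dispersion estimate, >= 0.
#' @export
estimate_dispersion <- function(x) {
  stopifnot(inherits(x, "RegionCountMatrix"))
  grp <- x$design$group
  if (any(table(grp) < 2)) stop("need >= 2 samples per group")
  eq <- equalize_counts(x)
  num <- 0; den <- 0
  for (g in levels(grp)) {
    sub <- eq[, grp == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Negative-binomial exact test for two groups
#'
#' Conditional exact test on the two group sums of library-size-equalized
#' counts. Each group sum is NB with mean n_g * m and size n_g / phi (the sum
#' of n_g i.i.d. NB(m, phi) variables); conditioning on the overall total, the
#' two-sided p-value is the probability mass of all splits no more probable
#' than the observed one. At phi = 0 this is the Poisson-conditional binomial
#' exact test.
#'
#' @param counts_a,counts_b non-negative integer vectors (equalized counts).
#' @param phi common NB dispersion, >= 0.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_a, counts_b, phi) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (length(phi) != 1 || is.na(phi) || phi < 0) stop("phi must be >= 0")
  n1 <- length(counts_a); n2 <- length(counts_b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  nb_exact_test_sums(sum(counts_a), sum(counts_b), n1, n2, phi)
}

# Exact test on pre-computed group sums (internal fast path for call_dmrs).
nb_exact_test_sums <- function(sa, sb, n1, n2, phi) {
  total <- sa + sb
  if (total == 0) return(1)
  x <- 0:total
  if (phi < 1e-12) {
    pr <- stats::dbinom(x, total, n1 / (n1 + n2))
  } else {
    m <- total / (n1 + n2)
    pa <- stats::dnbinom(x, size = n1 / phi, mu = n1 * m)
    pb <- stats::dnbinom(total - x, size = n2 / phi, mu = n2 * m)
    pr <- pa * pb
    pr <- pr / sum(pr)
  }
  pobs <- pr[sa + 1]
  # tolerance-padded tie inclusion keeps the two-sided sum deterministic
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

#' Residualize log-CPM on adjustment covariates
#'
#' Per-region least-squares residuals of log-CPM on every design column except
#' `group` (plus an intercept). Group-mean differences are preserved in
#' expectation because group labels are excluded from the regression.
#'
#' @param log_cpm regions x samples matrix (from [normalize_log_cpm]).
#' @param design design data.frame with a `group` column and covariates.
#' @return residual matrix, same shape.
#' @export
adjust_covariates <- function(log_cpm, design) {
  covars <- design[, setdiff(names(design), "group"), drop = FALSE]
  keep <- vapply(covars, function(z) length(unique(z)) > 1, logical(1))
  covars <- covars[, keep, drop = FALSE]
  if (ncol(covars) == 0) {
    mm <- matrix(1, nrow(design), 1)
  } else {
    mm <- stats::model.matrix(~ ., data = covars)
  }
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm))
    stop("covariate matrix is rank deficient (collinear covariates)")
  t(qr.resid(qr_mm, t(log_cpm)))
}

#' Call differentially methylated regions across all pairwise contrasts
#'
#' Runs the NB exact test for every pairwise group contrast (4 groups give 6
#' contrasts) on library-size-equalized counts with a common pooled
#' dispersion. A region is a DMR when its case-vs-control p-value falls below
#' `alpha` for at least one case group. Direction (hypo/hyper in cases)
#' follows the sign of the log2 fold difference versus the control group, and
#' each DMR gets a cluster label from its pattern of significant calls:
#' hypomethylation private to one case group (`hypo_<group>`), hypermethylation
#' in every case group (`hyper_all`), or `other`.
#'
#' @param x RegionCountMatrix (first group level is the control/reference
#'   unless `control` is given).
#' @param alpha significance threshold on the raw p-value, in (0,1);
#'   default 0.01.
#' @param control control group label; default first level of the design.
#' @param phi optional dispersion; estimated from `x` when NULL.
#' @return data.frame with region coordinates, per-contrast raw p-values and
#'   BH q-values, case-vs-control log2 fold differences, `direction`,
#'   `significant` and `cluster`.
#' @export
call_dmrs <- function(x, alpha = 0.01, control = NULL, phi = NULL) {
  stopifnot(inherits(x, "RegionCountMatrix"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  grp <- x$design$group
  labs <- levels(grp)
  if (length(labs) < 2) stop("need >= 2 groups")
  if (is.null(control)) control <- labs[1]
  if (!control %in% labs) stop("unknown control group")
  cases <- setdiff(labs, control)
  if (is.null(phi)) phi <- estimate_dispersion(x)

  eq <- equalize_counts(x)
  gsum <- vapply(labs, function(g) rowSums(eq[, grp == g, drop = FALSE]),
                 numeric(nrow(eq)))
  gsum <- matrix(gsum, nrow = nrow(eq), dimnames = list(NULL, labs))
  n_per <- table(grp)[labs]

  out <- x$regions
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  pvals <- list()
  # memoize p-values by (sa, sb) within a contrast: many regions share totals
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    sa <- gsum[, a]; sb <- gsum[, b]
    key <- paste(sa, sb)
    uk <- !duplicated(key)
    pu <- mapply(nb_exact_test_sums, sa[uk], sb[uk],
                 MoreArgs = list(n1 = n_per[[a]], n2 = n_per[[b]], phi = phi))
    p <- pu[match(key, key[uk])]
    pvals[[paste(a, b, sep = "|")]] <- p
    pvals[[paste(b, a, sep = "|")]] <- p
    out[[paste0("p_", a, "_vs_", b)]] <- p
    out[[paste0("q_", a, "_vs_", b)]] <- stats::p.adjust(p, "BH")
  }

  sig_hypo <- sig_hyper <- matrix(FALSE, nrow(eq), length(cases),
                                  dimnames = list(NULL, cases))
  for (g in cases) {
    p <- pvals[[paste(control, g, sep = "|")]]
    lfc <- log2((gsum[, g] / n_per[[g]] + 0.5) /
                (gsum[, control] / n_per[[control]] + 0.5))
    out[[paste0("logfc_", g)]] <- lfc
    sig <- if (alpha >= 1) rep(TRUE, length(p)) else p < alpha
    sig_hypo[, g] <- sig & lfc < 0
    sig_hyper[, g] <- sig & lfc >= 0
  }
  out$significant <- rowSums(sig_hypo) + rowSums(sig_hyper) > 0
  out$direction <- ifelse(rowSums(sig_hypo) > 0, "hypo",
                          ifelse(rowSums(sig_hyper) > 0, "hyper", "none"))

  cl <- rep(NA_character_, nrow(eq))
  hyper_all <- rowSums(sig_hyper) == length(cases)
  cl[out$significant] <- "other"
  # hypo clusters take the worst (latest-listed) significant case group,
  # mirroring the private-hypomethylation categories
  for (g in cases) cl[sig_hypo[, g]] <- paste0("hypo_", g)
  cl[hyper_all] <- "hyper_all"
  out$cluster <- cl
  attr(out, "alpha") <- alpha
  attr(out, "phi") <- phi
  attr(out, "control") <- control
  out
}

#' Hierarchical clustering of DMR profiles
#'
#' Agglomerative clustering of region profiles with distance 1 - Pearson
#' correlation and average linkage, cut at `k` clusters. Zero-variance
#' profiles have undefined correlation; their distances are set to 1 by
#' convention, with a warning.
#'
#' @param profiles numeric matrix, regions x groups (or samples).
#' @param k number of clusters, >= 2.
#' @return list with `labels` (integer cluster per region) and `hclust`.
#' @export
cluster_dmr_profiles <- function(profiles, k) {
  profiles <- as.matrix(profiles)
  if (k < 2) stop("k must be >= 2")
  if (nrow(profiles) < k) stop("need at least k profiles")
  cc <- suppressWarnings(stats::cor(t(profiles)))
  if (anyNA(cc)) {
    warning("zero-variance profile(s): correlation undefined, distance set to 1")
    cc[is.na(cc)] <- 0
  }
  d <- 1 - cc
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(labels = stats::cutree(hc, k = k), hclust = hc)
}

#' Sample-level PCA of adjusted log-CPM
#'
#' Column-centered SVD of the samples x regions matrix. Scores are the left
#' singular vectors scaled by singular values; component signs are fixed so
#' every component's loading sum is non-negative.
#'
#' @param mat regions x samples matrix (adjusted log-CPM).
#' @param n_components number of components to keep (default all).
#' @return list with `scores` (samples x k), `loadings` (regions x k),
#'   `sdev`, and `var_explained`.
#' @export
sample_pca <- function(mat, n_components = NULL) {
  x <- t(as.matrix(mat))              # samples x regions
  if (nrow(x) < 3) stop("need >= 3 samples")
  if (all(x == 0)) stop("all-zero matrix")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  k <- if (is.null(n_components)) length(sv$d) else min(n_components, length(sv$d))
  sgn <- ifelse(colSums(sv$v[, seq_len(k), drop = FALSE]) < 0, -1, 1)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k),
                  2, sgn, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, sgn, "*")
  list(scores = scores, loadings = loadings,
       sdev = sv$d / sqrt(max(1, nrow(x) - 1)),
       var_explained = sv$d^2 / sum(sv$d^2))
}
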