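# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and its IRanges backing): plain arithmetic and convolution only.

# NB exact test oracle: the group-sum distributions are built by repeated
# per-sample convolution of NB(mu = m, size = 1/phi) pmfs (Poisson at phi=0),
# truncated at the observed total; the two-sided p is the normalized mass of
# all splits no more probable than the observed one.
oracle_nb_exact <- function(counts_a, counts_b, phi) {
  n1 <- length(counts_a); n2 <- length(counts_b)
  total <- sum(counts_a) + sum(counts_b)
  if (total == 0) return(1)
  m <- total / (n1 + n2)
  pmf1 <- if (phi == 0) dpois(0:total, m) else
    dnbinom(0:total, size = 1 / phi, mu = m)
  conv_n <- function(n) {
    out <- pmf1
    if (n > 1) for (i in 2:n) {
      full <- convolve(out, rev(pmf1), type = "open")
      out <- full[1:(total + 1)]
    }
    out
  }
  pa <- conv_n(n1); pb <- conv_n(n2)
  x <- 0:total
  joint <- pa[x + 1] * pb[total - x + 1]
  joint <- joint / sum(joint)
  pobs <- joint[sum(counts_a) + 1]
  min(1, sum(joint[joint <= pobs * (1 + 1e-12)]))
}

# linear-scan region classifier (no interval index)
oracle_classify <- function(regions, genes, exons, cgis, promoter_window) {
  mid <- floor((regions$start + regions$end) / 2)
  point_dist <- function(p, s, e) {
    # distance to nearest covered base of [s, e)
    if (length(s) == 0) return(Inf)
    min(pmax(s - p, p - e + 1, 0))
  }
  n <- length(mid)
  cpg <- gene <- character(n)
  for (i in seq_len(n)) {
    d <- point_dist(mid[i], cgis$start, cgis$end)
    cpg[i] <- if (d == 0) "CGI" else if (d <= 1000) "shore" else
      if (d <= 5000) "shelf" else "open_sea"
    if (is.null(genes) || nrow(genes) == 0) { gene[i] <- "intergenic"; next }
    tssd <- min(abs(mid[i] - genes$tss))
    in_gene <- any(genes$start <= mid[i] & mid[i] < genes$end)
    in_exon <- !is.null(exons) && nrow(exons) > 0 &&
      any(exons$start <= mid[i] & mid[i] < exons$end)
    gene[i] <- if (tssd <= promoter_window) "promoter" else
      if (in_exon && in_gene) "exon" else if (in_gene) "intron" else
        "intergenic"
  }
  prec <- c("CGI", "shore", "shelf", "promoter", "exon", "intron", "intergenic")
  primary <- ifelse(cpg != "open_sea", cpg, gene)
  data.frame(gene_context = gene, cpg_context = cpg,
             primary = factor(primary, levels = prec))
}

# O(n*m) all-pairs probe-to-DMR distances
oracle_probe_dist <- function(pos, dmrs) {
  vapply(pos, function(p)
    min(pmax(dmrs$start - p, p - dmrs$end + 1, 0)), numeric(1))
}

# per-base coverage fraction of a region by a set of intervals
oracle_coverage_frac <- function(s, e, tf_start, tf_end) {
  bases <- s:(e - 1)
  covered <- vapply(bases, function(b)
    any(tf_start <= b & b < tf_end), logical(1))
  mean(covered)
}

# O(n^2) pair-counting AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# chi-squared survival function with even df = 2k, closed form:
# P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!
oracle_chisq_sf_even <- function(x, df) {
  k <- df / 2
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# independently typed CKD-EPI 2009 creatinine equation
oracle_ckd_epi <- function(scr, age, female) {
  k <- if (female) 0.7 else 0.9
  a <- if (female) -0.329 else -0.411
  egfr <- 141 * min(scr / k, 1)^a * max(scr / k, 1)^(-1.209) * 0.993^age
  if (female) egfr * 1.018 else egfr
}

# the published KDIGO G x A risk heatmap, transcribed independently
oracle_kdigo <- data.frame(
  g = rep(c("G1", "G2", "G3a", "G3b", "G4", "G5"), each = 3),
  a = rep(c("A1", "A2", "A3"), 6),
  risk = c("low", "moderate", "high",
           "low", "moderate", "high",
           "moderate", "high", "very_high",
           "high", "very_high", "very_high",
           "very_high", "very_high", "very_high",
           "very_high", "very_high", "very_high"))

# elementwise log-CPM arithmetic, written out longhand
oracle_log_cpm <- function(counts, lib, pseudo) {
  out <- counts * NA_real_
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts)))
    out[i, j] <- log2(counts[i, j] / lib[j] * 1e6 + pseudo)
  out
}

# small helpers used across tests
toy_matrix <- function(n_regions = 50, n_per_group = 4,
                       groups = c("healthy", "Normo"), seed = 42,
                       dispersion = 0.1, ...) {
  cfg <- region_sim_config(n_regions = n_regions, n_per_group = n_per_group,
                           group_labels = groups, dispersion = dispersion,
                           seed = seed, ...)
  simulate_region_counts(cfg)
}
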