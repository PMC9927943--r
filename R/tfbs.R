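#' Fractional TFBS coverage of DMRs
#'
#' For each DMR, computes the fraction of its length covered by the merged
#' union of a factor's binding-site intervals (no double counting of
#' overlapping sites), and flags the DMR as overlapping when the fraction
#' reaches `min_frac` (inclusive threshold).
#'
#' @param dmrs data.frame chrom/start/end (0-based half-open).
#' @param tfbs data.frame chrom/start/end of one factor's intervals.
#' @param min_frac coverage threshold in (0, 1]; default 0.5.
#' @return data.frame with `covered_bp`, `fraction` and logical `overlap`.
#' @export
overlap_fraction <- function(dmrs, tfbs, min_frac = 0.5) {
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  len <- dmrs$end - dmrs$start
  if (any(len <= 0)) stop("zero-length DMR")
  covered <- rep(0L, nrow(dmrs))
  if (!is.null(tfbs) && nrow(tfbs) > 0) {
    dgr <- .gr(dmrs)
    tgr <- GenomicRanges::reduce(.gr(tfbs))
    hits <- GenomicRanges::findOverlaps(dgr, tgr)
    if (length(hits) > 0) {
      pint <- IRanges::pintersect(dgr[S4Vectors::queryHits(hits)],
                                  tgr[S4Vectors::subjectHits(hits)])
      bp <- tapply(GenomicRanges::width(pint), S4Vectors::queryHits(hits), sum)
      covered[as.integer(names(bp))] <- as.integer(bp)
    }
  }
  frac <- covered / len
  data.frame(covered_bp = covered, fraction = frac,
             overlap = frac >= min_frac)
}

#' Odds-ratio test for TFBS over-representation among hypo- vs hyper-DMRs
#'
#' Builds the 2x2 table (hypo/hyper x overlap/no-overlap), computes the odds
#' ratio with the Haldane-Anscombe +0.5 correction applied only when a cell is
#' zero, a two-sided Fisher exact p-value (sum of hypergeometric probabilities
#' no larger than the observed one, at fixed margins), and a 95% CI from the
#' log-OR normal approximation.
#'
#' @param hypo_overlap logical vector: overlap flags for hypo-DMRs.
#' @param hyper_overlap logical vector: overlap flags for hyper-DMRs.
#' @param factor_label optional label carried into the result.
#' @return list of class `EnrichmentResult`: `table`, `odds_ratio`, `p`,
#'   `ci`, per-class overlap fractions.
#' @export
tfbs_odds_ratio_test <- function(hypo_overlap, hyper_overlap,
                                 factor_label = NA_character_) {
  if (length(hypo_overlap) == 0 || length(hyper_overlap) == 0)
    stop("both DMR classes must be non-empty")
  a <- sum(hypo_overlap); b <- sum(!hypo_overlap)
  cc <- sum(hyper_overlap); d <- sum(!hyper_overlap)
  tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                dimnames = list(c("hypo", "hyper"),
                                c("overlap", "no_overlap")))
  corr <- if (any(tab == 0)) 0.5 else 0
  or <- ((a + corr) * (d + corr)) / ((b + corr) * (cc + corr))
  se <- sqrt(1 / (a + corr) + 1 / (b + corr) +
             1 / (cc + corr) + 1 / (d + corr))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- fisher_exact_2x2(a, b, cc, d)
  structure(list(factor = factor_label, table = tab, odds_ratio = or,
                 p = p, ci = ci,
                 frac_hypo = a / (a + b), frac_hyper = cc / (cc + d)),
            class = "EnrichmentResult")
}

# two-sided Fisher exact p for a 2x2 table with rows (a,b), (c,d)
fisher_exact_2x2 <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  x <- lo:hi
  pr <- stats::dhyper(x, m1, m2, k)
  pobs <- stats::dhyper(a, m1, m2, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("TFBS enrichment%s: OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              if (is.na(x$factor)) "" else paste0(" [", x$factor, "]"),
              x$odds_ratio, x$ci[1], x$ci[2], x$p))
  print(x$table)
  invisible(x)
}

#' Per-factor TFBS enrichment scan over called DMRs
#'
#' Applies [overlap_fraction()] and [tfbs_odds_ratio_test()] for every factor
#' in the bundle, contrasting hypomethylated against hypermethylated DMRs,
#' and returns the per-factor overlap fractions for scatter plotting.
#'
#' @param dmrs DMR data.frame with a `direction` column (`hypo`/`hyper`).
#' @param bundle AnnotationBundle with a non-empty `tfbs` list.
#' @param min_frac coverage threshold (default 0.5).
#' @return data.frame, one row per factor: 2x2 cells, fractions, OR, p, CI,
#'   and `testable`; full `EnrichmentResult`s in attribute `results`.
#' @export
enrichment_scan <- function(dmrs, bundle, min_frac = 0.5) {
  stopifnot(inherits(bundle, "AnnotationBundle"))
  if (length(bundle$tfbs) == 0) stop("need >= 1 TFBS factor")
  hypo <- dmrs[dmrs$direction == "hypo", , drop = FALSE]
  hyper <- dmrs[dmrs$direction == "hyper", , drop = FALSE]
  if (nrow(hypo) == 0 || nrow(hyper) == 0)
    stop("both hypo and hyper DMR classes must be non-empty")
  res <- list(); rows <- list()
  for (f in names(bundle$tfbs)) {
    tf <- bundle$tfbs[[f]]
    if (is.null(tf) || nrow(tf) == 0) {
      rows[[f]] <- data.frame(factor = f, a = 0, b = nrow(hypo), c = 0,
                              d = nrow(hyper), frac_hypo = 0, frac_hyper = 0,
                              odds_ratio = NA_real_, p = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              testable = FALSE)
      next
    }
    ov_hypo <- overlap_fraction(hypo, tf, min_frac)$overlap
    ov_hyper <- overlap_fraction(hyper, tf, min_frac)$overlap
    r <- tfbs_odds_ratio_test(ov_hypo, ov_hyper, f)
    res[[f]] <- r
    rows[[f]] <- data.frame(factor = f, a = r$table[1, 1], b = r$table[1, 2],
                            c = r$table[2, 1], d = r$table[2, 2],
                            frac_hypo = r$frac_hypo, frac_hyper = r$frac_hyper,
                            odds_ratio = r$odds_ratio, p = r$p,
                            ci_lo = r$ci[1], ci_hi = r$ci[2], testable = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- res
  out
}
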