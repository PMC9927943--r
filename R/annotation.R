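#' Bundle of annotation interval tracks
#'
#' Holds the feature tracks used for region classification and enrichment:
#' genes (with strand and TSS), exon sub-intervals, CpG islands, array probe
#' positions and per-factor TFBS interval sets. All coordinates are 0-based
#' half-open.
#'
#' @param genes data.frame chrom/start/end/name/strand (TSS derived: start for
#'   `+`, end-1 for `-`), or NULL.
#' @param exons data.frame chrom/start/end/name (name = parent gene), or NULL.
#' @param cpg_islands data.frame chrom/start/end, or NULL.
#' @param probes data.frame chrom/pos/probe_id, or NULL.
#' @param tfbs named list of data.frames chrom/start/end, one per factor.
#' @param promoter_window TSS +/- window (bp) defining promoters;
#'   default 2000.
#' @return object of class `AnnotationBundle`.
#' @export
annotation_bundle <- function(genes = NULL, exons = NULL, cpg_islands = NULL,
                              probes = NULL, tfbs = list(),
                              promoter_window = 2000) {
  chk <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(df)
    if (any(df$start >= df$end))
      stop(sprintf("%s: start must be < end (row %d)", what,
                   which(df$start >= df$end)[1]))
    df
  }
  genes <- chk(genes, "genes"); exons <- chk(exons, "exons")
  cpg_islands <- chk(cpg_islands, "cpg_islands")
  for (f in names(tfbs)) tfbs[[f]] <- chk(tfbs[[f]], paste0("tfbs:", f))
  if (!is.null(genes) && nrow(genes) > 0) {
    if (is.null(genes$strand)) genes$strand <- "+"
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  }
  structure(list(genes = genes, exons = exons, cpg_islands = cpg_islands,
                 probes = probes, tfbs = tfbs,
                 promoter_window = promoter_window),
            class = "AnnotationBundle")
}

#' @export
print.AnnotationBundle <- function(x, ...) {
  n <- function(df) if (is.null(df)) 0 else nrow(df)
  cat(sprintf(
    "AnnotationBundle: %d genes, %d exons, %d CpG islands, %d probes, %d TFBS factors\n",
    n(x$genes), n(x$exons), n(x$cpg_islands), n(x$probes), length(x$tfbs)))
  invisible(x)
}

.gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
.gr_point <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
}

# distance (bp) from 0-based points to the nearest covered base of any
# interval in df: 0 iff inside, 1 for the base immediately flanking, Inf if
# the track is empty
.dist_to_track <- function(chrom, pos, df) {
  out <- rep(Inf, length(pos))
  if (is.null(df) || nrow(df) == 0) return(out)
  pts <- .gr_point(chrom, pos)
  hit <- .gr(df)
  inside <- GenomicRanges::countOverlaps(pts, hit) > 0
  dtn <- GenomicRanges::distanceToNearest(pts, hit)
  out[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance + 1
  out[inside] <- 0
  out
}

#' Classify regions by gene context and CpG context
#'
#' CpG context from the region midpoint: `CGI` when inside an island, `shore`
#' within 1 kb of an island edge, `shelf` within 1-5 kb, else `open_sea`
#' (distances measured to the nearest island edge; a position qualifying for
#' two islands takes the nearer class). Gene context: `promoter` when the
#' midpoint lies within the TSS window, else `exon`, `intron`, `intergenic`.
#' The primary label follows the precedence
#' CGI > shore > shelf > promoter > exon > intron > intergenic.
#'
#' @param regions data.frame chrom/start/end.
#' @param bundle AnnotationBundle.
#' @return data.frame with `gene_context`, `cpg_context` and `primary`.
#' @export
classify_region <- function(regions, bundle) {
  stopifnot(inherits(bundle, "AnnotationBundle"))
  mid <- floor((regions$start + regions$end) / 2)
  chrom <- regions$chrom
  known <- unique(unlist(lapply(
    list(bundle$genes, bundle$exons, bundle$cpg_islands),
    function(df) if (is.null(df)) character() else unique(df$chrom))))
  if (length(known) > 0 && !all(chrom %in% known))
    stop("unknown contig: ", setdiff(chrom, known)[1])

  d_cgi <- .dist_to_track(chrom, mid, bundle$cpg_islands)
  cpg <- ifelse(d_cgi == 0, "CGI",
         ifelse(d_cgi <= 1000, "shore",
         ifelse(d_cgi <= 5000, "shelf", "open_sea")))

  gene_context <- rep("intergenic", length(mid))
  if (!is.null(bundle$genes) && nrow(bundle$genes) > 0) {
    tss <- bundle$genes$tss
    d_tss <- vapply(mid, function(p) min(abs(p - tss)), numeric(1))
    in_gene <- .dist_to_track(chrom, mid, bundle$genes) == 0
    in_exon <- .dist_to_track(chrom, mid, bundle$exons) == 0
    gene_context[in_gene] <- "intron"
    gene_context[in_exon & in_gene] <- "exon"
    gene_context[d_tss <= bundle$promoter_window] <- "promoter"
  }
  prec <- c("CGI", "shore", "shelf", "promoter", "exon", "intron", "intergenic")
  primary <- ifelse(cpg != "open_sea", cpg, gene_context)
  data.frame(gene_context = gene_context, cpg_context = cpg,
             primary = factor(primary, levels = prec), stringsAsFactors = FALSE)
}

#' Signed TSS-distance histogram for DMRs
#'
#' Distance from each DMR midpoint to its nearest TSS, strand-reflected so
#' that upstream is negative. Distances beyond `max_distance` are excluded
#' from the histogram and counted separately.
#'
#' @param dmrs data.frame chrom/start/end.
#' @param genes data.frame with `strand` and either `tss` or start/end.
#' @param bin_width histogram bin width in bp.
#' @param max_distance half-range of the histogram in bp.
#' @return list with `breaks`, `counts`, `mids` and `excluded`.
#' @export
tss_distance_profile <- function(dmrs, genes, bin_width = 1000,
                                 max_distance = 10000) {
  if (is.null(genes) || nrow(genes) == 0) stop("no genes")
  if (is.null(genes$tss))
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  signed <- vapply(mid, function(p) {
    i <- which.min(abs(p - genes$tss))
    (p - genes$tss[i]) * (if (genes$strand[i] == "+") 1 else -1)
  }, numeric(1))
  keep <- abs(signed) <= max_distance
  breaks <- seq(-max_distance, max_distance, by = bin_width)
  if (breaks[length(breaks)] < max_distance) breaks <- c(breaks, max_distance)
  h <- hist(signed[keep], breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids,
       excluded = sum(!keep), distances = signed)
}

#' Cumulative probe counts within distance windows of DMRs
#'
#' For each window `w`, counts probes whose distance to the nearest DMR is at
#' most `w`; distance 0 means the probe position lies inside a DMR
#' (half-open). Counts are cumulative, hence non-decreasing in `w`.
#'
#' @param probes data.frame chrom/pos (0-based positions).
#' @param dmrs data.frame chrom/start/end.
#' @param windows non-negative distances in bp, sorted ascending.
#' @return named integer vector of counts, one per window.
#' @export
probe_proximity <- function(probes, dmrs, windows = c(0, 10000, 100000)) {
  if (any(windows < 0)) stop("negative window")
  if (is.unsorted(windows)) stop("windows must be sorted ascending")
  d <- .dist_to_track(probes$chrom, probes$pos,
                      dmrs[, c("chrom", "start", "end")])
  counts <- vapply(windows, function(w) sum(d <= w), integer(1))
  names(counts) <- paste0("within_", windows, "bp")
  counts
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric p-value per gene set against a gene universe,
#' with Benjamini-Hochberg q-values across sets.
#'
#' @param selected character vector of selected genes (subset of universe).
#' @param universe character vector of all testable genes.
#' @param gene_sets named list of character vectors.
#' @param fdr enrichment threshold on q (default 0.05).
#' @return data.frame with set name, sizes, overlap, `p`, `q`, `enriched`.
#' @export
geneset_enrichment <- function(selected, universe, gene_sets, fdr = 0.05) {
  selected <- unique(selected); universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("selected gene absent from universe: ",
         setdiff(selected, universe)[1])
  if (any(lengths(gene_sets) == 0)) stop("gene sets must be non-empty")
  N <- length(universe); n <- length(selected)
  res <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    K <- length(set); k <- length(intersect(set, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, set_size = K, overlap = k, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out$enriched <- out$q < fdr
  out
}
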