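#' Region-level methylation count matrix
#'
#' Container for methyl-capture sequencing abundance summarised over genomic
#' regions: an integer matrix of regions x samples, per-sample library sizes,
#' and a sample design table holding the group label and the adjustment
#' covariates (age, sex, cell-fraction estimates, library cluster
#' concentration).
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `region_id`.
#' @param counts integer matrix, regions x samples; non-negative.
#' @param library_sizes numeric vector of per-sample totals, all positive.
#' @param design data.frame, one row per sample, with a `group` column
#'   (factor or character) plus any numeric/binary covariates.
#' @return An object of class `RegionCountMatrix`.
#' @export
region_count_matrix <- function(regions, counts, library_sizes, design) {
  counts <- as.matrix(counts)
  stopifnot(is.data.frame(regions), is.data.frame(design))
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  if (nrow(regions) != nrow(counts))
    stop("nrow(regions) must equal nrow(counts)")
  if (ncol(counts) != nrow(design))
    stop("design rows must match count columns")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(regions$start >= regions$end)) stop("regions must satisfy start < end")
  if (!"group" %in% names(design)) stop("design must contain a 'group' column")
  if (is.null(regions$region_id))
    regions$region_id <- sprintf("region_%05d", seq_len(nrow(regions)))
  design$group <- if (is.factor(design$group)) droplevels(design$group)
                  else factor(design$group, levels = unique(design$group))
  structure(
    list(regions = regions, counts = counts,
         library_sizes = as.numeric(library_sizes), design = design),
    class = "RegionCountMatrix")
}

#' @export
print.RegionCountMatrix <- function(x, ...) {
  cat(sprintf("RegionCountMatrix: %d regions x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:", paste(sprintf("%s (n=%d)", levels(x$design$group),
                               table(x$design$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.RegionCountMatrix <- function(x) dim(x$counts)

group_labels <- function(x) levels(x$design$group)

#' Subset a RegionCountMatrix by regions and/or samples
#'
#' @param x RegionCountMatrix.
#' @param i region index. @param j sample index.
#' @param ... unused.
#' @export
`[.RegionCountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  region_count_matrix(x$regions[i, , drop = FALSE],
                      x$counts[i, j, drop = FALSE],
                      x$library_sizes[j],
                      x$design[j, , drop = FALSE])
}
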