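# On-disk formats: tab-separated UTF-8 with '#'-prefixed provenance/header
# lines, BED6 for interval tracks, JSON for truth tables and summaries.
# All genomic coordinates are 0-based half-open on disk and in memory.

prov_lines <- function(seed = NA) {
  c(sprintf("# dnmeth %s", as.character(utils::packageVersion("dnmeth"))),
    sprintf("# seed: %s", seed))
}

write_tsv_prov <- function(df, path, seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(prov_lines(seed), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    mat <- vapply(df, function(col) {
      s <- as.character(col); s[is.na(s)] <- ""; s
    }, character(nrow(df)))
    mat <- matrix(mat, nrow = nrow(df))
    writeLines(apply(mat, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

read_tsv_prov <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = "#", na.strings = ""))
}

#' Write / read a region count matrix as TSV
#'
#' Layout: chrom, start, end, region_id, then one integer column per sample.
#' Library sizes and the design table travel in sidecar files
#' (`<stem>.design.tsv`).
#'
#' @param x RegionCountMatrix.
#' @param path output TSV path (design written next to it).
#' @param seed provenance seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_region_counts <- function(x, path, seed = NA) {
  stopifnot(inherits(x, "RegionCountMatrix"))
  df <- cbind(x$regions[, c("chrom", "start", "end", "region_id")],
              as.data.frame(x$counts))
  write_tsv_prov(df, path, seed)
  des <- cbind(sample = colnames(x$counts), x$design,
               library_size = x$library_sizes)
  write_tsv_prov(des, sub("\\.tsv$", ".design.tsv", path), seed)
  invisible(path)
}

#' @rdname write_region_counts
#' @export
read_region_counts <- function(path) {
  df <- read_tsv_prov(path)
  des <- read_tsv_prov(sub("\\.tsv$", ".design.tsv", path))
  meta_cols <- c("chrom", "start", "end", "region_id")
  counts <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  design <- des[, setdiff(names(des), c("sample", "library_size")),
                drop = FALSE]
  region_count_matrix(df[, meta_cols], counts, des$library_size, design)
}

#' Write / read BED6 interval tracks
#'
#' Columns: chrom, start, end, name, score, strand. `read_bed` validates
#' start < end and names the offending line on failure.
#'
#' @param df data.frame with chrom/start/end and optional name/score/strand.
#' @param path file path.
#' @return `path` (writer) or a data.frame (reader).
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if (is.null(df$name)) "." else df$name,
                    score = if (is.null(df$score)) 0 else df$score,
                    strand = if (is.null(df$strand)) "." else df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand")[1:6],
                          fill = TRUE, stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad) > 0)
    stop(sprintf("malformed BED: start >= end at line %d of %s",
                 bad[1], path))
  df
}

#' Write / read a clinical cohort table (with follow-up series)
#'
#' The subject-level table goes to `<path>`; the longitudinal eGFR series to
#' `<stem>.followup.tsv`.
#'
#' @param cohort list with `cohort` and `followup` data.frames (as returned
#'   by [simulate_cohort()]), or a plain subject data.frame.
#' @param path output TSV path.
#' @param seed provenance seed.
#' @return `path` (writer) or a list with `cohort` and `followup` (reader).
#' @export
write_cohort <- function(cohort, path, seed = NA) {
  if (is.data.frame(cohort)) cohort <- list(cohort = cohort, followup = NULL)
  write_tsv_prov(cohort$cohort, path, seed)
  if (!is.null(cohort$followup))
    write_tsv_prov(cohort$followup, sub("\\.tsv$", ".followup.tsv", path),
                   seed)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  fu_path <- sub("\\.tsv$", ".followup.tsv", path)
  list(cohort = read_tsv_prov(path),
       followup = if (file.exists(fu_path)) read_tsv_prov(fu_path) else NULL)
}

#' Write a truth table or result summary as JSON
#'
#' @param x list or data.frame.
#' @param path output path.
#' @param seed provenance seed embedded in the object.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(x, path, seed = NA) {
  obj <- list(provenance = list(package = "dnmeth",
                                version = as.character(utils::packageVersion("dnmeth")),
                                seed = seed),
              data = x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
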