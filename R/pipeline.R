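# Pipeline orchestration: each stage reads standard-format inputs, runs one
# module, writes outputs with a provenance header, and never mutates inputs.
# One top-level seed fans out to per-stage child seeds via a counter scheme.

stage_seed <- function(seed, stage_index) {
  (as.integer(seed) * 1009L + stage_index * 9173L) %% 2147483647L
}

default_run_config <- function() {
  list(
    alpha = 0.01, min_frac = 0.5, promoter_window = 2000,
    bootstrap_B = 500, hba1c_unit = "percent", albuminuria_measure = "uacr",
    simulate = list(regions = list(), annotation = list(), cohort = list()))
}

#' Run one or more pipeline stages from a config
#'
#' Stages: `simulate_regions`, `simulate_annotation`, `simulate_cohort`,
#' `dmr`, `annotate`, `enrich`, `index`, `risk`, `progression`, `meta`. The
#' config is a named list (or JSON file path) whose entries override
#' module defaults; `out` is the output directory. Every output carries a
#' provenance header with the fanned-out stage seed.
#'
#' @param stages character vector of stage names, run in order.
#' @param config named list or path to a JSON config file.
#' @param out output directory (created if missing).
#' @param seed top-level integer seed.
#' @return named list of per-stage result objects, invisibly.
#' @export
run_pipeline <- function(stages, config = list(), out = ".", seed = 1) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  p <- function(...) file.path(out, ...)

  for (si in seq_along(stages)) {
    st <- stages[si]
    sseed <- stage_seed(seed, si)
    res <- switch(st,
      simulate_regions = {
        rc <- do.call(region_sim_config,
                      utils::modifyList(cfg$simulate$regions,
                                        list(seed = sseed)))
        sim <- simulate_region_counts(rc)
        write_region_counts(sim$matrix, p("region_counts.tsv"), sseed)
        write_truth_json(sim$truth, p("region_truth.json"), sseed)
        sim
      },
      simulate_annotation = {
        sim <- results$simulate_regions
        if (is.null(sim)) stop("simulate_annotation requires simulate_regions")
        args <- utils::modifyList(cfg$simulate$annotation, list(seed = sseed))
        bundle <- do.call(simulate_annotation,
                          c(list(regions = sim$matrix$regions,
                                 truth = sim$truth), args))
        for (f in names(bundle$tfbs))
          write_bed(bundle$tfbs[[f]], p(sprintf("tfbs_%s.bed", f)))
        if (!is.null(bundle$genes)) write_bed(bundle$genes, p("genes.bed"))
        if (!is.null(bundle$cpg_islands))
          write_bed(bundle$cpg_islands, p("cpg_islands.bed"))
        bundle
      },
      simulate_cohort = {
        ccfg <- do.call(cohort_sim_config,
                        utils::modifyList(cfg$simulate$cohort,
                                          list(seed = sseed)))
        sim <- simulate_cohort(ccfg)
        write_cohort(sim, p("cohort.tsv"), sseed)
        write_truth_json(sim$truth, p("cohort_truth.json"), sseed)
        sim
      },
      dmr = {
        mat <- if (!is.null(results$simulate_regions))
          results$simulate_regions$matrix
        else read_region_counts(p("region_counts.tsv"))
        dmrs <- call_dmrs(mat, alpha = cfg$alpha)
        called <- dmrs[dmrs$significant, ]
        bed <- data.frame(chrom = called$chrom, start = called$start,
                          end = called$end, name = called$cluster,
                          score = round(-log10(pmax(
                            do.call(pmin, called[grep("^p_", names(called))]),
                            1e-300)), 3))
        write_bed(bed, p("dmrs.bed"))
        dmrs
      },
      annotate = {
        dmrs <- results$dmr
        bundle <- results$simulate_annotation
        if (is.null(dmrs) || is.null(bundle))
          stop("annotate requires dmr and simulate_annotation stages")
        called <- dmrs[dmrs$significant, ]
        cls <- classify_region(called, bundle)
        out_df <- cbind(called[, c("chrom", "start", "end", "region_id")], cls)
        write_tsv_prov(out_df, p("dmr_annotation.tsv"), sseed)
        out_df
      },
      enrich = {
        dmrs <- results$dmr
        bundle <- results$simulate_annotation
        if (is.null(dmrs) || is.null(bundle))
          stop("enrich requires dmr and simulate_annotation stages")
        called <- dmrs[dmrs$significant, ]
        scan <- enrichment_scan(called, bundle, min_frac = cfg$min_frac)
        write_tsv_prov(scan, p("tfbs_enrichment.tsv"), sseed)
        scan
      },
      index = {
        co <- if (!is.null(results$simulate_cohort))
          results$simulate_cohort$cohort
        else read_cohort(p("cohort.tsv"))$cohort
        genes <- intersect(c("MTOR", "RPTOR", "IRS2", "TXNRD1", "LCAT",
                             "SMPD3", "COL1A2"), names(co))
        ref <- if ("Normo" %in% co$group) "Normo" else unique(co$group)[1]
        mi <- combine_core_genes(co[, genes], co$group, ref)
        idx_df <- data.frame(subject = co$subject[mi$kept],
                             group = co$group[mi$kept], index = mi$index)
        write_tsv_prov(idx_df, p("meth_index.tsv"), sseed)
        mi
      },
      risk = {
        co <- if (!is.null(results$simulate_cohort))
          results$simulate_cohort$cohort
        else read_cohort(p("cohort.tsv"))$cohort
        acat <- albuminuria_stage(uacr = co$uacr)
        kr <- kdigo_risk(co$egfr, acat, esrd = co$esrd)
        kr <- cbind(subject = co$subject, kr)
        write_tsv_prov(kr, p("kdigo_risk.tsv"), sseed)
        kr
      },
      progression = {
        sim <- results$simulate_cohort
        co <- if (!is.null(sim)) sim$cohort else read_cohort(p("cohort.tsv"))$cohort
        fu <- if (!is.null(sim)) sim$followup else read_cohort(p("cohort.tsv"))$followup
        sl <- vapply(split(fu, fu$subject), function(d)
          egfr_slope(d$time, d$egfr), numeric(1))
        sl <- sl[co$subject]
        pr <- data.frame(subject = co$subject, egfr_slope = unname(sl),
                         decline_class = classify_decline(unname(sl)),
                         albuminuria_progressor =
                           classify_albuminuria_progression(
                             co$baseline_stage, co$last_stage))
        write_tsv_prov(pr, p("progression.tsv"), sseed)
        pr
      },
      meta = {
        mi <- results$index
        krisk <- results$risk
        if (is.null(mi) || is.null(krisk))
          stop("meta requires index and risk stages")
        co <- results$simulate_cohort$cohort
        idx <- mi$index
        kept <- mi$kept
        mr <- meta_analyze_cohorts(idx, co$cohort[kept],
                                   as.character(krisk$risk)[kept],
                                   risk_group = "very_high", seed = sseed)
        write_tsv_prov(mr$per_cohort, p("meta_per_cohort.tsv"), sseed)
        write_truth_json(list(pooled = mr$pooled,
                              fisher_x2 = mr$fisher$statistic,
                              fisher_p = mr$fisher$p),
                         p("meta_summary.json"), sseed)
        mr
      },
      stop("unknown stage: ", st))
    results[[st]] <- res
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Subcommands mirror the pipeline stages:
#' `simulate regions|annotation|cohort`, `dmr`, `annotate`, `enrich`,
#' `index`, `risk`, `progression`, `meta`; each accepts `--config cfg.json`,
#' `--seed N`, `--out dir`. Invoke via
#' `Rscript -e 'dnmeth::dnmeth_cli()' <subcommand> [options]`.
#'
#' @param args character vector of arguments (defaults to the command line).
#' @return exit status, invisibly (0 on success).
#' @export
dnmeth_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dnmeth <simulate regions|annotation|cohort|dmr|annotate|enrich|",
    "       index|risk|progression|meta> [--config cfg.json] [--seed N]",
    "       [--out dir]", sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  opt <- list(config = list(), seed = 1L, out = ".")
  pos <- character()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--config", "--seed", "--out", "--log-level")) {
      v <- args[i + 1]; i <- i + 2
      if (a == "--config") opt$config <- v
      if (a == "--seed") opt$seed <- as.integer(v)
      if (a == "--out") opt$out <- v
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  stage <- if (identical(pos[1], "simulate"))
    paste0("simulate_", if (pos[2] == "regions") "regions" else pos[2])
  else pos[1]
  if (stage == "simulate_annotation")
    stages <- c("simulate_regions", "simulate_annotation")
  else stages <- stage
  run_pipeline(stages, config = opt$config, out = opt$out, seed = opt$seed)
  invisible(0L)
}
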