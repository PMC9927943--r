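#' Configuration for the region-count simulator
#'
#' The generator emulates methyl-capture sequencing summarised over regions
#' (~510 bp) on a single synthetic contig: negative-binomial counts with a
#' common baseline mean, planted hypo-/hyper-methylated regions with a
#' multiplicative fold change in affected case groups, and optional log-scale
#' covariate effects.
#'
#' @param n_regions number of regions.
#' @param n_per_group samples per group: scalar or one value per group label.
#' @param group_labels ordered group labels; the first is the control.
#' @param baseline_mean expected count per region per sample.
#' @param dispersion NB dispersion phi >= 0 (Var = mu + phi mu^2).
#' @param n_hypo_dmrs,n_hyper_dmrs planted DMR counts.
#' @param effect_fold multiplicative change (> 0) in affected groups; hypo
#'   regions are divided by it, hyper regions multiplied.
#' @param covariate_effects named numeric vector of log-scale coefficients on
#'   standardized covariates (`age`, `sex`, `cellfrac`, `cluster_conc`); all
#'   zero by default.
#' @param region_length mean region length in bp (default 510).
#' @param genome_length synthetic contig length.
#' @param seed integer seed.
#' @return list of class `RegionSimConfig`.
#' @export
region_sim_config <- function(n_regions = 2000, n_per_group = 10,
                              group_labels = c("healthy", "Normo", "Macro", "ESRD"),
                              baseline_mean = 50, dispersion = 0.1,
                              n_hypo_dmrs = 0, n_hyper_dmrs = 0,
                              effect_fold = 2,
                              covariate_effects = c(age = 0, sex = 0,
                                                    cellfrac = 0, cluster_conc = 0),
                              region_length = 510, genome_length = NULL,
                              seed = 1) {
  if (length(n_per_group) == 1)
    n_per_group <- rep(n_per_group, length(group_labels))
  if (any(n_per_group <= 0)) stop("non-positive n_per_group")
  if (dispersion < 0) stop("negative dispersion")
  if (effect_fold <= 0) stop("effect_fold must be > 0")
  if (n_hypo_dmrs + n_hyper_dmrs > n_regions)
    stop("n_hypo_dmrs + n_hyper_dmrs must not exceed n_regions")
  if (is.null(genome_length)) genome_length <- n_regions * region_length * 4
  structure(list(n_regions = n_regions, n_per_group = n_per_group,
                 group_labels = group_labels, baseline_mean = baseline_mean,
                 dispersion = dispersion, n_hypo_dmrs = n_hypo_dmrs,
                 n_hyper_dmrs = n_hyper_dmrs, effect_fold = effect_fold,
                 covariate_effects = covariate_effects,
                 region_length = region_length, genome_length = genome_length,
                 seed = as.integer(seed)),
            class = "RegionSimConfig")
}

rnb <- function(n, mu, phi) {
  if (phi < 1e-12) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a region-level methylation count matrix with planted DMRs
#'
#' Counts are NB(mu = baseline * group effect * covariate effect * library
#' factor, dispersion = phi). Each planted hypomethylated region affects one
#' case group (cycled over case groups so every private-hypo pattern occurs);
#' hypermethylated regions affect all case groups. The truth table records
#' each planted region's direction and affected groups.
#'
#' @param config a [region_sim_config()].
#' @return list with `matrix` (RegionCountMatrix) and `truth` (data.frame
#'   with region_id, direction, affected_groups, effect_fold).
#' @export
simulate_region_counts <- function(config) {
  stopifnot(inherits(config, "RegionSimConfig"))
  set.seed(config$seed)
  nr <- config$n_regions
  labs <- config$group_labels
  nper <- config$n_per_group
  ns <- sum(nper)

  # regions on a single synthetic contig, 0-based half-open, sorted
  width <- pmax(50, round(stats::rgamma(nr, shape = 8,
                                        scale = config$region_length / 8)))
  start <- sort(sample.int(config$genome_length - max(width), nr))
  regions <- data.frame(chrom = "chrS", start = start, end = start + width,
                        region_id = sprintf("region_%05d", seq_len(nr)))

  grp <- factor(rep(labs, nper), levels = labs)
  design <- data.frame(
    group = grp,
    age = round(stats::rnorm(ns, 45, 10)),
    sex = stats::rbinom(ns, 1, 0.5),
    cellfrac = stats::rbeta(ns, 20, 10),        # dominant leukocyte fraction
    cluster_conc = stats::rnorm(ns, 0, 1))

  cov_mult <- rep(1, ns)
  ce <- config$covariate_effects
  for (nm in intersect(names(ce), c("age", "sex", "cellfrac", "cluster_conc"))) {
    z <- design[[nm]]
    z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
    cov_mult <- cov_mult * exp(ce[[nm]] * z)
  }
  lib_factor <- stats::runif(ns, 0.8, 1.2)

  cases <- labs[-1]
  idx_dmr <- sample.int(nr, config$n_hypo_dmrs + config$n_hyper_dmrs)
  idx_hypo <- idx_dmr[seq_len(config$n_hypo_dmrs)]
  idx_hyper <- setdiff(idx_dmr, idx_hypo)
  affected <- rep(cases, length.out = max(1, config$n_hypo_dmrs))

  fold <- matrix(1, nr, length(labs), dimnames = list(NULL, labs))
  if (config$n_hypo_dmrs > 0)
    for (i in seq_along(idx_hypo))
      fold[idx_hypo[i], affected[i]] <- 1 / config$effect_fold
  if (length(idx_hyper) > 0)
    fold[idx_hyper, cases] <- config$effect_fold

  mu <- config$baseline_mean * fold[, as.integer(grp), drop = FALSE]
  mu <- sweep(mu, 2, cov_mult * lib_factor, "*")
  counts <- matrix(rnb(length(mu), as.vector(mu), config$dispersion), nr, ns)
  colnames(counts) <- sprintf("%s_%02d", grp, stats::ave(seq_len(ns), grp,
                                                         FUN = seq_along))
  library_sizes <- nr * config$baseline_mean * lib_factor

  truth <- data.frame(
    region_id = regions$region_id[c(idx_hypo, idx_hyper)],
    direction = c(rep("hypo", length(idx_hypo)), rep("hyper", length(idx_hyper))),
    affected_groups = c(affected[seq_along(idx_hypo)],
                        rep(paste(cases, collapse = ","), length(idx_hyper))),
    effect_fold = rep(config$effect_fold, length(idx_dmr)),
    stringsAsFactors = FALSE)

  list(matrix = region_count_matrix(regions, counts, library_sizes, design),
       truth = truth)
}

#' Simulate annotation tracks with planted TFBS enrichment
#'
#' Places genes (with strand, TSS and exons), non-overlapping CpG islands,
#' array probe positions, and per-factor TFBS interval sets on the synthetic
#' contig. For factors listed in `planted_factors`, TFBS intervals are placed
#' over regions so that the odds of a hypo-DMR being covered at >= 50% are
#' `planted_or` times the odds for non-hypo regions; other factors get equal
#' odds (OR = 1).
#'
#' @param regions region data.frame (chrom, start, end, region_id).
#' @param truth planted-DMR truth table from [simulate_region_counts()].
#' @param n_genes,n_cgis,n_probes numbers of features.
#' @param tfbs_factors character vector of factor labels.
#' @param planted_or planted odds ratio (> 0) for `planted_factors`.
#' @param planted_factors factors carrying the planted enrichment; default the
#'   first element of `tfbs_factors`.
#' @param base_overlap baseline overlap probability for non-hypo regions.
#' @param genome_length synthetic contig length.
#' @param seed integer seed.
#' @return an `AnnotationBundle` (see [annotation_bundle()]).
#' @export
simulate_annotation <- function(regions, truth = NULL, n_genes = 100,
                                n_cgis = 50, n_probes = 0,
                                tfbs_factors = c("CTCF", "POL2B"),
                                planted_or = 1,
                                planted_factors = tfbs_factors[1],
                                base_overlap = 0.2,
                                genome_length = NULL, seed = 1) {
  if (planted_or <= 0) stop("planted_or must be > 0")
  set.seed(seed)
  if (is.null(genome_length)) genome_length <- max(regions$end) + 100000L
  if (genome_length < max(regions$end)) stop("genome does not cover regions")

  genes <- NULL
  if (n_genes > 0) {
    glen <- round(stats::runif(n_genes, 5000, 30000))
    gstart <- sort(sample.int(max(1, genome_length - max(glen)), n_genes))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- data.frame(chrom = "chrS", start = gstart, end = gstart + glen,
                        name = sprintf("gene_%03d", seq_len(n_genes)),
                        strand = strand, stringsAsFactors = FALSE)
  }
  exons <- NULL
  if (n_genes > 0) {
    ex <- lapply(seq_len(n_genes), function(i) {
      ne <- sample(2:6, 1)
      w <- genes$end[i] - genes$start[i]
      es <- sort(sample.int(w - 200, ne)) + genes$start[i]
      data.frame(chrom = "chrS", start = es, end = pmin(es + 150, genes$end[i]),
                 name = genes$name[i], stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, ex)
  }
  cgis <- NULL
  if (n_cgis > 0) {
    # non-overlapping by construction: islands on a spaced grid, with jitter
    # and width each under half the grid pitch
    pitch <- floor(genome_length / (n_cgis + 1))
    cs <- seq_len(n_cgis) * pitch +
      sample.int(max(1, pitch %/% 4), n_cgis, replace = TRUE)
    wmax <- max(2, min(1500, pitch %/% 2))
    cw <- round(stats::runif(n_cgis, min(500, wmax - 1), wmax))
    cgis <- data.frame(chrom = "chrS", start = cs,
                       end = pmin(cs + cw, genome_length),
                       name = sprintf("cgi_%03d", seq_len(n_cgis)),
                       stringsAsFactors = FALSE)
  }
  probes <- NULL
  if (n_probes > 0)
    probes <- data.frame(chrom = "chrS",
                         pos = sort(sample.int(genome_length, n_probes)),
                         probe_id = sprintf("cg%07d", seq_len(n_probes)),
                         stringsAsFactors = FALSE)

  is_hypo <- if (is.null(truth)) rep(FALSE, nrow(regions)) else
    regions$region_id %in% truth$region_id[truth$direction == "hypo"]
  odds0 <- base_overlap / (1 - base_overlap)
  p1 <- planted_or * odds0 / (1 + planted_or * odds0)
  tfbs <- list()
  for (f in tfbs_factors) {
    p_hit <- if (f %in% planted_factors)
      ifelse(is_hypo, p1, base_overlap) else rep(base_overlap, nrow(regions))
    hit <- stats::rbinom(nrow(regions), 1, p_hit) == 1
    if (any(hit)) {
      # interval covering the whole region guarantees >= 50% coverage
      tfbs[[f]] <- data.frame(chrom = "chrS",
                              start = pmax(0, regions$start[hit] - 10),
                              end = pmin(genome_length, regions$end[hit] + 10),
                              name = f, stringsAsFactors = FALSE)
    } else {
      tfbs[[f]] <- data.frame(chrom = character(), start = integer(),
                              end = integer(), name = character(),
                              stringsAsFactors = FALSE)
    }
  }
  annotation_bundle(genes = genes, exons = exons, cpg_islands = cgis,
                    probes = probes, tfbs = tfbs)
}

#' Configuration for the clinical cohort simulator
#'
#' Emulates the multi-cohort design: per-subject methyl-qPCR percentages for
#' the 7 core genes that decrease with renal risk level, clinical covariates
#' correlated with mean core methylation through a Gaussian copula, and
#' longitudinal eGFR trajectories from three planted decline classes.
#'
#' @param cohorts named integer list/vector per cohort: subjects per
#'   albuminuria group (one value recycles over all groups).
#' @param group_labels albuminuria groups in risk order.
#' @param gene_names core gene labels.
#' @param baseline_meth baseline methylation % per gene (recycled).
#' @param risk_effect mean % methylation reduction per group (same length as
#'   `group_labels`, non-decreasing for a monotone risk effect).
#' @param covariate_corr target correlations of mean core methylation with
#'   `hba1c`, `egfr` and (log-scale) `uacr`.
#' @param noise_sd per-gene methylation noise SD in %.
#' @param shared_var_frac fraction of methylation noise variance shared across
#'   genes (drives attainable covariate correlations).
#' @param egfr_group_mean mean baseline eGFR per group.
#' @param followup_years follow-up span in years (annual visits).
#' @param decline_class_mix proportions of none/slow/steep decline; must sum
#'   to 1.
#' @param seed integer seed.
#' @return list of class `CohortSimConfig`.
#' @export
cohort_sim_config <- function(cohorts = list(synthetic = 50),
                              group_labels = c("healthy", "Normo", "Micro",
                                               "Macro", "ESRD"),
                              gene_names = c("MTOR", "RPTOR", "IRS2", "TXNRD1",
                                             "LCAT", "SMPD3", "COL1A2"),
                              baseline_meth = 92,
                              risk_effect = c(0, 2, 6, 12, 18),
                              covariate_corr = c(hba1c = -0.4, egfr = 0.4,
                                                 uacr = -0.35),
                              noise_sd = 8, shared_var_frac = 0.7,
                              egfr_group_mean = c(100, 95, 75, 70, 8),
                              followup_years = 5,
                              decline_class_mix = c(none = 0.6, slow = 0.25,
                                                    steep = 0.15),
                              seed = 1) {
  baseline_meth <- rep(baseline_meth, length.out = length(gene_names))
  risk_effect <- rep(risk_effect, length.out = length(group_labels))
  if (any(baseline_meth < 0 | baseline_meth > 100))
    stop("baseline methylation must be within [0, 100]")
  if (abs(sum(decline_class_mix) - 1) > 1e-8)
    stop("decline_class_mix must sum to 1")
  if (any(abs(covariate_corr) >= 1)) stop("unattainable correlation targets")
  structure(list(cohorts = cohorts, group_labels = group_labels,
                 gene_names = gene_names, baseline_meth = baseline_meth,
                 risk_effect = risk_effect, covariate_corr = covariate_corr,
                 noise_sd = noise_sd, shared_var_frac = shared_var_frac,
                 egfr_group_mean = egfr_group_mean,
                 followup_years = followup_years,
                 decline_class_mix = decline_class_mix,
                 seed = as.integer(seed)),
            class = "CohortSimConfig")
}

# log10 UACR bounds (mg/g) per albuminuria group
.uacr_bounds <- rbind(healthy = c(0.3, 1.46), Normo = c(0.3, 1.46),
                      Micro = c(log10(30), log10(298)),
                      Macro = c(log10(305), 3.7), ESRD = c(log10(305), 3.7))

#' Simulate a multi-cohort clinical table with ground truth
#'
#' Per-gene methylation percentage = baseline - risk_effect[group] + Gaussian
#' noise with a shared subject factor, truncated to [0, 100]. HbA1c, eGFR and
#' UACR are drawn through a Gaussian copula against the shared factor, with
#' per-variable latent correlations inflated so that the target correlations
#' hold for the *mean* core methylation; infeasible targets error. UACR is
#' mapped into group-consistent log-scale bounds (right-skewed), so
#' albuminuria stages agree with UACR. eGFR trajectories are linear from the
#' planted slope class with noisy interior visits but exact endpoints, so the
#' first-vs-last slope classifier recovers the planted class.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `cohort` (data.frame, one row per subject), `followup`
#'   (long data.frame subject/time/egfr) and `truth` (planted risk level,
#'   decline class, progression flag per subject).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortSimConfig"))
  set.seed(config$seed)
  labs <- config$group_labels
  genes <- config$gene_names
  G <- length(genes)
  w <- config$shared_var_frac

  rows <- list(); fu <- list()
  # attenuation of corr(mean meth, covariate) from per-gene noise averaging
  atten <- sqrt(w / (w + (1 - w) / G))
  rlat <- config$covariate_corr / atten
  if (any(abs(rlat) >= 1))
    stop("unattainable correlation targets given shared_var_frac")

  sid <- 0
  for (co in names(config$cohorts)) {
    nper <- rep(unlist(config$cohorts[[co]]), length.out = length(labs))
    for (gi in seq_along(labs)) {
      g <- labs[gi]; n <- nper[gi]
      if (n == 0) next
      u <- stats::rnorm(n)
      lat <- vapply(rlat, function(r)
        r * u + sqrt(1 - r^2) * stats::rnorm(n), numeric(n))
      meth <- vapply(seq_len(G), function(j)
        pmin(100, pmax(0, config$baseline_meth[j] - config$risk_effect[gi] +
          config$noise_sd * (sqrt(w) * u + sqrt(1 - w) * stats::rnorm(n)))),
        numeric(n))
      colnames(meth) <- genes

      hba1c <- 8 + 1.2 * lat[, "hba1c"]
      bounds <- .uacr_bounds[g, ]
      uacr <- 10^(bounds[1] + (bounds[2] - bounds[1]) *
                    stats::pnorm(lat[, "uacr"]))
      egfr <- pmax(2, config$egfr_group_mean[gi] +
                     (if (g == "ESRD") 3 else 10) * lat[, "egfr"])
      if (g == "ESRD") egfr <- pmin(egfr, 14)

      decl <- sample(names(config$decline_class_mix), n, replace = TRUE,
                     prob = config$decline_class_mix)
      slope <- ifelse(decl == "none", stats::runif(n, -0.8, 0.5),
               ifelse(decl == "slow", stats::runif(n, -2.8, -1.2),
                      stats::runif(n, -5.5, -3.2)))
      # a declining trajectory must stay above the physiological floor
      # (2 mL/min/1.73 m^2) over at least one year; subjects whose baseline
      # cannot support the drawn class are re-planted as non-decliners
      infeasible <- slope < 0 & (egfr - 2) / -slope < 1
      decl[infeasible] <- "none"
      slope[infeasible] <- stats::runif(sum(infeasible), 0, 0.5)
      prog_p <- c(none = 0.10, slow = 0.25, steep = 0.50)[decl]
      stage <- if (g == "healthy") "Normo" else g
      progressor <- stats::rbinom(n, 1, ifelse(stage == "ESRD", 0, prog_p)) == 1
      stages <- c("Normo", "Micro", "Macro", "ESRD")
      last_stage <- ifelse(progressor,
                           stages[pmin(4, match(stage, stages) + 1)], stage)

      ids <- sprintf("S%05d", sid + seq_len(n)); sid <- sid + n
      rows[[length(rows) + 1]] <- data.frame(
        subject = ids, cohort = co, group = g,
        meth, hba1c = hba1c, egfr = egfr, uacr = uacr,
        age = round(stats::rnorm(n, 45, 10)),
        duration = pmax(1, round(stats::rnorm(n, 30, 8))),
        sex = sample(c("male", "female"), n, replace = TRUE),
        smoking = stats::rbinom(n, 1, 0.25),
        sbp = round(stats::rnorm(n, 135, 15)),
        esrd = g == "ESRD",
        baseline_stage = stage, last_stage = last_stage,
        check.names = FALSE, stringsAsFactors = FALSE)

      for (i in seq_len(n)) {
        span <- config$followup_years
        if (slope[i] < 0)
          span <- max(1, min(span, floor((egfr[i] - 2) / -slope[i])))
        times <- 0:span
        # exact endpoints (the slope classifier uses first/last only),
        # noisy interior visits
        traj <- egfr[i] + slope[i] * times
        if (span >= 2) {
          mid <- 2:span
          traj[mid] <- pmax(1, traj[mid] + stats::rnorm(length(mid) , 0, 2))
        }
        fu[[length(fu) + 1]] <- data.frame(subject = ids[i], time = times,
                                           egfr = traj)
      }
      rows[[length(rows)]]$decline_class <- decl
      rows[[length(rows)]]$slope_true <- slope
    }
  }
  cohort <- do.call(rbind, rows)
  truth <- cohort[, c("subject", "group", "decline_class", "slope_true",
                      "baseline_stage", "last_stage")]
  truth$risk_level <- match(truth$group, labs)
  list(cohort = cohort, followup = do.call(rbind, fu), truth = truth)
}

#' Simulate a prediction cohort with a planted AUC gain
#'
#' Binormal construction: five standardized clinical covariates are shifted in
#' cases so their optimal combined AUC equals `auc_clinical`; an independent
#' methylation index adds orthogonal signal so the full model's optimal AUC is
#' `auc_full`. Used to exercise [bootstrap_delta_auc()] under a known
#' ground-truth improvement.
#'
#' @param n subjects. @param auc_clinical,auc_full target true AUCs.
#' @param prevalence outcome prevalence.
#' @param seed integer seed.
#' @return data.frame with `outcome`, covariates `duration`, `hba1c`, `uacr`,
#'   `smoking`, `sbp`, and `meth_index`.
#' @export
simulate_prediction_data <- function(n = 500, auc_clinical = 0.65,
                                     auc_full = 0.75, prevalence = 0.3,
                                     seed = 1) {
  set.seed(seed)
  d_clin <- sqrt(2) * stats::qnorm(auc_clinical)
  d_full <- sqrt(2) * stats::qnorm(auc_full)
  if (d_full < d_clin) stop("auc_full must be >= auc_clinical")
  d_idx <- sqrt(d_full^2 - d_clin^2)
  y <- stats::rbinom(n, 1, prevalence)
  shift <- d_clin / sqrt(5)
  covs <- vapply(1:5, function(j) stats::rnorm(n) + shift * y, numeric(n))
  colnames(covs) <- c("duration", "hba1c", "uacr", "smoking", "sbp")
  idx <- stats::rnorm(n) - d_idx * y   # reduced methylation index in cases
  data.frame(outcome = y, covs, meth_index = idx)
}
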