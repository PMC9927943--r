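# dnmeth

Leukocyte DNA-methylation analysis of diabetic nephropathy (DN) risk in type 1
diabetes, as a reusable, tested R pipeline. The package has two arms:

1. **Genomic arm** — region-level differential methylation for methyl-capture
   sequencing counts: log-CPM normalization, covariate adjustment (age, sex,
   cell heterogeneity, library cluster concentration), a negative-binomial
   exact test over all pairwise group contrasts (healthy / Normo / Macro /
   ESRD), DMR calling at raw *P* < 0.01, profile clustering, and annotation of
   called DMRs by gene context (promoter / exon / intron / intergenic), CpG
   context (CGI / shore ±1 kb / shelf 1–5 kb / open sea), TSS-distance
   profiles, array-probe proximity windows, gene-set over-representation, and
   transcription-factor binding-site (TFBS) overlap enrichment (50% coverage
   criterion, odds-ratio + Fisher exact test).
2. **Clinical arm** — a core-gene methylation index
   (*MTOR, RPTOR, IRS2, TXNRD1, LCAT, SMPD3, COL1A2*; PC1-loading weighted,
   rescaled so the reference group's mean is 100%), Mann-Whitney group
   contrasts and Pearson covariate correlations, CKD-EPI eGFR and KDIGO
   G×A risk categories, eGFR-decline classification (none / slow / steep from
   the first-to-last slope), albuminuria-progression flags, logistic risk
   models with ROC AUC and a bootstrap ΔAUC test for the added value of the
   methylation index, and sample-size-weighted median-difference
   meta-analysis across cohorts with Fisher's combined probability test.

Patient-level cohort data are not distributable, so the package ships
synthetic-data generators with known ground truth (planted DMRs, planted TFBS
odds ratios, planted risk effects, correlations and decline classes); every
pipeline stage is validated against these truths and against independent
brute-force oracles.

## Core statistics

* **NB exact test.** For two groups with equalized library sizes, the group
  sums are `S_g ~ NB(n_g m, n_g/φ)` under a common dispersion φ
  (`Var = μ + φμ²`). Conditional on `S_a + S_b = N`, the two-sided p-value is
  the total probability of all splits of `N` no more probable than the
  observed one; φ = 0 reduces to the Poisson-conditional binomial test.
  Dispersion is pooled method-of-moments, clipped at 0.
* **Methylation index.** `index_i = 100 · (x_i·w) / mean_ref(x·w)` where `w`
  is the first principal-component loading vector (unit norm, non-negative
  sum) of the column-centered subject × gene percentage matrix.
* **ΔAUC.** `AUC` via the Mann-Whitney relation with midrank ties; ΔAUC =
  AUC(clinical + index) − AUC(clinical); two-sided bootstrap p = doubled
  proportion of subject resamples (both models refit) with ΔAUC ≤ 0, clipped
  to [2/B, 1].
* **Meta-analysis.** Per-cohort median difference vs the low-risk group with
  percentile-bootstrap CI and Mann-Whitney p; pooled by sample-size weights;
  evidence combined as `X² = −2Σ log pᵢ ~ χ²(2k)`.

## Worked example

```r
library(dnmeth)

## genomic arm: simulate counts with 200 planted 2-fold hypo-DMRs
cfg <- region_sim_config(n_regions = 2000, n_per_group = 12,
                         group_labels = c("healthy", "Normo"),
                         n_hypo_dmrs = 200, effect_fold = 2, seed = 42)
sim  <- simulate_region_counts(cfg)
dmrs <- call_dmrs(sim$matrix, alpha = 0.01)
sum(dmrs$significant)        # 221  (~185 true positives + ~1.8% false calls)
attr(dmrs, "phi")            # 0.101 (truth: 0.1)

## TFBS enrichment on a direction-balanced DMR set with planted OR = 3
#   factor frac_hypo frac_hyper odds_ratio        p
#     CTCF     0.440      0.196       3.22 4.99e-32
#    POL2B     0.389      0.188       2.75 2.56e-23
#    NULLF     0.209      0.190       1.13 3.14e-01

## clinical arm
co <- simulate_cohort(cohort_sim_config(
        cohorts = list(FinnDiane = 40, PROFIL = 40), seed = 44))
genes <- c("MTOR","RPTOR","IRS2","TXNRD1","LCAT","SMPD3","COL1A2")
mi <- combine_core_genes(co$cohort[, genes], co$cohort$group, "Normo")
round(tapply(mi$index, co$cohort$group, mean), 2)
#   ESRD healthy   Macro   Micro   Normo
#  83.27  102.44   91.03   96.15  100.00     <- index falls with renal risk

kr <- kdigo_risk(co$cohort$egfr, albuminuria_stage(uacr = co$cohort$uacr),
                 co$cohort$esrd)
meta_analyze_cohorts(mi$index, co$cohort$cohort, as.character(kr$risk),
                     "very_high")
# pooled median difference -18.5%, Fisher X2 = 160.0 (df 4), p = 1.46e-33

## added predictive value of the index (planted true gain 0.10)
d <- simulate_prediction_data(n = 500, seed = 45)
clin <- c("duration","hba1c","uacr","smoking","sbp")
bootstrap_delta_auc(d[, c(clin, "meth_index")], clin, d$outcome,
                    B = 500, seed = 46)
# AUC clinical 0.672 -> full 0.762 (dAUC 0.091, p = 0.004)
```

The printed numbers above are actual output at the stated seeds. The group
means, enrichment odds ratios and ΔAUC mirror the qualitative pattern the
pipeline is designed to detect: reduced core-gene methylation with rising
renal risk, CTCF/Pol2B over-representation at hypomethylated regions, and a
~0.10 AUC improvement from adding the methylation index to clinical
covariates.

## Pipeline / CLI

```sh
Rscript -e 'dnmeth::dnmeth_cli()' simulate cohort --seed 3 --out out/
Rscript -e 'dnmeth::dnmeth_cli()' index --seed 3 --out out/
```

Subcommands: `simulate regions|annotation|cohort`, `dmr`, `annotate`,
`enrich`, `index`, `risk`, `progression`, `meta`; options `--config cfg.json`,
`--seed N`, `--out dir`. Outputs are TSV/BED6/JSON with `#` provenance
headers; all coordinates 0-based half-open.

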