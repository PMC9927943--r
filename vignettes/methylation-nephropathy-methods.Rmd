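---
title: "Methods: region-level methylation analysis and renal-risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-level methylation analysis and renal-risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmeth)
```

This vignette documents the models behind `dnmeth`, the assumptions they
make, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical conventions chosen where
the underlying study design left the details open.

## 1. The scientific setting

Methyl-capture (methyl-binding-domain pulldown) sequencing measures DNA
methylation as regional read abundance: more methylated DNA in a region means
more captured fragments, hence higher counts. Leukocyte methylomes from type
1 diabetes cohorts stratified by albuminuria (healthy, Normo, Macro, ESRD)
are compared region by region; regions whose abundance differs between groups
are differentially methylated regions (DMRs). Downstream, a panel of seven
core genes (*MTOR*, *RPTOR*, *IRS2*, *TXNRD1*, *LCAT*, *SMPD3*, *COL1A2*) is
assayed per subject by methyl-qPCR (percent methylation), combined into a
single index, and related to renal risk and longitudinal kidney-function
decline.

## 2. Region-level differential methylation

**Model.** Counts for region *r*, sample *j* are negative binomial with mean
proportional to the sample's library size and a common dispersion φ
(`Var = μ + φμ²`). φ is estimated by pooled method of moments on
library-size-equalized counts: `φ̂ = Σ(s²_rg − m_rg) / Σ m²_rg` over regions
and groups, clipped at zero. This is deliberately the simplest consistent
estimator; it is validated against generator truth (φ = 0.2 data yield
estimates in [0.15, 0.25] at 5,000 regions).

**Exact test.** For a two-group contrast the group sums of equalized counts
are `S_g ~ NB(n_g m, size = n_g/φ)` (the NB family is closed under summation
at fixed dispersion). Conditional on the total `N = S_a + S_b`, the two-sided
p-value sums the probability of every split of `N` no more probable than the
observed one. Ties in the enumeration are included up to a relative
tolerance of 1e−12, which makes the two-sided definition deterministic under
floating point. At φ = 0 the conditional distribution is exactly
`Binomial(N, n_a/(n_a+n_b))`. The test is verified against an independent
convolution oracle (per-sample pmfs convolved numerically) for all totals
≤ 30 at 1e−10.

Covariate adjustment (age, sex, cell fraction, cluster concentration) is
applied as per-region least-squares residuals of log-CPM — used for
clustering and PCA only, not inside the exact test. A full covariate-adjusted
GLM test was deliberately not implemented: the exact test is verifiable
against enumeration, which anchors the whole calling pipeline, and the
calling threshold (raw *P* < 0.01, the study's convention) is applied to the
unadjusted contrast. Benjamini–Hochberg q-values are reported alongside.

**DMR clusters.** A region significant in at least one case-vs-control
contrast is a DMR. Its cluster label is the significance pattern:
hypomethylation private to a case group (`hypo_Normo`, `hypo_Macro`,
`hypo_ESRD`), hypermethylation in all case groups (`hyper_all`), or `other`.
When several hypo contrasts are significant, the highest-risk group listed
last in the design wins; this is a deterministic tie-break, documented here
because the published four-category scheme does not specify one.
Hierarchical clustering (distance 1 − Pearson r, average linkage) is
available as an independent view; zero-variance profiles get distance 1 by
convention with a warning.

## 3. Annotation conventions

All coordinates are 0-based half-open everywhere (memory and disk); 1-based
positions appear only in log messages. Regions are assigned by midpoint
(regions average ~510 bp, much smaller than the features they are assigned
to); distance from a point to a track is the distance to the nearest covered
base (0 inside, 1 immediately adjacent).

* CpG context: `CGI` inside an island; `shore` within 1 kb of an island
  edge (inclusive); `shelf` within 1–5 kb; else `open_sea`. A midpoint in
  range of two islands takes the nearer class.
* Gene context: `promoter` within TSS ± 2 kb (the window is a common
  convention, configurable via `annotation_bundle(promoter_window=)`);
  else `exon`, `intron`, `intergenic`.
* Primary label precedence: CGI > shore > shelf > promoter > exon > intron >
  intergenic.
* Probe proximity: a probe "directly overlaps" a DMR iff its position lies
  in `[start, end)`; per-window counts are cumulative, reproducing the
  nested direct/10 kb/100 kb structure used to compare sequencing-derived
  DMRs with array probes.

TFBS overlap uses the DMR as denominator: a DMR overlaps a factor iff ≥ 50%
of its length is covered by the merged union of the factor's intervals
(inclusive threshold; no double counting, invariant to splitting intervals
into abutting pieces). The enrichment contrast is hypo- versus
hyper-methylated DMRs — the published framing — with the odds ratio
Haldane–Anscombe-corrected only when a cell is zero, a two-sided Fisher
exact p, and a log-OR normal 95% CI.

## 4. Clinical arm

**Methylation index.** PC1 loadings of the column-centered subject × gene
matrix (unit norm; sign fixed so the loading sum is non-negative), applied to
the raw percentages, then scaled multiplicatively so the reference group's
mean is exactly 100%. "PCA loading analysis" admits several readings; this
one was chosen because the study reports reference means of exactly 100%,
which a multiplicative rescale preserves by construction. Subjects missing
any core gene are excluded (complete case) — no imputation rule was
published. A constant matrix falls back to equal weights with a warning.
HbA1c is stored in NGSP %, with the standard NGSP/IFCC linear conversion
(`convert_hba1c`).

**Renal classification.** eGFR by CKD-EPI 2009 creatinine (no race term),
the contemporary standard for these cohorts' era. Albuminuria categories use
the KDIGO cutoffs 30/300, identical numerically for UACR (mg/g) and AER
(mg/24 h); the boundary 30 is assigned upward (A2) and 300 stays in A2, so
the stages partition `[0, ∞)` reproducibly. Risk comes from the standard
18-cell KDIGO G×A matrix; an explicit ESRD flag (dialysis/transplant) forces
G5/very-high regardless of eGFR, matching the clinical definition.

**Progression.** The eGFR slope is (last − first)/(t_last − t_first) —
intermediate visits are ignored by definition. Decline classes: `none` at
slope ≥ −1, `slow` strictly between −3 and −1, `steep` at ≤ −3. The boundary
−3 is unassigned by the published wording ("greater than −3" / "less than
−3"); it is assigned to `steep`, conservative toward higher risk.
Albuminuria progression is a strict worsening of stage (Normo < Micro <
Macro < ESRD); regression counts as non-progression.

**Prediction.** Logistic regression by IRLS on internally standardized
covariates (DM duration, HbA1c, UACR, smoking, SBP ± methylation index); the
model family is a package decision — the study reports covariate-wise AUC
contributions consistent with a score-based model, and logistic regression
is the simplest member producing a risk score. Perfect separation is
detected (standardized coefficient exceeding 30) and aborts with a
diagnostic rather than returning divergent estimates. The default outcome is
steep decline versus the rest. AUC uses the Mann-Whitney relation with
midrank ties (cross-checked against an O(n²) pair-counting oracle). The
ΔAUC bootstrap resamples subjects with replacement, refits both nested and
full models per resample, and reports the two-sided fraction-based p
(doubled proportion of resamples with ΔAUC ≤ 0, clipped to [2/B, 1]);
resamples missing an outcome class are redrawn with bounded retries. The
published analysis says only "bootstrap in R"; the percentile form was
chosen for transparency, and the same machinery exposes the raw bootstrap
distribution for any alternative summary.

**Meta-analysis.** Per-cohort median difference against the low-risk group
(percentile-bootstrap 95% CI under a fixed seed, Mann-Whitney p with exact
enumeration at n₁+n₂ ≤ 20 and tie-corrected normal approximation above),
pooled with sample-size weights — the simplest mode of the named
median-difference tooling. Fisher's combined statistic uses a p floor of
1e−300 before the log to avoid −∞.

## 5. Synthetic generators: what they emulate, and what not

The generators state the world the tests run in; their defaults are fixed
once and are not tuned to outcomes.

* `simulate_region_counts`: NB counts at a common baseline mean (default 50
  per region per sample — region-level capture depth is a free parameter;
  the study does not report per-region depth distributions), dispersion 0.1,
  per-sample library factors uniform in [0.8, 1.2], groups healthy / Normo /
  Macro / ESRD. Hypo-DMRs divide the mean by `effect_fold` in one case group
  (cycled so every private-hypo pattern occurs); hyper-DMRs multiply it in
  all case groups, mirroring the published four clusters. Covariate effects
  are log-linear and default to zero.
* `simulate_annotation`: genes (5–30 kb, random strand), exons, CpG islands
  non-overlapping by grid construction, probes, and per-factor TFBS sets.
  The planted odds ratio is exact by construction: each region receives a
  covering interval with probability p₁ (hypo) or p₀ (others) with
  odds(p₁) = OR · odds(p₀), p₀ = 0.2 baseline.
* `simulate_cohort`: per-gene methylation % = baseline (92%) − risk effect
  (0/2/6/12/18% across healthy→ESRD, a monotone pattern of the size seen in
  the validation figures) + Gaussian noise (SD 8%), truncated to [0, 100],
  with 70% of the noise variance shared per subject. Clinical covariates are
  tied to the shared factor through a Gaussian copula with latent
  correlations inflated to hit the target correlations of the *mean* core
  methylation (defaults −0.4 HbA1c, +0.4 eGFR, −0.35 log-UACR); infeasible
  targets raise an error. UACR is mapped into stage-consistent log-scale
  bounds, so albuminuria stages agree with UACR by construction. eGFR
  trajectories are linear in the planted slope class (none/slow/steep mixed
  0.6/0.25/0.15) with noisy interior visits but exact endpoints; follow-up
  is shortened for subjects whose baseline cannot support the drawn slope
  above the physiological floor (2 mL/min/1.73 m²), and classes infeasible
  within one year are re-planted as non-decliners.
* `simulate_prediction_data`: binormal construction in which five
  standardized clinical covariates carry a combined discriminability
  matching AUC 0.65 and an orthogonal methylation index raises the optimal
  AUC to 0.75 — the published 0.10 gain as ground truth.

Not emulated: raw reads, bisulfite chemistry, cell-type deconvolution,
genuine genomic sequence structure (one synthetic contig), between-gene
differences in effect size, informative dropout, or measurement error in
creatinine. A green test therefore establishes that each algorithm does what
its definition says on data with the stated structure — not that the stated
structure captures every property of the cohorts.

## 6. Numerical choices and degenerate inputs

* Exact-test tie inclusion at relative 1e−12; p-values returned in (0, 1].
* `call_dmrs(alpha = 1)` returns every region (degenerate threshold).
* Zero-variance profiles in clustering: distance 1, with warning.
* PCA signs: every component's loading sum is made non-negative, so results
  are reproducible across BLAS implementations.
* Mann-Whitney: exact enumeration at n₁+n₂ ≤ 20 (handles ties via midranks),
  tie-corrected normal approximation without continuity correction above.
* Fisher exact 2×2: enumeration at fixed margins with relative tie tolerance
  1e−7 (the convention of standard implementations).
* Pipeline seeds: one top-level seed fans out deterministically to stages
  (`seed·1009 + stage·9173 mod 2³¹−1`), recorded in output provenance
  headers.
* Configs are JSON (not YAML): the deployment environment guarantees a JSON
  parser but not a YAML one.

## 7. Known limitations

* The exact test ignores covariates; strong covariate–group confounding
  would inflate calls. The residualized log-CPM is the place to look when
  PCA shows structure along covariates.
* The common-dispersion assumption is cruder than per-region shrinkage
  estimators; it is the price of an enumerable exact null.
* Region discovery (how variable regions are defined) is out of scope:
  regions are accepted as given, or tiled by the simulator.
* The bootstrap ΔAUC p-value is percentile-based; near ΔAUC = 0 it is
  granular at 2/B.
* Meta-analysis weights are sample-size based; an inverse-variance mode
  (bootstrap variances) would weight heterogeneous cohorts differently.
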