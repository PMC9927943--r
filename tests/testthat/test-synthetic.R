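test_that("region simulator is deterministic and validates config", {
  sim1 <- toy_matrix(seed = 7)
  sim2 <- toy_matrix(seed = 7)
  expect_identical(sim1$matrix$counts, sim2$matrix$counts)
  expect_identical(sim1$truth, sim2$truth)
  expect_true(all(sim1$matrix$regions$start < sim1$matrix$regions$end))

  expect_error(region_sim_config(n_per_group = 0), "non-positive")
  expect_error(region_sim_config(dispersion = -1), "negative dispersion")
  expect_error(region_sim_config(n_regions = 5, n_hypo_dmrs = 4,
                                 n_hyper_dmrs = 3), "exceed")
})

test_that("region counts match configured NB moments", {
  cfg <- region_sim_config(n_regions = 5000, n_per_group = 10,
                           group_labels = c("healthy", "Normo"),
                           baseline_mean = 50, dispersion = 0.2, seed = 11)
  sim <- simulate_region_counts(cfg)
  expect_lt(abs(mean(sim$matrix$counts) - 50) / 50, 0.05)
  phi <- estimate_dispersion(sim$matrix)
  expect_gte(phi, 0.15)
  expect_lte(phi, 0.25)
})

test_that("null region config gives exchangeable groups", {
  # effect_fold irrelevant with no planted DMRs; KS between group count
  # distributions should be unremarkable
  sim <- toy_matrix(n_regions = 500, n_per_group = 10, seed = 3)
  g <- sim$matrix$design$group
  # compare on the CPM scale so per-sample library factors drop out
  cpm <- sweep(sim$matrix$counts, 2, sim$matrix$library_sizes, "/")
  a <- rowMeans(cpm[, g == "healthy"])
  b <- rowMeans(cpm[, g == "Normo"])
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("truth table records every planted DMR with its direction", {
  sim <- toy_matrix(n_regions = 300, n_hypo_dmrs = 30, n_hyper_dmrs = 20,
                    groups = c("healthy", "Normo", "Macro", "ESRD"), seed = 5)
  expect_equal(nrow(sim$truth), 50)
  expect_equal(sum(sim$truth$direction == "hypo"), 30)
  expect_true(all(sim$truth$region_id %in% sim$matrix$regions$region_id))
  hyp <- sim$truth[sim$truth$direction == "hypo", ]
  expect_true(all(hyp$affected_groups %in% c("Normo", "Macro", "ESRD")))
  hyper <- sim$truth[sim$truth$direction == "hyper", ]
  expect_true(all(hyper$affected_groups == "Normo,Macro,ESRD"))
})

test_that("annotation simulator plants overlap odds and handles empty tracks", {
  sim <- toy_matrix(n_regions = 400, n_hypo_dmrs = 100, seed = 2)
  b <- simulate_annotation(sim$matrix$regions, sim$truth, planted_or = 1,
                           n_probes = 20, seed = 4)
  expect_s3_class(b, "AnnotationBundle")
  expect_error(simulate_annotation(sim$matrix$regions, sim$truth,
                                   planted_or = 0), "planted_or")
  # zero CpG islands: everything classifies as non-CpG context
  b0 <- simulate_annotation(sim$matrix$regions, sim$truth, n_cgis = 0,
                            seed = 4)
  cls <- classify_region(sim$matrix$regions, b0)
  expect_true(all(cls$cpg_context == "open_sea"))
  # determinism
  b2 <- simulate_annotation(sim$matrix$regions, sim$truth, planted_or = 1,
                            n_probes = 20, seed = 4)
  expect_identical(b$tfbs, b2$tfbs)
})

test_that("cohort simulator: determinism, null risk effect, planted slopes", {
  cfg <- cohort_sim_config(cohorts = list(A = 30), seed = 9)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_true(all(s1$cohort$MTOR >= 0 & s1$cohort$MTOR <= 100))

  # risk_effect all zero: group mean methylation equal within noise
  cfg0 <- cohort_sim_config(cohorts = list(A = 60), risk_effect = 0, seed = 10)
  s0 <- simulate_cohort(cfg0)
  gm <- tapply(s0$cohort$MTOR, s0$cohort$group, mean)
  se <- sd(s0$cohort$MTOR) / sqrt(60)
  expect_lt(max(gm) - min(gm), 3 * se * sqrt(2) * 2)

  # planted slope forces the decline class through the first/last classifier
  fu <- s1$followup
  sl <- vapply(split(fu, fu$subject), function(d) egfr_slope(d$time, d$egfr),
               numeric(1))[s1$cohort$subject]
  expect_equal(unname(sl), s1$cohort$slope_true, tolerance = 1e-10)
  expect_identical(classify_decline(unname(sl)), s1$cohort$decline_class)

  # albuminuria stage consistent with UACR for non-ESRD subjects
  co <- s1$cohort[!s1$cohort$esrd, ]
  expect_identical(unname(albuminuria_label(albuminuria_stage(co$uacr))),
                   co$baseline_stage)
})

test_that("cohort copula hits the target methylation-covariate correlation", {
  # Fisher-z bound: at n = 500 and rho = -0.4, realized r lies in
  # [-0.48, -0.32] with high probability
  cfg <- cohort_sim_config(cohorts = list(A = c(0, 500, 0, 0, 0)), seed = 21)
  s <- simulate_cohort(cfg)
  m <- rowMeans(s$cohort[, cfg$gene_names])
  r <- cor(m, s$cohort$hba1c)
  expect_gte(r, -0.48)
  expect_lte(r, -0.32)
  expect_error(
    cohort_sim_config(covariate_corr = c(hba1c = -1.2, egfr = 0.4,
                                         uacr = -0.3)), "unattainable")
})

test_that("prediction-data generator plants the intended AUC gap", {
  d <- simulate_prediction_data(n = 4000, seed = 3)
  clin <- fit_logistic(as.matrix(d[, 2:6]), d$outcome)
  full <- fit_logistic(as.matrix(d[, 2:7]), d$outcome)
  expect_lt(abs(roc_auc(clin$fitted, d$outcome) - 0.65), 0.04)
  expect_lt(abs(roc_auc(full$fitted, d$outcome) - 0.75), 0.04)
})
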