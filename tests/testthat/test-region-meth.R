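test_that("log-CPM normalization matches longhand arithmetic", {
  sim <- toy_matrix(n_regions = 50, n_per_group = 3, seed = 1)
  lc <- normalize_log_cpm(sim$matrix, pseudocount = 0.5)
  expect_equal(lc, oracle_log_cpm(sim$matrix$counts,
                                  sim$matrix$library_sizes, 0.5),
               tolerance = 1e-12)
  # spot values: count 1 at library 1e6 -> log2(1.5); count 0 -> log2(pseudo)
  m <- region_count_matrix(
    data.frame(chrom = "chrS", start = 0:1 * 100, end = 0:1 * 100 + 50),
    matrix(c(1L, 0L), 2, 1), 1e6,
    data.frame(group = "g1"))
  lc2 <- normalize_log_cpm(m, 0.5)
  expect_equal(lc2[1, 1], log2(1.5))
  expect_equal(lc2[2, 1], log2(0.5))
})

test_that("dispersion estimator: Poisson null, NB truth, zero variance", {
  cfgp <- region_sim_config(n_regions = 5000, n_per_group = 10,
                            group_labels = c("a", "b"), baseline_mean = 50,
                            dispersion = 0, seed = 2)
  expect_lte(estimate_dispersion(simulate_region_counts(cfgp)$matrix), 0.02)

  counts <- matrix(5L, 20, 6)  # constant within (and across) groups
  m <- region_count_matrix(
    data.frame(chrom = "chrS", start = 0:19 * 100, end = 0:19 * 100 + 50),
    counts, rep(1000, 6), data.frame(group = rep(c("a", "b"), each = 3)))
  expect_equal(estimate_dispersion(m), 0)
  expect_error(estimate_dispersion(m[, c(1, 2, 4, 5)]), NA)
  expect_error(
    estimate_dispersion(region_count_matrix(
      m$regions, counts[, 1:3], rep(1000, 3),
      data.frame(group = c("a", "a", "b")))), ">= 2 samples")
})

test_that("nb_exact_test agrees with the convolution oracle and limits", {
  set.seed(4)
  for (phi in c(0, 0.1, 0.5)) {
    for (i in 1:20) {
      a <- rpois(3, 5); b <- rpois(3, 5)
      expect_equal(nb_exact_test(a, b, phi), oracle_nb_exact(a, b, phi),
                   tolerance = 1e-10)
    }
  }
  # spec case: group sums 8 vs 2, n = 3 per group
  expect_equal(nb_exact_test(c(8, 0, 0), c(2, 0, 0), 0.1),
               oracle_nb_exact(c(8, 0, 0), c(2, 0, 0), 0.1),
               tolerance = 1e-10)
  # phi = 0 equals the Poisson-conditional binomial exact test
  p0 <- nb_exact_test(c(7, 1), c(1, 1), 0)
  x <- 0:10; pr <- dbinom(x, 10, 0.5)
  expect_equal(p0, sum(pr[pr <= pr[9] * (1 + 1e-12)]), tolerance = 1e-12)
  # balanced observed split is the mode
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), 0.3), 1)
  expect_error(nb_exact_test(c(-1, 2), c(1, 1), 0.1), "negative")
  expect_error(nb_exact_test(c(1, 2), c(1, 1), -0.1), "phi")
})

test_that("p-value is monotone in split imbalance at fixed total", {
  for (phi in c(0, 0.2)) {
    ps <- vapply(10:20, function(sa)
      nb_exact_test(c(sa), c(20 - sa), phi), numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("covariate adjustment removes covariates and is idempotent", {
  set.seed(6)
  n <- 40
  design <- data.frame(group = rep(c("a", "b"), each = n / 2),
                       age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.5))
  lc <- matrix(rnorm(30 * n), 30, n)
  lc <- lc + outer(rep(1, 30), design$age)  # planted age effect beta = 1
  res <- adjust_covariates(lc, design)
  cors <- apply(res, 1, function(r) cor(r, design$age))
  expect_true(all(abs(cors) < 0.05))
  expect_equal(adjust_covariates(res, design), res, tolerance = 1e-10)

  # constant covariates: residuals are the row-centered matrix
  dc <- data.frame(group = design$group, age = 1, sex = 0)
  expect_equal(adjust_covariates(lc, dc), lc - rowMeans(lc),
               tolerance = 1e-10)
  dd <- design; dd$age2 <- design$age * 2
  expect_error(adjust_covariates(lc, dd), "rank deficient")
})

test_that("call_dmrs recovers planted DMRs and respects alpha", {
  sim <- toy_matrix(n_regions = 600, n_per_group = 12, n_hypo_dmrs = 60,
                    dispersion = 0.1, seed = 8)
  d <- call_dmrs(sim$matrix, alpha = 0.01)
  planted <- d$region_id %in% sim$truth$region_id
  expect_gte(mean(d$significant[planted] & d$direction[planted] == "hypo"),
             0.8)
  expect_lte(mean(d$significant[!planted]), 0.05)
  expect_error(call_dmrs(sim$matrix, alpha = 0), "alpha")
  # alpha = 1: every region is significant
  d1 <- call_dmrs(sim$matrix, alpha = 1)
  expect_true(all(d1$significant))
})

test_that("cluster labels follow the significance pattern across case groups", {
  sim <- toy_matrix(n_regions = 400, n_per_group = 10,
                    groups = c("healthy", "Normo", "Macro", "ESRD"),
                    n_hypo_dmrs = 60, n_hyper_dmrs = 30, effect_fold = 3,
                    seed = 12)
  d <- call_dmrs(sim$matrix, alpha = 0.01)
  called <- merge(d[d$significant, ], sim$truth, by = "region_id")
  hyp <- called[called$direction.y == "hypo", ]
  # private hypo clusters should predominantly match the affected group
  match_frac <- mean(hyp$cluster == paste0("hypo_", hyp$affected_groups))
  expect_gte(match_frac, 0.7)
  hyper <- called[called$direction.y == "hyper", ]
  expect_gte(mean(hyper$cluster == "hyper_all"), 0.5)
})

test_that("profile clustering: exact distances and archetype recovery", {
  p <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1))
  cl <- cluster_dmr_profiles(p, k = 2)
  d <- as.matrix(cophenetic(cl$hclust))
  expect_equal(cl$labels[1], cl$labels[2])  # r = 1, merged first
  expect_equal(d[1, 3], 2, tolerance = 1e-12)  # r = -1 -> distance 2

  set.seed(13)
  arch <- matrix(rnorm(32), 4, 8)  # four well-separated profile archetypes
  x <- arch[rep(1:4, each = 25), ] + matrix(rnorm(800, 0, 0.2), 100)
  cl4 <- cluster_dmr_profiles(x, k = 4)
  truth <- rep(1:4, each = 25)
  # adjusted Rand via pair counting
  tab <- table(cl4$labels, truth)
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2)); n2 <- choose(100, 2)
  ari <- (a - b * cc / n2) / ((b + cc) / 2 - b * cc / n2)
  expect_gte(ari, 0.9)

  expect_warning(cluster_dmr_profiles(rbind(c(1, 1, 1, 1), p), k = 2),
                 "zero-variance")
  # labels invariant under region reordering
  perm <- sample(100)
  clp <- cluster_dmr_profiles(x[perm, ], k = 4)
  expect_equal(sort(as.integer(table(clp$labels))),
               sort(as.integer(table(cl4$labels))))
})

test_that("sample PCA separates groups, conserves variance, fixes signs", {
  sim <- toy_matrix(n_regions = 300, n_per_group = 8, n_hypo_dmrs = 150,
                    effect_fold = 3, seed = 14)
  lc <- normalize_log_cpm(sim$matrix)
  pc <- sample_pca(lc)
  g <- sim$matrix$design$group
  gap <- abs(mean(pc$scores[g == "healthy", 1]) -
             mean(pc$scores[g == "Normo", 1]))
  wsd <- sqrt(mean(tapply(pc$scores[, 1], g, var)))
  expect_gt(gap, 3 * wsd)
  # total score variance equals total (centered) data variance
  xc <- t(lc) - colMeans(t(lc))[col(t(lc))]
  expect_equal(sum(pc$scores^2), sum(xc^2), tolerance = 1e-8)
  expect_true(all(colSums(pc$loadings) >= -1e-10))
  # duplicated sample gets identical coordinates
  lc2 <- cbind(lc, lc[, 1])
  pc2 <- sample_pca(lc2)
  expect_equal(pc2$scores[1, ], pc2$scores[ncol(lc2), ], tolerance = 1e-8)
})
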