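# hand-built micro-fixture: one gene on each strand, one CpG island
micro_bundle <- function(promoter_window = 2000) {
  genes <- data.frame(chrom = "chrS",
                      start = c(10000L, 60000L), end = c(30000L, 80000L),
                      name = c("gplus", "gminus"), strand = c("+", "-"))
  exons <- data.frame(chrom = "chrS",
                      start = c(12000L, 25000L), end = c(12500L, 25600L),
                      name = c("gplus", "gplus"))
  cgis <- data.frame(chrom = "chrS", start = 40000L, end = 41000L,
                     name = "cgi1")
  annotation_bundle(genes = genes, exons = exons, cpg_islands = cgis,
                    promoter_window = promoter_window)
}

test_that("classify_region applies shore/shelf windows and precedence", {
  b <- micro_bundle()
  reg <- function(mid) data.frame(chrom = "chrS", start = mid - 10,
                                  end = mid + 10)
  # 500 bp past the island edge (last base 40999) -> shore
  expect_equal(classify_region(reg(41499), b)$cpg_context, "shore")
  # 3 kb past -> shelf
  expect_equal(classify_region(reg(43999), b)$cpg_context, "shelf")
  expect_equal(classify_region(reg(40500), b)$cpg_context, "CGI")
  # >5 kb from the island and >10 kb from genes -> intergenic open sea
  far <- classify_region(reg(99000), b)
  expect_equal(far$cpg_context, "open_sea")
  expect_equal(far$gene_context, "intergenic")
  expect_equal(as.character(far$primary), "intergenic")
  # inside an exon far from the TSS window
  ex <- classify_region(reg(25300), b)
  expect_equal(ex$gene_context, "exon")
  # in-gene, not exon, beyond promoter window -> intron
  expect_equal(classify_region(reg(20000), b)$gene_context, "intron")
  # promoter window around the minus-strand TSS at 79999
  expect_equal(classify_region(reg(79000), b)$gene_context, "promoter")
  # CGI inside an exon would still take CGI as primary (precedence)
  b2 <- annotation_bundle(
    genes = data.frame(chrom = "chrS", start = 39000L, end = 45000L,
                       name = "g", strand = "+"),
    exons = data.frame(chrom = "chrS", start = 40000L, end = 41000L,
                       name = "g"),
    cpg_islands = b$cpg_islands)
  hit <- classify_region(reg(40500), b2)
  expect_equal(as.character(hit$primary), "CGI")
  expect_error(classify_region(data.frame(chrom = "chrX", start = 1,
                                          end = 10), b), "unknown contig")
})

test_that("classify_region matches the linear-scan oracle on a large fixture", {
  sim <- toy_matrix(n_regions = 500, seed = 31)
  b <- simulate_annotation(sim$matrix$regions, sim$truth, n_genes = 150,
                           n_cgis = 80, seed = 32)
  got <- classify_region(sim$matrix$regions, b)
  want <- oracle_classify(sim$matrix$regions, b$genes, b$exons,
                          b$cpg_islands, b$promoter_window)
  expect_identical(got$gene_context, want$gene_context)
  expect_identical(got$cpg_context, want$cpg_context)
  expect_identical(as.character(got$primary), as.character(want$primary))
})

test_that("TSS distance profile is strand-aware and conserving", {
  b <- micro_bundle()
  # DMR midpoint at the plus-strand TSS
  d0 <- tss_distance_profile(data.frame(chrom = "chrS", start = 9990,
                                        end = 10010), b$genes,
                             bin_width = 1000, max_distance = 10000)
  expect_equal(sum(d0$counts[d0$mids > -1000 & d0$mids < 1000]), 1)
  # 5 kb 3' of the minus-strand TSS (79999): midpoint 74999 -> signed +5000
  d5 <- tss_distance_profile(data.frame(chrom = "chrS", start = 74989,
                                        end = 75009), b$genes)
  expect_equal(d5$distances, 5000)
  # conservation: histogram + excluded = total
  sim <- toy_matrix(n_regions = 300, seed = 33)
  bb <- simulate_annotation(sim$matrix$regions, sim$truth, seed = 34)
  h <- tss_distance_profile(sim$matrix$regions, bb$genes,
                            bin_width = 2000, max_distance = 20000)
  expect_equal(sum(h$counts) + h$excluded, 300)
  expect_error(tss_distance_profile(sim$matrix$regions,
                                    data.frame()[0, ]), "no genes")
})

test_that("probe proximity counts match the all-pairs oracle and nest", {
  set.seed(35)
  dmrs <- data.frame(chrom = "chrS",
                     start = sort(sample.int(1e6, 200)) * 1L)
  dmrs$end <- dmrs$start + 500L
  probes <- data.frame(chrom = "chrS", pos = sample.int(1.2e6, 500))
  wins <- c(0, 1000, 10000, 100000)
  got <- probe_proximity(probes, dmrs, wins)
  d <- oracle_probe_dist(probes$pos, dmrs)
  expect_equal(unname(got), vapply(wins, function(w) sum(d <= w), integer(1)))
  expect_true(all(diff(got) >= 0))
  # probe inside a DMR counts at every window including 0
  inside <- data.frame(chrom = "chrS", pos = dmrs$start[1] + 5)
  expect_equal(unname(probe_proximity(inside, dmrs, wins)), rep(1L, 4))
  expect_error(probe_proximity(probes, dmrs, c(-1, 10)), "negative window")
})

test_that("gene-set enrichment equals the hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = universe[1:5], all = universe)
  res <- geneset_enrichment(universe[1:5], universe, sets)
  # overlap 5 of 5 selected, set size 5 in universe 20
  expect_equal(res$p[res$set == "hit"],
               phyper(4, 5, 15, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p[res$set == "all"], 1)
  # spec example: universe 20, set 5, selected 5, overlap 4
  res4 <- geneset_enrichment(c(universe[1:4], universe[10]), universe,
                             list(s = universe[1:5]))
  manual <- sum(dhyper(4:5, 5, 15, 5))
  expect_equal(res4$p, manual, tolerance = 1e-12)
  # empty selection: p = 1 everywhere
  res0 <- geneset_enrichment(character(0), universe, sets)
  expect_true(all(res0$p == 1))
  expect_error(geneset_enrichment("nope", universe, sets), "absent")
  # BH q monotone in p, bounded by 1
  set.seed(36)
  many <- lapply(1:30, function(i) sample(universe, sample(3:8, 1)))
  names(many) <- paste0("s", 1:30)
  rm2 <- geneset_enrichment(sample(universe, 6), universe, many)
  o <- order(rm2$p)
  expect_true(all(diff(rm2$q[o]) >= -1e-12))
  expect_true(all(rm2$q <= 1))
})
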