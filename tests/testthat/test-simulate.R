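test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_sim_config(seed = 7, n_genes = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (f in basename(s1$files)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  s3 <- simulate_dataset(tiny_sim_config(seed = 8, n_genes = 10))
  expect_false(identical(s1$calls_H$meth, s3$calls_H$meth))
})

test_that("simulated genes are pairwise disjoint including their flanks", {
  for (seed in 1:3) {
    g <- simulate_annotation(tiny_sim_config(seed = seed, n_genes = 30))$genes
    g <- g[order(start)]
    expect_true(all(g$start[-1] - 3000 >= head(g$end, -1) + 3000))
    expect_true(all(g$start - 3000 >= 0))
    expect_true(all(g$end > g$start))
    expect_false(anyDuplicated(g$gene_id) > 0)
  }
})

test_that("strand assignment stays inside binomial bounds across seeds", {
  frac <- vapply(1:10, function(seed) {
    g <- simulate_annotation(tiny_sim_config(seed = seed, n_genes = 50))$genes
    mean(g$strand == "+")
  }, numeric(1))
  # pooled over 500 genes: 4 sd of Binomial(500, .5)
  expect_lt(abs(mean(frac) - 0.5), 4 * sqrt(0.25 / 500))
})

test_that("an explicit chromosome length that cannot hold the genes errors", {
  cfg <- tiny_sim_config(seed = 1, n_genes = 10, chrom_length = 1000L)
  expect_error(simulate_annotation(cfg), "too small")
})

test_that("empirical site levels converge to the truth at high coverage", {
  cfg <- tiny_sim_config(seed = 2, n_genes = 8, coverage_mean = 1000,
                         coverage_size = 1e6, dispersion = 1e-6,
                         n_samples_per_group = 4L,
                         dmr_injection = list(n_dmrs = 0L, effect_size = 0,
                                              width = 100L))
  sim <- simulate_dataset(cfg)
  pooled <- pool_calls(sim$calls_L)
  m <- merge(pooled[, .(pos0 = pos - 1L, emp = meth / total)],
             sim$truth[, .(pos0, true_level)], by = "pos0")
  expect_gt(nrow(m), 100)
  dev <- abs(m$emp - m$true_level)
  expect_lt(mean(dev), 0.02)          # law-of-large-numbers tolerance
  expect_lt(max(dev), 0.05)           # ~6 binomial se at 4 x 1000 reads
})

test_that("a zero true level never yields methylated reads", {
  cfg <- tiny_sim_config(seed = 3, n_genes = 12, prop_unmethylated = 0.5)
  sim <- simulate_dataset(cfg)
  zero_sites <- sim$truth[true_level == 0, pos0]
  expect_gt(length(zero_sites), 0)
  # group L sees the base truth (H additionally carries the DMR shifts)
  expect_true(all(sim$calls_L[(pos - 1L) %in% zero_sites, meth] == 0L))
})

test_that("without injected effects the H and L methylomes are exchangeable", {
  cfg <- tiny_sim_config(seed = 4, n_genes = 20,
                         dmr_injection = list(n_dmrs = 0L, effect_size = 0,
                                              width = 100L))
  sim <- simulate_dataset(cfg)
  h <- pool_calls(sim$calls_H)[, meth / total]
  l <- pool_calls(sim$calls_L)[, meth / total]
  expect_gt(suppressWarnings(stats::ks.test(h, l)$p.value), 0.01)
})

test_that("the TSS dip and region levels shape the true methylome", {
  cfg <- tiny_sim_config(seed = 5, n_genes = 15, prop_unmethylated = 0)
  sim <- simulate_dataset(cfg)
  tr <- merge(sim$truth[!is.na(gene_id) & context == "CG"],
              sim$genes[, .(gene_id, start, end, strand)], by = "gene_id")
  dtss <- tr[, data.table::fifelse(strand == "+", pos0 - start, end - 1L - pos0)]
  at_tss <- tr[abs(dtss) <= 50]
  far_body <- tr[dtss > 500 & pos0 >= start & pos0 < end]
  expect_gt(nrow(far_body), 0)
  expect_lt(mean(at_tss$true_level), mean(far_body$true_level))
  # CHG/CHH sites sit at the low non-CG level
  expect_lt(max(sim$truth[context != "CG", true_level]), 0.1)
})

test_that("injected DMRs shift the H methylome in the recorded direction", {
  cfg <- tiny_sim_config(seed = 6, n_genes = 25)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$dmr_truth), 5L)
  ph <- pool_calls(sim$calls_H); pl <- pool_calls(sim$calls_L)
  for (i in seq_len(nrow(sim$dmr_truth))) {
    s <- sim$dmr_truth$start[i]; e <- sim$dmr_truth$end[i]
    lh <- ph[pos - 1L >= s & pos - 1L < e & context == "CG", sum(meth) / sum(total)]
    ll <- pl[pos - 1L >= s & pos - 1L < e & context == "CG", sum(meth) / sum(total)]
    sgn <- if (sim$dmr_truth$direction[i] == "M+") 1 else -1
    expect_gt(sgn * (lh - ll), 0.2)  # nominal effect 0.4 minus sampling noise
  }
})

test_that("expression couples to methylation and carries the injected DEGs", {
  cfg <- sim_config(seed = 9, n_genes = 150,
                    dmr_injection = list(n_dmrs = 0L, effect_size = 0, width = 100L),
                    deg_injection = list(n_degs = 20L, log2fc_effect = 2),
                    prop_nonexpressed = 0)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$expression$rpkm >= 0))
  em <- sim$expression[, .(rpkm = mean(rpkm)), by = gene_id]
  up <- methylink:::.true_region_levels(sim$genes, sim$truth, 3000L)
  m <- merge(em, up, by = "gene_id")
  expect_lt(stats::cor(rank(m$upstream), rank(m$rpkm)), 0)
  # injected DEGs: H/L mean ratio centred on 4 for the up half
  eh <- sim$expression[startsWith(sample_id, "H"),
                       .(mh = mean(rpkm)), by = gene_id]
  el <- sim$expression[startsWith(sample_id, "L"),
                       .(ml = mean(rpkm)), by = gene_id]
  r <- merge(merge(eh, el, by = "gene_id"),
             sim$deg_truth[direction == "up"], by = "gene_id")
  expect_gt(nrow(r), 5)
  expect_equal(median(r$mh / r$ml), 4, tolerance = 0.35)
})

test_that("noise-free uncoupled expression is constant at baseline", {
  cfg <- tiny_sim_config(seed = 10, n_genes = 10, prop_nonexpressed = 0,
                         expr_coupling = list(baseline = 2, beta_upstream = 0,
                                              beta_body = 0, noise_sd = 0),
                         deg_injection = list(n_degs = 0L, log2fc_effect = 0))
  sim <- simulate_dataset(cfg)
  expect_true(all(abs(sim$expression$rpkm - exp(2)) < 1e-3))
})

test_that("the forced non-expressed stratum populates the 'non' class", {
  cfg <- sim_config(seed = 11, n_genes = 200)
  sim <- simulate_dataset(cfg)
  em <- sim$expression[, .(rpkm = mean(rpkm)), by = gene_id]
  frac_non <- mean(em$rpkm <= 1)
  expect_gt(frac_non, 0.15)
  expect_lt(frac_non, 0.40)
})

test_that(".true_region_levels recovers the configured profile plateaus", {
  cfg <- tiny_sim_config(seed = 12, n_genes = 20, gene_level_sd = 0,
                         prop_unmethylated = 0)
  ann <- simulate_annotation(cfg)
  truth <- true_site_levels(cfg, ann$genes, ann$sites)
  lv <- methylink:::.true_region_levels(ann$genes, truth, 3000L)
  # downstream flank sits at the body level; upstream mixes flank and dip
  expect_equal(median(lv$downstream, na.rm = TRUE), 0.75, tolerance = 0.03)
  expect_lt(median(lv$upstream, na.rm = TRUE), 0.68)
  expect_gt(median(lv$genebody, na.rm = TRUE), 0.6)
})
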