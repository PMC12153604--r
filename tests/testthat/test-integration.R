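test_that("region-expression correlation reports monotone relations exactly", {
  rm_ <- data.table::data.table(gene_id = paste0("g", 1:4),
                                level = c(.1, .2, .3, .4))
  up <- data.table::data.table(gene_id = paste0("g", 1:4),
                               rpkm = c(10, 20, 30, 40))
  expect_equal(region_expression_correlation(rm_, up)$rho, 1)
  dn <- data.table::data.table(gene_id = paste0("g", 1:4),
                               rpkm = c(40, 30, 20, 10))
  expect_equal(region_expression_correlation(rm_, dn)$rho, -1)
  # computed on the intersection of genes only
  extra <- rbind(up, data.table::data.table(gene_id = "g9", rpkm = 5))
  expect_equal(region_expression_correlation(rm_, extra)$n, 4L)
  expect_warning(r0 <- region_expression_correlation(rm_[1:2], up[1:2]),
                 "fewer than 3")
  expect_null(r0)
})

test_that("correlation_by_region stratifies by region and context", {
  set.seed(41)
  rm_ <- data.table::CJ(gene_id = paste0("g", 1:30),
                        region_class = c("upstream", "genebody"),
                        context = "CG")
  rm_[, level := runif(.N)]
  expr <- data.table::data.table(gene_id = paste0("g", 1:30), rpkm = runif(30))
  out <- correlation_by_region(rm_, expr)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$n == 30L))
  ref <- spearman_test(rm_[region_class == "upstream", level][order(rm_[region_class == "upstream", gene_id])],
                       expr$rpkm[order(expr$gene_id)])
  expect_equal(out[region_class == "upstream", rho], ref$rho)
})

test_that("expression change by DMR groups fold changes by position and direction", {
  links <- data.table::data.table(dmr_id = "d1", gene_id = "g1",
                                  region_class = "genebody", context = "CG",
                                  direction = "M+")
  degs <- data.table::data.table(gene_id = "g1", mean_H = 3, mean_L = 1,
                                 log2fc = 1.5, p_value = 0.2,
                                 direction_class = "none")
  out <- expression_change_by_dmr(links, degs)
  expect_equal(nrow(out$values), 1L)  # all genes contribute, not only DEGs
  expect_equal(out$values$dmr_direction, "UP_DMR")
  expect_equal(out$values$log2fc, 1.5)
  expect_equal(out$summary$median_log2fc, 1.5)

  none <- expression_change_by_dmr(links[0], degs)
  expect_equal(nrow(none$values), 0L)
})

test_that("a symmetric null leaves both DMR-direction medians near zero", {
  set.seed(43)
  n <- 500
  links <- data.table::data.table(
    dmr_id = sprintf("d%03d", 1:n), gene_id = sprintf("g%03d", 1:n),
    region_class = sample(c("upstream", "genebody", "downstream"), n, TRUE),
    context = "CG", direction = sample(c("M+", "M-"), n, TRUE))
  degs <- data.table::data.table(gene_id = sprintf("g%03d", 1:n),
                                 log2fc = rnorm(n, 0, 0.5))
  med <- expression_change_by_dmr(links, degs)$values[
    , .(m = median(log2fc)), by = dmr_direction]
  expect_true(all(abs(med$m) < 0.1))
})

test_that("quadrant counts tabulate distinct DEG-linked DMR pairs", {
  links <- data.table::data.table(
    dmr_id = c("d1", "d1", "d2", "d3"),
    gene_id = c("g1", "g1", "g2", "g3"),
    region_class = c("upstream", "upstream", "genebody", "genebody"),
    context = "CG", direction = c("M+", "M+", "M-", "M+"))
  degs <- data.table::data.table(
    gene_id = c("g1", "g2", "g3"),
    direction_class = c("special_down", "other_up", "none"))
  q <- quadrant_table(links, degs)
  # duplicate identical link rows count once
  expect_equal(q[region_class == "upstream" & expr_dir == "E-" &
                   meth_dir == "M+", count], 1L)
  expect_equal(q[region_class == "genebody" & expr_dir == "E+" &
                   meth_dir == "M-", count], 1L)
  # genes without a DEG direction are excluded; totals = DEG-linked links
  expect_equal(sum(q$count), 2L)
  expect_true(all(q$count >= 0L))
  # zero-filled full grid over regions and quadrants
  expect_equal(nrow(q), 12L)
})

test_that("hypergeometric enrichment p equals the exact upper tail", {
  sets <- list(list(set_id = "S1", name = "five", members = paste0("g", 1:5)))
  background <- paste0("g", 1:20)
  study <- c("g1", "g2", "g3", "g10", "g11")  # k = 3 of K = 5
  res <- hypergeometric_enrichment(study, sets, background)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$k, 3L)
  expect_equal(res$fold, (3 / 5) / (5 / 20))

  # k = 0 is the certain upper tail
  res0 <- hypergeometric_enrichment(paste0("g", 16:20),
                                    list(list(set_id = "S", name = "",
                                              members = paste0("g", 1:5))),
                                    background)
  expect_equal(res0$p_value, 1)

  # study = background: k = K, p = 1
  resF <- hypergeometric_enrichment(background, sets, background)
  expect_equal(resF$p_value, 1)
  expect_equal(resF$k, 5L)

  expect_error(hypergeometric_enrichment(character(), sets, background), "empty")
  expect_error(hypergeometric_enrichment("zz", sets, background), "missing from background")
  # set vanishing after intersection with the background is skipped
  res_skip <- hypergeometric_enrichment(
    study, list(list(set_id = "S0", name = "", members = "outside")), background)
  expect_equal(nrow(res_skip), 0L)
})

test_that("enrichment matches brute-force enumeration over small universes", {
  set.seed(47)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    background <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    members <- sample(background, K)
    study <- sample(background, n)
    res <- hypergeometric_enrichment(
      study, list(list(set_id = "S", name = "", members = members)), background)
    k <- length(intersect(study, members))
    expect_equal(res$p_value, brute_hyper_upper(k, N, K, n), tolerance = 1e-12)
  }
})
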