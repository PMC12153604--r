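test_that("region methylation is the read-weighted level over qualifying sites", {
  g <- make_genes(100, 400, "+")
  regions <- gene_regions(g, flank_size = 50L)
  calls <- make_calls(pos = c(151, 201), meth = c(3, 7), total = c(10, 10))
  rm_ <- region_methylation(calls, regions, min_coverage = 1L)
  expect_equal(rm_$level, 0.5)     # 10/20
  expect_equal(rm_$n_sites, 2L)
  expect_equal(rm_$region_class, "genebody")

  all0 <- region_methylation(make_calls(151, 0, 10), regions, min_coverage = 1L)
  expect_equal(all0$level, 0)
  all1 <- region_methylation(make_calls(151, 10, 10), regions, min_coverage = 1L)
  expect_equal(all1$level, 1)
  # zero covered sites -> no record
  none <- region_methylation(make_calls(151, 1, 2), regions, min_coverage = 4L)
  expect_equal(nrow(none), 0L)
})

test_that("region methylation matches a brute-force per-site loop on random fixtures", {
  set.seed(21)
  for (i in 1:10) {
    n <- 50
    calls <- make_calls(pos = sample(1:1000, n),
                        meth = rbinom(n, 10, 0.4), total = 10,
                        context = sample(c("CG", "CHG"), n, replace = TRUE))
    calls$total <- calls$meth + rbinom(n, 5, 0.5)  # varying coverage
    calls <- calls[calls$total > 0]
    g <- make_genes(300, 700, "+")
    regions <- gene_regions(g, flank_size = 200L)
    got <- region_methylation(calls, regions, contexts = "CG", min_coverage = 3L)
    for (rc in c("upstream", "genebody", "downstream")) {
      span <- regions[region_class == rc]
      want <- brute_region_level(calls, span$start, span$end, "CG", 3L)
      have <- got[region_class == rc]
      if (is.null(want)) {
        expect_equal(nrow(have), 0L)
      } else {
        expect_equal(have$level, want$level)
        expect_equal(have$n_sites, want$n_sites)
      }
    }
  }
})

test_that("metagene profile averages per-site levels within bins", {
  g <- make_genes(5000, 8000, "+")
  grouping <- data.table::data.table(gene_id = "g1", group_label = "high")
  # constant per-site level 0.5 everywhere -> every bin mean 0.5
  pos <- seq(2001, 11000, by = 37)
  prof <- metagene_profile(make_calls(pos, 5, 10), g, grouping, min_coverage = 1L)
  expect_true(all(prof$mean_level == 0.5))
  # single CG at TSS+10 with 2/10 -> first body bin mean 0.2, nothing else
  prof1 <- metagene_profile(make_calls(5011, 2, 10), g, grouping, min_coverage = 1L)
  expect_equal(nrow(prof1), 1L)
  expect_equal(prof1$bin_index, 30L)
  expect_equal(prof1$mean_level, 0.2)
})

test_that("metagene profile of a '-' gene mirrors its '+' image", {
  set.seed(5)
  pos <- sort(sample(2000:11000, 120))
  meth <- rbinom(120, 10, 0.6)
  grouping <- data.table::data.table(gene_id = "g1", group_label = "x")
  p_plus <- metagene_profile(make_calls(pos, meth, 10),
                             make_genes(5000, 8000, "+"), grouping,
                             min_coverage = 1L)
  # mirror 1-based positions around the profiled span [2000, 11000)
  mirrored <- 13001 - pos
  p_minus <- metagene_profile(make_calls(sort(mirrored), rev(meth), 10),
                              make_genes(5000, 8000, "-"), grouping,
                              min_coverage = 1L)
  merged <- merge(p_plus, p_minus, by = "bin_index")
  expect_equal(nrow(merged), nrow(p_plus))
  expect_equal(merged$mean_level.x, merged$mean_level.y)
})

test_that("methylation classes: zeros are None, the rest split into near-equal thirds", {
  lv <- data.table::data.table(gene_id = paste0("g", 1:7),
                               level = c(0, .1, .2, .3, .4, .5, .6))
  cls <- methylation_binning(lv)
  expect_equal(as.character(cls[order(level)]$meth_class),
               c("None", "Low", "Low", "Middle", "Middle", "High", "High"))

  allz <- methylation_binning(data.table::data.table(gene_id = c("a", "b"),
                                                     level = c(0, 0)))
  expect_true(all(allz$meth_class == "None"))

  # 7 non-zero genes -> sizes (3, 2, 2), remainder to Low
  lv7 <- data.table::data.table(gene_id = paste0("g", 1:7),
                                level = seq(.1, .7, by = .1))
  tab <- table(methylation_binning(lv7)$meth_class)
  expect_equal(unname(tab[c("Low", "Middle", "High")]), c(3L, 2L, 2L),
               ignore_attr = TRUE)
})

test_that("methylation classes are monotone in level with balanced extremes", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(4:200, 1)
    lv <- data.table::data.table(gene_id = sprintf("g%03d", 1:n),
                                 level = round(runif(n) * rbinom(n, 1, 0.8), 3))
    cls <- methylation_binning(lv)
    tab <- table(cls$meth_class)
    expect_lte(abs(tab[["Low"]] - tab[["High"]]), 1)
    for (pair in list(c("Low", "Middle"), c("Middle", "High"))) {
      lo <- cls[meth_class == pair[1], level]
      hi <- cls[meth_class == pair[2], level]
      if (length(lo) && length(hi)) expect_lte(max(lo), min(hi))
    }
    expect_true(all(cls[meth_class == "None", level] == 0))
  }
})

test_that("expression histogram conserves gene counts and bins log10(rpkm+1)", {
  expr <- data.table::data.table(gene_id = paste0("g", 1:6),
                                 rpkm = c(0, 0, 9, 3, 99, 0.5))
  cls <- methylation_binning(data.table::data.table(
    gene_id = paste0("g", 1:6), level = c(0, .2, .4, .6, .8, .1)))
  h <- expression_histogram_by_meth_class(expr, cls)
  expect_equal(sum(h$count), 6L)
  # rpkm 9 -> log10(10) = 1.0 -> bin 10 at width 0.1
  expect_equal(h[count > 0][meth_class == "Middle" & expr_bin == 10, count], 1L)
  # all-zero expression collapses to the zero bin for every class
  z <- expression_histogram_by_meth_class(
    data.table::data.table(gene_id = cls$gene_id, rpkm = 0), cls)
  expect_true(all(z$expr_bin == 0))
  expect_equal(sum(z$count), 6L)
})
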