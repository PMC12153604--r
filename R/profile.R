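#' Pool methylation calls across samples
#'
#' Sums methylated and total read counts per site (chrom, pos, context)
#' across the supplied samples and relabels the result.
#'
#' @param calls call `data.table` (possibly several samples).
#' @param label `sample_id` given to the pooled calls.
#' @return pooled call `data.table` (strand kept from the first occurrence).
#' @export
pool_calls <- function(calls, label = "pooled") {
  pooled <- calls[, .(strand = strand[1L], meth = sum(meth), total = sum(total)),
                  by = .(chrom, pos, context)]
  pooled[, sample_id := label]
  data.table::setcolorder(pooled, c("chrom", "pos", "strand", "context",
                                    "meth", "total", "sample_id"))
  pooled[]
}

#' Weighted methylation level per gene region
#'
#' For every (gene, region, sample, context) combination the weighted level
#' is the sum of methylated read counts divided by the sum of total read
#' counts over all qualifying sites (context in `contexts`, coverage >=
#' `min_coverage`, position inside the region). Regions with no qualifying
#' site yield no row.
#'
#' @param calls call `data.table` (1-based `pos`).
#' @param regions region `data.table` from [gene_regions()].
#' @param contexts contexts to include (default `"CG"`).
#' @param min_coverage minimum total read count per site (default 4).
#' @return `data.table` with `gene_id`, `region_class`, `sample_id`,
#'   `context`, `level`, `n_sites`.
#' @export
region_methylation <- function(calls, regions, contexts = "CG", min_coverage = 4L) {
  stopifnot(min_coverage >= 1L)
  cc <- calls[context %in% contexts & total >= min_coverage]
  if (nrow(cc) == 0L) {
    return(data.table::data.table(gene_id = character(), region_class = character(),
                                  sample_id = character(), context = character(),
                                  level = numeric(), n_sites = integer()))
  }
  cc <- data.table::copy(cc)[, pos0 := pos - 1L]
  reg <- data.table::as.data.table(regions)
  hits <- cc[reg, on = .(chrom, pos0 >= start, pos0 < end), nomatch = NULL,
             .(gene_id = i.gene_id, region_class = i.region_class,
               sample_id = x.sample_id, context = x.context,
               meth = x.meth, total = x.total)]
  out <- hits[, .(level = sum(meth) / sum(total), n_sites = .N),
              by = .(gene_id, region_class, sample_id, context)]
  out[]
}

#' Metagene methylation profile by gene group
#'
#' Averages per-site methylation levels (`meth / total`) within metagene
#' bins across all genes of each group. Genes shorter than `n_body` bp are
#' excluded (their body bins would be empty); ungrouped genes are ignored.
#' Bins with no qualifying site are absent from the result.
#'
#' @param calls call `data.table`.
#' @param genes gene `data.table`.
#' @param grouping `data.table` (`gene_id`, `group_label`) naming the gene
#'   groups to profile.
#' @param n_flank,n_body bin counts (defaults 30 and 60).
#' @param flank_size flank width in bp.
#' @param contexts contexts to include.
#' @param min_coverage minimum total read count per site.
#' @return `data.table` with `group_label`, `bin_index`, `mean_level`,
#'   `n_sites`, `context`.
#' @export
metagene_profile <- function(calls, genes, grouping, n_flank = 30L, n_body = 60L,
                             flank_size = 3000L, contexts = "CG", min_coverage = 4L) {
  g <- data.table::as.data.table(genes)[end - start >= n_body]
  g <- g[gene_id %in% grouping$gene_id]
  cc <- calls[context %in% contexts & total >= min_coverage]
  empty <- data.table::data.table(group_label = character(), bin_index = integer(),
                                  mean_level = numeric(), n_sites = integer(),
                                  context = character())
  if (nrow(g) == 0L || nrow(cc) == 0L) return(empty)
  cc <- data.table::copy(cc)[, pos0 := pos - 1L]
  win <- g[, .(gene_id, chrom, gstart = start, gend = end, gstrand = strand,
               start = start - flank_size, end = end + flank_size)]
  hits <- cc[win, on = .(chrom, pos0 >= start, pos0 < end), nomatch = NULL,
             .(gene_id = i.gene_id, gstart = i.gstart, gend = i.gend,
               gstrand = i.gstrand, pos0 = x.pos0, context = x.context,
               meth = x.meth, total = x.total)]
  if (nrow(hits) == 0L) return(empty)
  hits[, bin_index := site_to_bin(pos0, gstart[1L], gend[1L], gstrand[1L],
                                  n_flank = n_flank, n_body = n_body,
                                  flank_size = flank_size),
       by = gene_id]
  hits <- merge(hits, data.table::as.data.table(grouping),
                by = "gene_id", allow.cartesian = TRUE)
  out <- hits[!is.na(bin_index),
              .(mean_level = mean(meth / total), n_sites = .N),
              by = .(group_label, bin_index, context)]
  data.table::setcolorder(out, c("group_label", "bin_index", "mean_level",
                                 "n_sites", "context"))
  out[order(group_label, context, bin_index)][]
}

#' Rank-based methylation classes (None / Low / Middle / High)
#'
#' Genes whose level is exactly zero (or <= `eps`) form the None class; the
#' remaining genes are sorted ascending by level and split into three
#' contiguous rank groups whose sizes differ by at most one, the remainder
#' going to the lower classes first. Ties at group boundaries are broken by
#' gene id order, so the split is deterministic.
#'
#' @param levels `data.table` (`gene_id`, `level`) with one row per gene.
#' @param eps non-methylation threshold (default 0: only exact zeros).
#' @return `data.table` with `gene_id`, `level`, `meth_class` (factor
#'   None < Low < Middle < High).
#' @export
methylation_binning <- function(levels, eps = 0) {
  lv <- data.table::as.data.table(levels)
  cls_levels <- c("None", "Low", "Middle", "High")
  if (nrow(lv) == 0L) {
    return(data.table::data.table(gene_id = character(), level = numeric(),
                                  meth_class = factor(character(), levels = cls_levels)))
  }
  stopifnot(!anyDuplicated(lv$gene_id))
  lv <- lv[order(level, gene_id)]
  lv[, meth_class := NA_character_]
  lv[level <= eps, meth_class := "None"]
  idx <- which(is.na(lv$meth_class))
  n <- length(idx)
  if (n > 0L) {
    q <- n %/% 3L; r <- n %% 3L
    sizes <- q + as.integer(seq_len(3L) <= r)  # remainder to Low first
    lv$meth_class[idx] <- rep(c("Low", "Middle", "High"), times = sizes)
  }
  lv[, meth_class := factor(meth_class, levels = cls_levels, ordered = TRUE)]
  lv[]
}

#' Expression-frequency histogram stratified by methylation class
#'
#' Counts genes per (methylation class, expression bin), where expression is
#' `log10(rpkm + 1)` binned at `binwidth`. Only genes present in both inputs
#' contribute.
#'
#' @param expr_mean `data.table` (`gene_id`, `rpkm`) of per-gene mean
#'   expression.
#' @param meth_classes output of [methylation_binning()].
#' @param binwidth histogram bin width on the log10 scale (default 0.1).
#' @return `data.table` with `meth_class`, `expr_bin` (bin index),
#'   `bin_mid` (bin midpoint on the log10(rpkm+1) scale), `count`.
#' @export
expression_histogram_by_meth_class <- function(expr_mean, meth_classes,
                                               binwidth = 0.1) {
  stopifnot(binwidth > 0)
  dt <- merge(data.table::as.data.table(expr_mean)[, .(gene_id, rpkm)],
              data.table::as.data.table(meth_classes)[, .(gene_id, meth_class)],
              by = "gene_id")
  dt[, expr_bin := as.integer(floor(log10(rpkm + 1) / binwidth))]
  out <- dt[, .(count = .N), by = .(meth_class, expr_bin)]
  out[, bin_mid := (expr_bin + 0.5) * binwidth]
  data.table::setcolorder(out, c("meth_class", "expr_bin", "bin_mid", "count"))
  out[order(meth_class, expr_bin)][]
}
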