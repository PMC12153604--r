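#' Region-wise Spearman correlation between methylation and expression
#'
#' Correlates per-gene region methylation with per-gene mean expression on
#' the intersection of genes carrying both values, using [spearman_test()]
#' (average ranks; exact permutation p for n <= 9, t approximation
#' otherwise). Fewer than 3 shared genes yields no result, with a warning.
#'
#' @param region_meth `data.table` (`gene_id`, `level`) for one region and
#'   context.
#' @param expression `data.table` (`gene_id`, `rpkm`) of mean expression.
#' @return list with `rho`, `p_value`, `n`, or `NULL` when n < 3.
#' @export
region_expression_correlation <- function(region_meth, expression) {
  dt <- merge(data.table::as.data.table(region_meth)[, .(gene_id, level)],
              data.table::as.data.table(expression)[, .(gene_id, rpkm)],
              by = "gene_id")
  if (nrow(dt) < 3L) {
    warning("fewer than 3 genes with both methylation and expression; no correlation")
    return(NULL)
  }
  r <- spearman_test(dt$level, dt$rpkm)
  list(rho = r$rho, p_value = r$p_value, n = r$n)
}

#' Spearman correlation per region class and context
#'
#' Convenience wrapper applying [region_expression_correlation()] to each
#' (region_class, context) stratum of a region-methylation table.
#'
#' @param region_meth output of [region_methylation()] (one sample or
#'   pooled).
#' @param expression `data.table` (`gene_id`, `rpkm`).
#' @return `data.table` with `region_class`, `context`, `rho`, `p_value`, `n`.
#' @export
correlation_by_region <- function(region_meth, expression) {
  rm <- data.table::as.data.table(region_meth)
  rm[, {
    r <- suppressWarnings(region_expression_correlation(.SD, expression))
    if (is.null(r)) NULL else data.table::data.table(rho = r$rho, p_value = r$p_value, n = r$n)
  }, by = .(region_class, context)]
}

#' Expression change of genes grouped by DMR position and direction
#'
#' For every (DMR, gene) link, records the gene's log2 fold change under the
#' DMR's positional class and direction (`UP_DMR` for hypermethylated in H,
#' `DOWN_DMR` for hypomethylated); all genes with a fold change contribute,
#' not only significant ones. Medians summarise each cell.
#'
#' @param links output of [link_dmrs_to_genes()].
#' @param degs output of [deg_table()].
#' @return list with `values` (per-link records: `region_class`,
#'   `dmr_direction`, `context`, `gene_id`, `log2fc`) and `summary`
#'   (`region_class`, `dmr_direction`, `context`, `median_log2fc`, `n`).
#' @export
expression_change_by_dmr <- function(links, degs) {
  lk <- data.table::as.data.table(links)
  empty <- data.table::data.table(region_class = character(),
                                  dmr_direction = character(),
                                  context = character(), gene_id = character(),
                                  log2fc = numeric())
  if (nrow(lk) == 0L) {
    empty_sum <- data.table::data.table(region_class = character(),
                                        dmr_direction = character(),
                                        context = character(),
                                        median_log2fc = numeric(), n = integer())
    return(list(values = empty, summary = empty_sum))
  }
  lk[, dmr_direction := data.table::fifelse(direction == "M+", "UP_DMR", "DOWN_DMR")]
  values <- merge(lk[, .(dmr_id, gene_id, region_class, context, dmr_direction)],
                  data.table::as.data.table(degs)[, .(gene_id, log2fc)],
                  by = "gene_id")
  values <- values[, .(region_class, dmr_direction, context, gene_id, log2fc)]
  summary <- values[, .(median_log2fc = median(log2fc), n = .N),
                    by = .(region_class, dmr_direction, context)]
  list(values = values[], summary = summary[order(region_class, dmr_direction)][])
}

#' E+/E- by M+/M- quadrant counts of DMR-DEG links
#'
#' Cross-tabulates distinct (gene, DMR) links by context, positional class,
#' expression direction (E+ = special_up or other_up, E- = special_down or
#' other_down) and methylation direction (M+/M-). Genes without a DEG
#' direction are excluded. The full grid over observed contexts and regions
#' is returned, zero-filled.
#'
#' @param links output of [link_dmrs_to_genes()].
#' @param degs output of [deg_table()].
#' @return `data.table` with `context`, `region_class`, `expr_dir`,
#'   `meth_dir`, `count`.
#' @export
quadrant_table <- function(links, degs) {
  lk <- unique(data.table::as.data.table(links)[, .(dmr_id, gene_id, region_class,
                                                    context, direction)])
  dg <- data.table::as.data.table(degs)[direction_class != "none",
                                        .(gene_id, direction_class)]
  empty <- data.table::data.table(context = character(), region_class = character(),
                                  expr_dir = character(), meth_dir = character(),
                                  count = integer())
  if (nrow(lk) == 0L || nrow(dg) == 0L) return(empty)
  dg[, expr_dir := data.table::fifelse(direction_class %in% c("special_up", "other_up"),
                                       "E+", "E-")]
  dt <- merge(lk, dg, by = "gene_id")
  if (nrow(dt) == 0L) return(empty)
  dt[, meth_dir := direction]
  grid <- data.table::CJ(context = unique(dt$context),
                         region_class = c("upstream", "genebody", "downstream"),
                         expr_dir = c("E+", "E-"), meth_dir = c("M+", "M-"))
  counts <- dt[, .(count = .N), by = .(context, region_class, expr_dir, meth_dir)]
  out <- merge(grid, counts, by = names(grid), all.x = TRUE)
  out[is.na(count), count := 0L]
  out[order(context, region_class, expr_dir, meth_dir)][]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of a study gene list against each gene
#' set, relative to a background universe: `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)` where `N` is the background size, `K` the
#' set size after intersection with the background, `n` the study size and
#' `k` the study/set overlap. Sets empty after intersection are skipped.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `background`; non-empty).
#' @param gene_sets list of gene sets as from [read_gene_sets()].
#' @param background character vector: the gene universe.
#' @param method `"none"` (default) or `"BH"` to add a `q_value` column.
#' @return `data.table` sorted by p-value with `set_id`, `name`, `k`,
#'   `n_study`, `K`, `N_background`, `fold`, `p_value` (and `q_value`).
#' @export
hypergeometric_enrichment <- function(study, gene_sets, background,
                                      method = c("none", "BH")) {
  method <- match.arg(method)
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0L) stop("empty study gene list")
  outside <- setdiff(study, background)
  if (length(outside)) stop("study genes missing from background: ",
                            paste(head(outside, 3), collapse = ", "))
  N <- length(background)
  n <- length(study)
  rows <- lapply(gene_sets, function(s) {
    members <- intersect(unique(s$members), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(study, members))
    data.table::data.table(
      set_id = s$set_id, name = s$name, k = k, n_study = n, K = K,
      N_background = N, fold = (k / n) / (K / N),
      p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.table::data.table(set_id = character(), name = character(),
                                  k = integer(), n_study = integer(),
                                  K = integer(), N_background = integer(),
                                  fold = numeric(), p_value = numeric()))
  }
  out <- data.table::rbindlist(rows)
  if (method == "BH") out[, q_value := p.adjust(p_value, method = "BH")]
  out[order(p_value)][]
}
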