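#' Validate a pipeline configuration
#'
#' A configuration is a named list (or JSON file) with input paths and
#' parameters. Required: `annotation` (path), `annotation_format`
#' ("bed"/"gtf"), `methylation_calls` (named list/vector sample_id -> path),
#' `expression` (path), `groups` (named sample -> "H"/"L"; inferred from
#' leading H/L in sample names when absent), `output_dir`. Optional:
#' `gene_sets` (GMT path), `flank_size`, `n_flank_bins`, `n_body_bins`,
#' `min_coverage`, `contexts`, `window`, `step`, `min_sites`, `min_diff`,
#' `alpha_dmr`, `alpha_deg`, `expr_threshold`, `binwidth`.
#'
#' @param config named list or path to a JSON file.
#' @return the completed configuration list (defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  .fail <- function(...) stop(structure(class = c("methylink_validation_error",
                                                  "error", "condition"),
                                        list(message = paste0(...), call = NULL)))
  for (f in c("annotation", "methylation_calls", "expression", "output_dir")) {
    if (is.null(config[[f]])) .fail("config field missing: ", f)
  }
  calls <- unlist(config$methylation_calls)
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    .fail("methylation_calls must be named by sample_id")
  }
  for (p in c(config$annotation, config$expression, calls, config$gene_sets)) {
    if (!file.exists(p)) .fail("input file not found: ", p)
  }
  if (is.null(config$groups)) {
    config$groups <- setNames(substr(names(calls), 1L, 1L), names(calls))
  }
  config$groups <- unlist(config$groups)
  if (!all(config$groups %in% c("H", "L"))) .fail("groups must map samples to 'H' or 'L'")
  if (!all(names(calls) %in% names(config$groups))) .fail("every sample needs a group")
  defaults <- list(annotation_format = "bed", flank_size = 3000L,
                   n_flank_bins = 30L, n_body_bins = 60L, min_coverage = 4L,
                   contexts = "CG", dmr_contexts = c("CG", "CHG", "CHH"),
                   window = 200L, step = 50L, min_sites = 4L, min_diff = 0.1,
                   alpha_dmr = 0.05, alpha_deg = 0.05, expr_threshold = 1,
                   binwidth = 0.1, pseudocount = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config$methylation_calls <- calls
  config
}

#' Run the full methylome-transcriptome pipeline
#'
#' Reads every input, derives gene regions, quantifies region methylation
#' per sample and per group, builds metagene profiles stratified by
#' expression class and by DEG direction class, computes methylation classes
#' and the expression histogram, calls DMRs between groups H and L, links
#' them to genes, cross-tabulates the E/M quadrants, correlates region
#' methylation with expression, and (when gene sets are supplied) runs
#' hypergeometric enrichment of the differentially methylated and expressed
#' genes (DMEGs). All result tables are written as TSV into `output_dir`
#' together with a JSON manifest of parameters and input checksums.
#'
#' @param config named list or JSON path (see [validate_config()]).
#' @return invisibly, a named list of the in-memory result tables.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(msg) message(format(Sys.time(), "%H:%M:%S"), " [", msg, "]")

  stage("read inputs")
  genes <- read_gene_annotation(config$annotation, config$annotation_format)
  calls <- data.table::rbindlist(lapply(names(config$methylation_calls), function(s) {
    read_methylation_calls(config$methylation_calls[[s]], s)
  }))
  expr <- read_expression_table(config$expression)
  groups <- config$groups
  h_samples <- names(groups)[groups == "H"]
  l_samples <- names(groups)[groups == "L"]

  stage("gene regions")
  regions <- gene_regions(genes, flank_size = config$flank_size)

  stage("region methylation")
  pooled_all <- pool_calls(calls, "all")
  rme_all <- region_methylation(pooled_all, regions, contexts = config$contexts,
                                min_coverage = config$min_coverage)
  rme_sample <- region_methylation(calls, regions, contexts = config$contexts,
                                   min_coverage = config$min_coverage)

  stage("expression classes + DEG")
  expr_mean <- expr[, .(rpkm = mean(rpkm)), by = gene_id]
  expr_classes <- expr_mean[, .(gene_id, rpkm,
                                expr_class = expression_binning(rpkm))]
  degs <- deg_table(expr, groups, alpha = config$alpha_deg,
                    pseudocount = config$pseudocount,
                    expr_threshold = config$expr_threshold)

  stage("metagene profiles")
  prof_expr <- metagene_profile(
    pooled_all, genes,
    expr_classes[, .(gene_id, group_label = as.character(expr_class))],
    n_flank = config$n_flank_bins, n_body = config$n_body_bins,
    flank_size = config$flank_size, contexts = config$contexts,
    min_coverage = config$min_coverage)
  deg_grouping <- degs[direction_class != "none",
                       .(gene_id, group_label = direction_class)]
  prof_deg <- metagene_profile(
    pooled_all, genes, deg_grouping,
    n_flank = config$n_flank_bins, n_body = config$n_body_bins,
    flank_size = config$flank_size, contexts = config$contexts,
    min_coverage = config$min_coverage)

  stage("methylation classes + histogram")
  body_levels <- rme_all[region_class == "genebody", .(gene_id, level)]
  meth_classes <- methylation_binning(body_levels)
  hist_tbl <- expression_histogram_by_meth_class(expr_mean, meth_classes,
                                                 binwidth = config$binwidth)

  stage("DMR calling")
  dmrs <- call_dmrs(calls[sample_id %in% h_samples],
                    calls[sample_id %in% l_samples],
                    contexts = config$dmr_contexts, window = config$window,
                    step = config$step, min_sites = config$min_sites,
                    min_diff = config$min_diff, alpha = config$alpha_dmr)
  links <- link_dmrs_to_genes(dmrs, genes, flank_size = config$flank_size)

  stage("integration")
  corr <- correlation_by_region(
    rme_all[, .(gene_id, region_class, context, level)], expr_mean)
  quad <- quadrant_table(links, degs)
  expr_change <- expression_change_by_dmr(links, degs)

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    stage("enrichment")
    sets <- read_gene_sets(config$gene_sets)
    background <- intersect(genes$gene_id, unique(expr$gene_id))
    dmegs <- intersect(unique(links$gene_id),
                       degs[direction_class != "none", gene_id])
    dmegs <- intersect(dmegs, background)
    if (length(dmegs) > 0L) {
      enrichment <- hypergeometric_enrichment(dmegs, sets, background)
    }
  }

  stage("write outputs")
  w <- function(x, f) data.table::fwrite(x, file.path(out_dir, f), sep = "\t")
  w(regions, "gene_regions.tsv")
  w(rme_all, "region_methylation_pooled.tsv")
  w(rme_sample, "region_methylation_per_sample.tsv")
  w(expr_classes, "expression_classes.tsv")
  w(degs, "deg_table.tsv")
  w(prof_expr, "metagene_by_expression_class.tsv")
  w(prof_deg, "metagene_by_deg_class.tsv")
  w(meth_classes, "methylation_classes.tsv")
  w(hist_tbl, "expression_histogram.tsv")
  w(dmrs, "dmrs.tsv")
  write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
  w(links, "dmr_gene_links.tsv")
  w(corr, "correlation_by_region.tsv")
  w(quad, "quadrant_counts.tsv")
  w(expr_change$values, "expression_change_by_dmr.tsv")
  w(expr_change$summary, "expression_change_by_dmr_summary.tsv")
  if (!is.null(enrichment)) w(enrichment, "enrichment.tsv")

  inputs <- c(config$annotation, config$expression, config$methylation_calls,
              config$gene_sets)
  manifest <- list(
    package = "methylink",
    version = as.character(utils::packageVersion("methylink")),
    parameters = config[setdiff(names(config), c("methylation_calls", "groups"))],
    groups = as.list(config$groups),
    inputs = as.list(tools::md5sum(unlist(inputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(regions = regions, region_methylation = rme_all,
                 region_methylation_per_sample = rme_sample,
                 expression_classes = expr_classes, degs = degs,
                 metagene_by_expression = prof_expr,
                 metagene_by_deg = prof_deg, methylation_classes = meth_classes,
                 expression_histogram = hist_tbl, dmrs = dmrs, links = links,
                 correlation = corr, quadrants = quad,
                 expression_change = expr_change, enrichment = enrichment))
}
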