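#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' two-group (H/L, 4 samples each) WGBS + expression study on one
#' chromosome: high flank/body CG methylation with a pronounced TSS dip,
#' expression negatively coupled to upstream methylation and positively to
#' gene-body methylation, plus injected DMRs (H-group shifts) and DEGs.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_genes number of non-overlapping genes.
#' @param gene_length_range min/max gene length in bp.
#' @param intergenic_gap_mean mean extra gap between gene neighbourhoods, bp.
#' @param chrom_length optional chromosome length; computed from the layout
#'   when `NULL`, and an error when too small for the genes plus flanks.
#' @param flank_size flank width in bp (3 kb).
#' @param cpg_spacing_mean mean gap between cytosine sites (geometric), bp.
#' @param context_probs site context probabilities (CG, CHG, CHH).
#' @param noncg_level true methylation level of CHG/CHH sites.
#' @param coverage_mean,coverage_size negative-binomial read-depth mean and
#'   size per site per sample.
#' @param meth_profile list: `flank`, `tss`, `body` true CG levels and
#'   `dip_halfwidth` (bp) of the linear TSS dip.
#' @param dispersion beta-binomial overdispersion in (0, 1); 0 = binomial.
#' @param gene_level_sd sd of per-gene additive shifts to the upstream-flank
#'   and body/downstream levels (gives genes distinct methylomes so that
#'   methylation-expression coupling is identifiable).
#' @param prop_unmethylated fraction of genes with a fully unmethylated
#'   neighbourhood (populates the "None" methylation class).
#' @param n_samples_per_group samples per group.
#' @param expr_coupling list: `baseline`, `beta_upstream` (< 0), `beta_body`
#'   (> 0) on the log scale, and per-sample log-normal `noise_sd`.
#' @param prop_nonexpressed fraction of genes forced to RPKM <= 1.
#' @param dmr_injection list: `n_dmrs`, `effect_size`, `width` (bp).
#' @param deg_injection list: `n_degs`, `log2fc_effect`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       gene_length_range = c(1000L, 3000L),
                       intergenic_gap_mean = 500,
                       chrom_length = NULL,
                       flank_size = 3000L,
                       cpg_spacing_mean = 25,
                       context_probs = c(CG = 0.7, CHG = 0.15, CHH = 0.15),
                       noncg_level = 0.02,
                       coverage_mean = 30,
                       coverage_size = 8,
                       meth_profile = list(flank = 0.65, tss = 0.25,
                                           body = 0.75, dip_halfwidth = 500),
                       dispersion = 0.05,
                       gene_level_sd = 0.15,
                       prop_unmethylated = 0.10,
                       n_samples_per_group = 4L,
                       expr_coupling = list(baseline = 2.5, beta_upstream = -4,
                                            beta_body = 3, noise_sd = 0.4),
                       prop_nonexpressed = 0.25,
                       dmr_injection = list(n_dmrs = 60L, effect_size = 0.4,
                                            width = 600L),
                       deg_injection = list(n_degs = 100L, log2fc_effect = 2)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1L, cfg$dispersion >= 0, cfg$dispersion < 1,
            all(unlist(meth_profile[c("flank", "tss", "body")]) >= 0),
            all(unlist(meth_profile[c("flank", "tss", "body")]) <= 1),
            abs(sum(context_probs) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation and cytosine site layout
#'
#' Places `n_genes` non-overlapping genes (flanks included) on one
#' chromosome with 50/50 strands, and lays cytosine sites along it with
#' geometric gaps and random contexts.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (gene `data.table`), `sites` (`data.table`:
#'   `pos0`, `context`), and `chrom_length`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$n_genes
  fl <- config$flank_size
  lens <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  gaps <- round(rexp(n, 1 / config$intergenic_gap_mean))
  starts <- integer(n)
  cur <- fl + gaps[1]
  for (i in seq_len(n)) {
    starts[i] <- cur
    cur <- starts[i] + lens[i] + 2L * fl + if (i < n) gaps[i + 1] else 0L
  }
  need <- starts[n] + lens[n] + fl + 1L
  if (!is.null(config$chrom_length)) {
    if (config$chrom_length < need) {
      stop("chrom_length ", config$chrom_length, " too small; need >= ", need)
    }
    chrom_length <- config$chrom_length
  } else {
    chrom_length <- need
  }
  genes <- data.table::data.table(
    gene_id = sprintf("gene%04d", seq_len(n)), chrom = "chr1",
    start = as.integer(starts), end = as.integer(starts + lens),
    strand = sample(c("+", "-"), n, replace = TRUE))
  n_sites_guess <- ceiling(chrom_length / config$cpg_spacing_mean * 1.5) + 100L
  gap_draws <- 1L + rgeom(n_sites_guess, 1 / config$cpg_spacing_mean)
  pos0 <- cumsum(gap_draws)
  pos0 <- pos0[pos0 < chrom_length]
  sites <- data.table::data.table(
    pos0 = as.integer(pos0),
    context = sample(names(config$context_probs), length(pos0),
                     replace = TRUE, prob = config$context_probs))
  list(genes = genes, sites = sites, chrom_length = chrom_length)
}

## per-gene latent methylome parameters (additive shifts + unmethylated flag)
.gene_effects <- function(config, genes) {
  set.seed(config$seed + 131L)
  n <- nrow(genes)
  data.table::data.table(
    gene_id = genes$gene_id,
    d_up = rnorm(n, 0, config$gene_level_sd),
    d_body = rnorm(n, 0, config$gene_level_sd),
    unmethylated = runif(n) < config$prop_unmethylated)
}

#' True per-site methylation levels
#'
#' Builds the piecewise true CG level at every site: the upstream flank sits
#' at `flank + d_up(gene)`, the gene body and downstream flank at
#' `body + d_body(gene)`, with a linear dip to `tss + d_body(gene)` within
#' `dip_halfwidth` of the TSS (in transcript orientation); intergenic sites
#' sit at the global flank level, CHG/CHH sites at `noncg_level`, and
#' unmethylated genes at 0 across their whole neighbourhood. All levels are
#' clipped to the unit interval.
#'
#' @param config a [sim_config()].
#' @param genes,sites from [simulate_annotation()].
#' @param gene_effects internal per-gene shifts (regenerated from the seed
#'   when `NULL`).
#' @return `data.table`: `pos0`, `context`, `gene_id` (NA intergenic),
#'   `true_level`.
#' @export
true_site_levels <- function(config, genes, sites, gene_effects = NULL) {
  if (is.null(gene_effects)) gene_effects <- .gene_effects(config, genes)
  mp <- config$meth_profile
  fl <- config$flank_size
  st <- data.table::copy(sites)
  g <- merge(genes, gene_effects, by = "gene_id")
  nb <- g[, .(gene_id, start = start - fl, end = end + fl,
              gstart = start, gend = end, strand, d_up, d_body, unmethylated)]
  st[, x := pos0]  # join key that survives the non-equi rename
  hit <- nb[st, on = .(start <= x, end > x),
            .(pos0 = i.pos0, context = i.context, gene_id = x.gene_id,
              gstart = x.gstart, gend = x.gend, strand = x.strand,
              d_up = x.d_up, d_body = x.d_body, unmethylated = x.unmethylated)]
  lvl <- rep(mp$flank, nrow(hit))  # intergenic default
  inside <- !is.na(hit$gene_id)
  if (any(inside)) {
    h <- hit[inside]
    tss <- data.table::fifelse(h$strand == "+", h$gstart, h$gend)
    # signed distance from TSS in transcript orientation (>0 = into the body)
    dtss <- data.table::fifelse(h$strand == "+", h$pos0 - tss, tss - 1L - h$pos0)
    up_side <- dtss < 0
    base <- data.table::fifelse(up_side, mp$flank + h$d_up, mp$body + h$d_body)
    dip_floor <- mp$tss + h$d_body
    w <- pmax(0, 1 - abs(dtss) / mp$dip_halfwidth)  # 1 at TSS, 0 beyond the dip
    v <- base + (dip_floor - base) * w
    v[h$unmethylated] <- 0
    lvl[inside] <- v
  }
  lvl[hit$context != "CG"] <- config$noncg_level
  out <- hit[, .(pos0, context, gene_id)]
  out[, true_level := pmin(1, pmax(0, lvl))]
  out[order(pos0)][]
}

#' Injected-DMR truth table
#'
#' Chooses `n_dmrs` methylated genes, one interval each (random region:
#' upstream, body or downstream; width `width`), and a direction that keeps
#' the shifted level inside the unit interval: levels that would clip at 1 are shifted
#' down (`M-`), levels that would clip at 0 up (`M+`), otherwise random.
#'
#' @param config a [sim_config()].
#' @param genes gene table.
#' @param truth output of [true_site_levels()].
#' @return `data.table`: `chrom`, `start`, `end`, `context` ("CG"),
#'   `direction`, `gene_id`, `region_class`.
#' @export
simulate_dmr_truth <- function(config, genes, truth) {
  set.seed(config$seed + 151L)
  inj <- config$dmr_injection
  if (inj$n_dmrs == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), context = character(),
                                  direction = character(), gene_id = character(),
                                  region_class = character()))
  }
  meth_genes <- truth[!is.na(gene_id) & context == "CG",
                      .(mx = max(true_level)), by = gene_id][mx > 0, gene_id]
  stopifnot(length(meth_genes) >= inj$n_dmrs)
  picked <- sample(meth_genes, inj$n_dmrs)
  fl <- config$flank_size
  g <- genes[match(picked, gene_id)]
  region <- sample(c("upstream", "genebody", "downstream"), inj$n_dmrs,
                   replace = TRUE)
  rows <- lapply(seq_len(inj$n_dmrs), function(i) {
    gs <- g$start[i]; ge <- g$end[i]; plus <- g$strand[i] == "+"
    span <- switch(region[i],
      upstream = if (plus) c(gs - fl, gs) else c(ge, ge + fl),
      genebody = c(gs, ge),
      downstream = if (plus) c(ge, ge + fl) else c(gs - fl, gs))
    w <- min(inj$width, span[2] - span[1])
    s <- span[1] + sample.int(span[2] - span[1] - w + 1L, 1L) - 1L
    data.table::data.table(chrom = g$chrom[i], start = as.integer(s),
                           end = as.integer(s + w), gene_id = g$gene_id[i],
                           region_class = region[i])
  })
  out <- data.table::rbindlist(rows)
  base <- truth[context == "CG"][out, on = .(pos0 >= start, pos0 < end),
                                 .(m = mean(true_level)), by = .EACHI]$m
  up_ok <- base + inj$effect_size <= 1
  dn_ok <- base - inj$effect_size >= 0
  dir <- ifelse(up_ok & dn_ok, sample(c("M+", "M-"), nrow(out), replace = TRUE),
                ifelse(up_ok, "M+", "M-"))
  dir[is.na(dir)] <- "M+"  # interval without CG sites (possible at tiny configs)
  out[, `:=`(context = "CG", direction = dir)]
  out[, .(chrom, start, end, context, direction, gene_id, region_class)][]
}

#' Simulate per-sample methylation calls for one group
#'
#' Per site and sample, coverage is negative-binomial and the methylated
#' count beta-binomial around the site's true level with overdispersion
#' `dispersion` (exact binomial when the level is 0 or 1, or dispersion 0).
#' In group H the injected DMRs shift the CG true level by `effect_size` in
#' their direction (clipped to the unit interval). Uncovered site-samples are dropped.
#'
#' @param config a [sim_config()].
#' @param truth output of [true_site_levels()].
#' @param dmr_truth output of [simulate_dmr_truth()] (H only shifts).
#' @param group `"H"` or `"L"`.
#' @return call `data.table` for all samples of the group (sample ids
#'   `H1..Hn` / `L1..Ln`).
#' @export
simulate_methylome <- function(config, truth, dmr_truth, group = c("H", "L")) {
  group <- match.arg(group)
  set.seed(config$seed + 211L + (group == "H") * 7L)
  lvl <- data.table::copy(truth)
  if (group == "H" && nrow(dmr_truth) > 0L) {
    shift <- config$dmr_injection$effect_size
    for (i in seq_len(nrow(dmr_truth))) {
      s <- dmr_truth$start[i]; e <- dmr_truth$end[i]
      sgn <- if (dmr_truth$direction[i] == "M+") 1 else -1
      lvl[pos0 >= s & pos0 < e & context == dmr_truth$context[i],
          true_level := pmin(1, pmax(0, true_level + sgn * shift))]
    }
  }
  rho <- config$dispersion
  samples <- paste0(group, seq_len(config$n_samples_per_group))
  out <- lapply(samples, function(sid) {
    n <- nrow(lvl)
    cov <- rnbinom(n, mu = config$coverage_mean, size = config$coverage_size)
    p <- lvl$true_level
    if (rho > 0) {
      mid <- p > 0 & p < 1
      a <- p[mid] * (1 - rho) / rho
      b <- (1 - p[mid]) * (1 - rho) / rho
      p[mid] <- rbeta(sum(mid), a, b)
    }
    m <- rbinom(n, cov, p)
    dt <- data.table::data.table(chrom = "chr1", pos = lvl$pos0 + 1L,
                                 strand = "+", context = lvl$context,
                                 meth = m, total = cov, sample_id = sid)
    dt[total > 0L]
  })
  data.table::rbindlist(out)
}

#' Simulate the expression table
#'
#' Per-gene log mean expression is `baseline + beta_upstream * upstream_level
#' + beta_body * body_level` over the gene's true (base, group-L) region
#' levels; per-sample RPKM is the mean times log-normal noise. A
#' `prop_nonexpressed` stratum is forced to RPKM <= 1, and `n_degs` injected
#' DEGs multiply the H-group mean by `2^(+/- log2fc_effect)`.
#'
#' @param config a [sim_config()].
#' @param genes gene table.
#' @param truth output of [true_site_levels()] (base levels, no DMR shifts).
#' @return list with `expression` (long `data.table`: `gene_id`,
#'   `sample_id`, `rpkm`) and `deg_truth` (`gene_id`, `log2fc_true`,
#'   `direction`).
#' @export
simulate_expression <- function(config, genes, truth) {
  set.seed(config$seed + 307L)
  ec <- config$expr_coupling
  fl <- config$flank_size
  reg_lv <- .true_region_levels(genes, truth, fl)
  g <- merge(genes[, .(gene_id)], reg_lv, by = "gene_id", all.x = TRUE)
  g[is.na(upstream), upstream := 0][is.na(genebody), genebody := 0]
  g[, mu := exp(ec$baseline + ec$beta_upstream * upstream + ec$beta_body * genebody)]
  n <- nrow(g)
  nonexpr <- runif(n) < config$prop_nonexpressed
  inj <- config$deg_injection
  candidates <- which(!nonexpr)
  stopifnot(length(candidates) >= inj$n_degs)
  deg_idx <- sample(candidates, inj$n_degs)
  deg_sign <- sample(rep(c(1, -1), length.out = inj$n_degs))
  log2fc_true <- numeric(n)
  log2fc_true[deg_idx] <- deg_sign * inj$log2fc_effect
  samples <- c(paste0("H", seq_len(config$n_samples_per_group)),
               paste0("L", seq_len(config$n_samples_per_group)))
  rows <- lapply(samples, function(sid) {
    mu <- g$mu * if (startsWith(sid, "H")) 2^log2fc_true else 1
    rpkm <- mu * exp(rnorm(n, 0, ec$noise_sd))
    rpkm[nonexpr] <- runif(sum(nonexpr), 0, 1)
    data.table::data.table(gene_id = g$gene_id, sample_id = sid,
                           rpkm = round(rpkm, 4))
  })
  deg_truth <- data.table::data.table(
    gene_id = g$gene_id[deg_idx], log2fc_true = log2fc_true[deg_idx],
    direction = ifelse(deg_sign > 0, "up", "down"))
  list(expression = data.table::rbindlist(rows), deg_truth = deg_truth[order(gene_id)])
}

## mean true CG level per gene region from the truth table
.true_region_levels <- function(genes, truth, flank_size) {
  tr <- truth[!is.na(gene_id) & context == "CG"]
  tr <- merge(tr, genes[, .(gene_id, start, end, strand)], by = "gene_id")
  tr[, region_class := assign_position(pos0, pos0 + 1L, start, end, strand[1L],
                                       flank_size = flank_size), by = gene_id]
  wide <- data.table::dcast(
    tr[!is.na(region_class), .(level = mean(true_level)),
       by = .(gene_id, region_class)],
    gene_id ~ region_class, value.var = "level")
  for (col in c("upstream", "genebody", "downstream")) {
    if (!col %in% names(wide)) wide[, (col) := NA_real_]
  }
  wide
}

#' Null methylomes for DMR-caller calibration
#'
#' Generates two groups sequenced from one shared beta-binomial methylome:
#' per-site true levels are drawn once from a beta distribution (mean
#' `mean_level`, overdispersion `dispersion`), then every sample of both
#' groups draws binomial read counts from those same levels. Under this
#' null the pooled Fisher window test is exactly valid, so the fraction of
#' windows below alpha measures the caller's calibration. Sites are laid in
#' well-separated blocks of `sites_per_window` sites so windows are
#' populated.
#'
#' @param seed integer seed.
#' @param n_windows number of site blocks.
#' @param sites_per_window sites per block.
#' @param window block width in bp (sites are evenly spaced inside it).
#' @param n_samples samples per group.
#' @param coverage_mean,coverage_size negative-binomial depth parameters.
#' @param mean_level mean true methylation level.
#' @param dispersion beta variance parameter in (0, 1).
#' @return list with `calls_H` and `calls_L`.
#' @export
simulate_null_calls <- function(seed = 1L, n_windows = 2000L,
                                sites_per_window = 8L, window = 200L,
                                n_samples = 4L, coverage_mean = 30,
                                coverage_size = 8, mean_level = 0.65,
                                dispersion = 0.05) {
  set.seed(seed)
  spacing <- window %/% sites_per_window
  block_gap <- 5L * window  # blocks far apart: no window spans two blocks
  pos0 <- as.vector(outer(seq_len(sites_per_window) - 1L,
                          (seq_len(n_windows) - 1L) * block_gap,
                          function(i, b) b + i * spacing))
  n <- length(pos0)
  a <- mean_level * (1 - dispersion) / dispersion
  b <- (1 - mean_level) * (1 - dispersion) / dispersion
  level <- rbeta(n, a, b)
  draw_group <- function(label) {
    data.table::rbindlist(lapply(seq_len(n_samples), function(s) {
      cov <- rnbinom(n, mu = coverage_mean, size = coverage_size)
      dt <- data.table::data.table(chrom = "chr1", pos = pos0 + 1L,
                                   strand = "+", context = "CG",
                                   meth = rbinom(n, cov, level), total = cov,
                                   sample_id = paste0(label, s))
      dt[total > 0L]
    }))
  }
  list(calls_H = draw_group("H"), calls_L = draw_group("L"))
}

#' Simulate a complete input bundle
#'
#' Runs annotation, methylome (both groups) and expression simulation under
#' one configuration, optionally writing every file a pipeline run needs
#' (annotation BED, per-sample methylation TSVs, expression TSV, truth
#' tables) into a directory. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if missing).
#' @return list with `genes`, `sites`, `truth`, `calls_H`, `calls_L`,
#'   `expression`, `dmr_truth`, `deg_truth`, `chrom_length`, `config`, and
#'   (when written) `files`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  ann <- simulate_annotation(config)
  eff <- .gene_effects(config, ann$genes)
  truth <- true_site_levels(config, ann$genes, ann$sites, eff)
  dmr_truth <- simulate_dmr_truth(config, ann$genes, truth)
  calls_H <- simulate_methylome(config, truth, dmr_truth, "H")
  calls_L <- simulate_methylome(config, truth, dmr_truth, "L")
  ex <- simulate_expression(config, ann$genes, truth)
  out <- list(genes = ann$genes, sites = ann$sites, truth = truth,
              calls_H = calls_H, calls_L = calls_L,
              expression = ex$expression, dmr_truth = dmr_truth,
              deg_truth = ex$deg_truth, chrom_length = ann$chrom_length,
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(annotation = file.path(dir, "annotation.bed"),
               expression = file.path(dir, "expression.tsv"),
               dmr_truth = file.path(dir, "dmr_truth.tsv"),
               deg_truth = file.path(dir, "deg_truth.tsv"))
    write_gene_annotation(out$genes, files["annotation"])
    write_expression_table(out$expression, files["expression"])
    data.table::fwrite(out$dmr_truth, files["dmr_truth"], sep = "\t")
    data.table::fwrite(out$deg_truth, files["deg_truth"], sep = "\t")
    all_calls <- rbind(calls_H, calls_L)
    for (sid in unique(all_calls$sample_id)) {
      f <- file.path(dir, paste0("calls_", sid, ".tsv"))
      write_methylation_calls(all_calls[sample_id == sid], f)
      files[paste0("calls_", sid)] <- f
    }
    out$files <- files
  }
  out
}
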