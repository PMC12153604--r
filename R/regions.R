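#' Derive strand-aware upstream / gene-body / downstream regions
#'
#' For each gene the gene body is the gene span itself and the upstream and
#' downstream regions are `flank_size`-bp windows on the 5' and 3' side in
#' transcriptional orientation (so for minus-strand genes upstream lies at
#' higher genomic coordinates). Flanks are clipped at position 0 and, when
#' `chrom_lengths` is supplied, at the chromosome end; clipped flanks may be
#' shorter than `flank_size` or empty.
#'
#' @param genes gene `data.table` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param flank_size flank width in bp (default 3000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return `data.table` with `gene_id`, `region_class` (upstream / genebody /
#'   downstream), `chrom`, `start`, `end`, `strand`; empty clipped regions
#'   are dropped.
#' @export
gene_regions <- function(genes, flank_size = 3000L, chrom_lengths = NULL) {
  stopifnot(flank_size > 0)
  g <- data.table::as.data.table(genes)
  left  <- g[, .(gene_id, chrom, start = start - flank_size, end = start, strand)]
  body  <- g[, .(gene_id, chrom, start, end, strand)]
  right <- g[, .(gene_id, chrom, start = end, end = end + flank_size, strand)]
  left[,  region_class := data.table::fifelse(strand == "+", "upstream", "downstream")]
  right[, region_class := data.table::fifelse(strand == "+", "downstream", "upstream")]
  body[,  region_class := "genebody"]
  out <- data.table::rbindlist(list(left, body, right), use.names = TRUE)
  out[start < 0L, start := 0L]
  if (!is.null(chrom_lengths)) {
    out[, end := pmin(end, chrom_lengths[chrom])]
  }
  out <- out[start < end]
  data.table::setcolorder(out, c("gene_id", "region_class", "chrom", "start", "end", "strand"))
  out[order(gene_id, start)][]
}

#' Assign an interval to a gene region by its midpoint
#'
#' Returns the region class (upstream / genebody / downstream, in the gene's
#' transcriptional orientation) whose span contains the interval midpoint,
#' or `NA` when the midpoint lies outside `[gene_start - flank, gene_end +
#' flank)`. Vectorised over intervals against a single gene.
#'
#' @param ivl_start,ivl_end interval coordinates, 0-based half-open.
#' @param gene_start,gene_end,gene_strand the gene model.
#' @param flank_size flank width in bp.
#' @return character vector of region classes (NA outside all regions).
#' @export
assign_position <- function(ivl_start, ivl_end, gene_start, gene_end,
                            gene_strand, flank_size = 3000L) {
  mid <- (ivl_start + ivl_end) / 2
  n <- length(mid)
  gene_start <- rep_len(gene_start, n)
  gene_end <- rep_len(gene_end, n)
  plus <- rep_len(gene_strand == "+", n)  # genomic-left flank is 5' on '+'
  out <- rep(NA_character_, n)
  left <- mid >= gene_start - flank_size & mid < gene_start
  right <- mid >= gene_end & mid < gene_end + flank_size
  out[mid >= gene_start & mid < gene_end] <- "genebody"
  out[left] <- ifelse(plus[left], "upstream", "downstream")
  out[right] <- ifelse(plus[right], "downstream", "upstream")
  out
}

#' Map genomic positions to metagene bin indices
#'
#' Bins run 5' to 3' in the gene's transcriptional orientation: `n_flank`
#' fixed-width bins across the upstream flank, `n_body` bins of width
#' `(end - start) / n_body` across the gene body, then `n_flank` bins across
#' the downstream flank, giving indices `0 .. 2 n_flank + n_body - 1`.
#' Positions outside `[start - flank, end + flank)` map to `NA`.
#'
#' @param pos0 0-based genomic positions.
#' @param gene_start,gene_end,gene_strand the gene model.
#' @param n_flank,n_body bin counts (defaults 30 and 60).
#' @param flank_size flank width in bp.
#' @return integer bin indices (NA outside the profiled span).
#' @export
site_to_bin <- function(pos0, gene_start, gene_end, gene_strand,
                        n_flank = 30L, n_body = 60L, flank_size = 3000L) {
  len <- gene_end - gene_start
  stopifnot(len >= n_body)  # shorter genes are excluded from profiling
  fw <- flank_size / n_flank
  bin <- rep(NA_real_, length(pos0))
  left <- pos0 >= gene_start - flank_size & pos0 < gene_start
  body <- pos0 >= gene_start & pos0 < gene_end
  right <- pos0 >= gene_end & pos0 < gene_end + flank_size
  bin[left] <- floor((pos0[left] - (gene_start - flank_size)) / fw)
  bin[body] <- n_flank + floor((pos0[body] - gene_start) * n_body / len)
  bin[right] <- n_flank + n_body + floor((pos0[right] - gene_end) / fw)
  if (gene_strand == "-") {
    bin <- (2L * n_flank + n_body - 1L) - bin
  }
  as.integer(bin)
}
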