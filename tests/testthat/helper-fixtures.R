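## in-memory fixture builders shared across test files

make_calls <- function(pos, meth, total, chrom = "chr1", strand = "+",
                       context = "CG", sample_id = "S1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, context = context,
                         meth = as.integer(meth), total = as.integer(total),
                         sample_id = sample_id)
}

make_genes <- function(start, end, strand = "+", chrom = "chr1",
                       gene_id = sprintf("g%d", seq_along(start))) {
  data.table::data.table(gene_id = gene_id, chrom = chrom,
                         start = as.integer(start), end = as.integer(end),
                         strand = strand)
}

## a fast low-volume generator configuration for unit tests
tiny_sim_config <- function(seed = 1L, n_genes = 25L, ...) {
  args <- list(seed = seed, n_genes = n_genes,
               gene_length_range = c(600L, 1200L),
               cpg_spacing_mean = 30,
               dmr_injection = list(n_dmrs = 5L, effect_size = 0.4, width = 400L),
               deg_injection = list(n_degs = 6L, log2fc_effect = 2))
  do.call(sim_config, utils::modifyList(args, list(...)))
}

## brute-force weighted level over sites inside [start, end)
brute_region_level <- function(calls, start, end, contexts = "CG",
                               min_coverage = 4L) {
  m <- 0; tot <- 0; n <- 0L
  for (i in seq_len(nrow(calls))) {
    p0 <- calls$pos[i] - 1L
    if (p0 >= start && p0 < end && calls$context[i] %in% contexts &&
        calls$total[i] >= min_coverage) {
      m <- m + calls$meth[i]; tot <- tot + calls$total[i]; n <- n + 1L
    }
  }
  if (n == 0L) NULL else list(level = m / tot, n_sites = n)
}

## exact hypergeometric upper tail by direct enumeration of the pmf
brute_hyper_upper <- function(k, N, K, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

## exact two-sided Fisher p for a 2x2 by enumerating fixed-margin tables
brute_fisher_two_sided <- function(m1, u1, m2, u2) {
  r1 <- m1 + u1; r2 <- m2 + u2; cm <- m1 + m2
  ks <- max(0, cm - r2):min(cm, r1)
  pmf <- choose(r1, ks) * choose(r2, cm - ks) / choose(r1 + r2, cm)
  sum(pmf[pmf <= pmf[ks == m1] * (1 + 1e-7)])
}
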