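#' Sliding-window DMR calling between two groups
#'
#' Read counts are pooled per site within each group, windows of width
#' `window` are slid in steps of `step` along every chromosome, and each
#' window with at least `min_sites` covered sites in both groups is tested
#' with the two-sided Fisher exact test on the pooled 2x2 table (methylated
#' / unmethylated reads by group). Windows with `p < alpha` and
#' `|level_H - level_L| >= min_diff` are significant; overlapping
#' significant windows of the same context and direction are merged, and
#' each merged span is re-pooled and re-tested. Contexts are processed
#' independently.
#'
#' @param calls_H,calls_L call `data.table`s for the two groups (any number
#'   of samples each; reads are summed per site within a group).
#' @param contexts contexts to scan (default CG, CHG, CHH).
#' @param window,step window width and step in bp.
#' @param min_sites minimum covered sites per group per window.
#' @param min_diff minimum absolute level difference.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"BH"` across all tested windows of a
#'   context.
#' @param return_windows also return the per-window table (with p-values for
#'   every tested window, not only those passing the difference filter).
#' @return `data.table` of DMRs with `chrom`, `start`, `end`, `context`,
#'   `level_H`, `level_L`, `diff_level`, `p_value`, `direction` (`M+` hyper
#'   in H, `M-` hypo in H), `n_sites`; when `return_windows = TRUE`, a list
#'   with elements `dmrs` and `windows`.
#' @export
call_dmrs <- function(calls_H, calls_L, contexts = c("CG", "CHG", "CHH"),
                      window = 200L, step = 50L, min_sites = 4L,
                      min_diff = 0.1, alpha = 0.05,
                      adjust = c("none", "BH"), return_windows = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(window > 0L, step > 0L, window %% step == 0L, min_sites >= 1L)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), level_H = numeric(), level_L = numeric(),
    diff_level = numeric(), p_value = numeric(), direction = character(),
    n_sites = integer())
  res <- list(); wins <- list()
  for (ctx in contexts) {
    w <- .dmr_windows(calls_H, calls_L, ctx, window, step, min_sites,
                      min_diff, compute_all_p = return_windows || adjust == "BH")
    if (is.null(w)) next
    wins[[ctx]] <- w
    sig_p <- if (adjust == "BH") p.adjust(w$p_value, method = "BH") else w$p_value
    sig <- w[!is.na(sig_p) & sig_p < alpha & abs(diff_level) >= min_diff]
    if (nrow(sig) == 0L) next
    res[[ctx]] <- .merge_windows(sig, calls_H, calls_L, ctx, window)
  }
  dmrs <- if (length(res)) data.table::rbindlist(res, use.names = TRUE) else empty
  dmrs <- dmrs[order(chrom, start)]
  if (return_windows) {
    windows <- if (length(wins)) data.table::rbindlist(wins, use.names = TRUE) else NULL
    return(list(dmrs = dmrs[], windows = windows))
  }
  dmrs[]
}

## per-context window statistics; p computed for all windows meeting the
## site minimum when compute_all_p, else only where the diff filter passes
.dmr_windows <- function(calls_H, calls_L, ctx, window, step, min_sites,
                         min_diff, compute_all_p = FALSE) {
  pH <- pool_calls(calls_H[context == ctx], "H")
  pL <- pool_calls(calls_L[context == ctx], "L")
  if (nrow(pH) == 0L || nrow(pL) == 0L) return(NULL)
  sites <- merge(pH[, .(chrom, pos0 = pos - 1L, mH = meth, tH = total)],
                 pL[, .(chrom, pos0 = pos - 1L, mL = meth, tL = total)],
                 by = c("chrom", "pos0"), all = TRUE)
  for (col in c("mH", "tH", "mL", "tL")) {
    data.table::set(sites, which(is.na(sites[[col]])), col, 0L)
  }
  k <- window %/% step
  expanded <- sites[rep(seq_len(.N), each = k)]
  expanded[, j := rep(seq_len(k) - 1L, times = nrow(sites))]
  expanded[, wstart := (pos0 %/% step - j) * step]
  expanded <- expanded[pos0 >= wstart & pos0 < wstart + window & wstart >= 0L]
  w <- expanded[, .(nH = sum(tH > 0L), nL = sum(tL > 0L),
                    mH = sum(mH), uH = sum(tH) - sum(mH),
                    mL = sum(mL), uL = sum(tL) - sum(mL)),
                by = .(chrom, wstart)]
  w <- w[nH >= min_sites & nL >= min_sites]
  if (nrow(w) == 0L) return(NULL)
  w[, `:=`(level_H = mH / (mH + uH), level_L = mL / (mL + uL))]
  w[, diff_level := level_H - level_L]
  w[, p_value := NA_real_]
  test_rows <- if (compute_all_p) seq_len(nrow(w)) else which(abs(w$diff_level) >= min_diff)
  if (length(test_rows)) {
    w$p_value[test_rows] <- fisher_exact_2x2(w$mH[test_rows], w$uH[test_rows],
                                             w$mL[test_rows], w$uL[test_rows])
  }
  w[, `:=`(start = wstart, end = wstart + window, context = ctx)]
  w[order(chrom, start)][]
}

## merge overlapping same-direction significant windows; re-pool and re-test
.merge_windows <- function(sig, calls_H, calls_L, ctx, window) {
  sig <- data.table::copy(sig)[, direction := data.table::fifelse(diff_level > 0, "M+", "M-")]
  pH <- pool_calls(calls_H[context == ctx], "H")[, pos0 := pos - 1L]
  pL <- pool_calls(calls_L[context == ctx], "L")[, pos0 := pos - 1L]
  out <- sig[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    data.table::data.table(start = BiocGenerics::start(ir) - 1L,
                           end = BiocGenerics::end(ir))
  }, by = .(chrom, direction)]
  stats <- lapply(seq_len(nrow(out)), function(i) {
    ch <- out$chrom[i]; s <- out$start[i]; e <- out$end[i]
    h <- pH[chrom == ch & pos0 >= s & pos0 < e]
    l <- pL[chrom == ch & pos0 >= s & pos0 < e]
    both <- length(intersect(h$pos0[h$total > 0L], l$pos0[l$total > 0L]))
    mh <- sum(h$meth); th <- sum(h$total); ml <- sum(l$meth); tl <- sum(l$total)
    list(level_H = mh / th, level_L = ml / tl,
         p_value = fisher_exact_2x2(mh, th - mh, ml, tl - ml),
         n_sites = both)
  })
  out <- cbind(out, data.table::rbindlist(stats))
  out[, diff_level := level_H - level_L]
  # direction fixed by the member windows; merged diff keeps the same sign
  out[, context := ctx]
  out[, .(chrom, start, end, context, level_H, level_L, diff_level,
          p_value, direction, n_sites)]
}

#' Link DMRs to genes by positional class
#'
#' A DMR is linked to every gene whose `[start - flank, end + flank)`
#' neighbourhood contains the DMR midpoint; the positional class comes from
#' [assign_position()]. One row per (DMR, gene) pair.
#'
#' @param dmrs DMR `data.table` from [call_dmrs()].
#' @param genes gene `data.table`.
#' @param flank_size flank width in bp (default 3000).
#' @return `data.table` with `dmr_id` (`chrom:start-end:context`), `gene_id`,
#'   `region_class`, `context`, `direction`.
#' @export
link_dmrs_to_genes <- function(dmrs, genes, flank_size = 3000L) {
  empty <- data.table::data.table(dmr_id = character(), gene_id = character(),
                                  region_class = character(), context = character(),
                                  direction = character())
  if (nrow(dmrs) == 0L) return(empty)
  d <- data.table::copy(data.table::as.data.table(dmrs))
  d[, dmr_id := paste0(chrom, ":", start, "-", end, ":", context)]
  d[, mid := (start + end) / 2]
  g <- data.table::as.data.table(genes)[, .(gene_id, chrom, gstart = start,
                                            gend = end, gstrand = strand,
                                            start = start - flank_size,
                                            end = end + flank_size)]
  hits <- g[d, on = .(chrom, start <= mid, end > mid), nomatch = NULL,
            .(dmr_id = i.dmr_id, gene_id = x.gene_id, gstart = x.gstart,
              gend = x.gend, gstrand = x.gstrand, dstart = i.start,
              dend = i.end, context = i.context, direction = i.direction)]
  if (nrow(hits) == 0L) return(empty)
  hits[, region_class := assign_position(dstart, dend, gstart, gend, gstrand,
                                         flank_size = flank_size)]
  out <- hits[!is.na(region_class),
              .(dmr_id, gene_id, region_class, context, direction)]
  unique(out)[]
}
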