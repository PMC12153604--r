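#' Expression classes from mean RPKM
#'
#' Classifies genes by mean expression: non (rpkm <= 1), low (1 < rpkm <=
#' 10), middle (10 < rpkm <= 100), high (rpkm > 100). Boundary values fall
#' in the lower class.
#'
#' @param rpkm_mean non-negative numeric vector of per-gene mean RPKM/FPKM.
#' @return ordered factor with levels non < low < middle < high.
#' @export
expression_binning <- function(rpkm_mean) {
  stopifnot(all(rpkm_mean >= 0, na.rm = TRUE))
  cut(rpkm_mean, breaks = c(-Inf, 1, 10, 100, Inf),
      labels = c("non", "low", "middle", "high"),
      right = TRUE, ordered_result = TRUE)
}

## Welch's t on log2(rpkm + 1); degenerate zero-variance cases resolved
## deterministically (identical constant groups -> p 1, separated -> p 0).
.welch_log2 <- function(h, l) {
  x <- log2(h + 1); y <- log2(l + 1)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / nx + vy / ny
  dm <- mean(x) - mean(y)
  if (se2 <= 0) return(if (abs(dm) < 1e-12) 1 else 0)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(dm / sqrt(se2)), df = df)
}

#' Two-group differential expression test for one gene
#'
#' Welch's t-test on `log2(rpkm + 1)` between the H and L groups, with a
#' pseudocounted log2 fold change `log2((mean_H + c) / (mean_L + c))`.
#'
#' @param rpkm_H,rpkm_L per-sample RPKM values (>= 2 samples each).
#' @param pseudocount pseudocount `c` in the fold change (default 1).
#' @return list with `mean_H`, `mean_L`, `log2fc`, `p_value`.
#' @export
deg_test <- function(rpkm_H, rpkm_L, pseudocount = 1) {
  stopifnot(length(rpkm_H) >= 2L, length(rpkm_L) >= 2L)
  mH <- mean(rpkm_H); mL <- mean(rpkm_L)
  list(mean_H = mH, mean_L = mL,
       log2fc = log2((mH + pseudocount) / (mL + pseudocount)),
       p_value = .welch_log2(rpkm_H, rpkm_L))
}

#' Direction class of a differential-expression record
#'
#' `special_up` when every H sample exceeds `expr_threshold` and every L
#' sample does not (group-specific expression); `special_down` is the
#' mirror. Otherwise `other_up` / `other_down` when the test is significant
#' at `alpha` with a non-zero fold change, else `none`.
#'
#' @param record list from [deg_test()].
#' @param rpkm_H,rpkm_L the per-sample values the record was computed from.
#' @param alpha significance level (default 0.05).
#' @param expr_threshold expressed/non-expressed RPKM cutoff (default 1).
#' @return one of `special_up`, `special_down`, `other_up`, `other_down`,
#'   `none`.
#' @export
deg_direction_class <- function(record, rpkm_H, rpkm_L, alpha = 0.05,
                                expr_threshold = 1) {
  if (all(rpkm_H > expr_threshold) && all(rpkm_L <= expr_threshold)) return("special_up")
  if (all(rpkm_L > expr_threshold) && all(rpkm_H <= expr_threshold)) return("special_down")
  if (is.finite(record$p_value) && record$p_value < alpha) {
    if (record$log2fc > 0) return("other_up")
    if (record$log2fc < 0) return("other_down")
  }
  "none"
}

#' Per-gene differential expression table with direction classes
#'
#' Runs [deg_test()] and [deg_direction_class()] for every gene in a
#' long-form expression table.
#'
#' @param expr long-form expression `data.table` (`gene_id`, `sample_id`,
#'   `rpkm`).
#' @param groups named character vector mapping `sample_id` to "H" or "L".
#' @param alpha significance level (default 0.05, applied to the raw or, if
#'   `adjust = "BH"`, the adjusted p-value).
#' @param pseudocount fold-change pseudocount.
#' @param expr_threshold expressed/non-expressed cutoff for the special
#'   classes.
#' @param adjust `"none"` (default, raw p < alpha) or `"BH"`.
#' @return `data.table` with `gene_id`, `mean_H`, `mean_L`, `log2fc`,
#'   `p_value` (plus `q_value` under BH), `direction_class`.
#' @export
deg_table <- function(expr, groups, alpha = 0.05, pseudocount = 1,
                      expr_threshold = 1, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  e <- data.table::as.data.table(expr)
  missing_grp <- setdiff(unique(e$sample_id), names(groups))
  if (length(missing_grp)) stop("samples without group assignment: ",
                                paste(missing_grp, collapse = ", "))
  e[, flag := unname(groups[sample_id])]
  stopifnot(all(e$flag %in% c("H", "L")))
  out <- e[, {
    h <- rpkm[flag == "H"]; l <- rpkm[flag == "L"]
    r <- deg_test(h, l, pseudocount = pseudocount)
    c(r, list(.h = list(h), .l = list(l)))
  }, by = gene_id]
  sig_p <- if (adjust == "BH") {
    out[, q_value := p.adjust(p_value, method = "BH")]
    out$q_value
  } else out$p_value
  out[, direction_class := vapply(seq_len(.N), function(i) {
    deg_direction_class(list(p_value = sig_p[i], log2fc = log2fc[i]),
                        .h[[i]], .l[[i]], alpha = alpha,
                        expr_threshold = expr_threshold)
  }, character(1))]
  out[, c(".h", ".l") := NULL]
  out[]
}
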