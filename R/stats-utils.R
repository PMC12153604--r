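#' Two-sided Fisher exact p-value for 2x2 tables of read counts
#'
#' Exact two-sided p-value for the table `rbind(c(m1, u1), c(m2, u2))`,
#' defined (as in [stats::fisher.test()]) as the total hypergeometric
#' probability of all tables with the same margins whose probability does not
#' exceed that of the observed table (within a relative tolerance of 1e-7).
#' Vectorised over the four count arguments.
#'
#' @param m1,u1 methylated / unmethylated read counts in group 1.
#' @param m2,u2 methylated / unmethylated read counts in group 2.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_2x2(8, 2, 2, 8)  # 4252/184756
#' @export
fisher_exact_2x2 <- function(m1, u1, m2, u2) {
  n <- length(m1)
  stopifnot(length(u1) == n, length(m2) == n, length(u2) == n)
  if (any(c(m1, u1, m2, u2) < 0)) stop("counts must be non-negative")
  vapply(seq_len(n), function(i) {
    r1 <- m1[i] + u1[i]; r2 <- m2[i] + u2[i]; cm <- m1[i] + m2[i]
    if (r1 == 0L || r2 == 0L || cm == 0L || cm == r1 + r2) return(1)
    support <- max(0, cm - r2):min(cm, r1)
    d <- dhyper(support, r1, r2, cm)
    sum(d[d <= d[support == m1[i]] * (1 + 1e-7)])
  }, numeric(1))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks. The
#' two-sided p-value uses exhaustive permutation enumeration when `n <=
#' exact_max` and the data are tie-free, and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df otherwise.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param exact_max largest n for which the exact permutation null is
#'   enumerated (default 9).
#' @return list with `rho`, `p_value`, `n`, and `method` ("exact" or
#'   "t-approximation").
#' @export
spearman_test <- function(x, y, exact_max = 9L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearman_test requires at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_max && !ties) {
    perms <- .all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    rhos <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) /
      (sqrt(sum(rxc^2)) * sqrt(sum(ryc^2)))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tstat), df = n - 2))
    method <- "t-approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

## all permutations of 1..n as an n! x n integer matrix (iterative insertion)
.all_perms <- function(n) {
  p <- matrix(1L, 1L, 1L)
  for (m in 2L:n) {
    k <- nrow(p)
    out <- matrix(0L, k * m, m)
    for (slot in seq_len(m)) {
      rows <- (slot - 1L) * k + seq_len(k)
      if (slot > 1L) out[rows, seq_len(slot - 1L)] <- p[, seq_len(slot - 1L), drop = FALSE]
      out[rows, slot] <- m
      if (slot < m) out[rows, (slot + 1L):m] <- p[, slot:(m - 1L), drop = FALSE]
    }
    p <- out
  }
  p
}
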