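#' Partial Mantel test
#'
#' Partial correlation between the off-diagonal entries of two distance
#' matrices A and B, controlling for a third matrix C (typically geographic
#' distance), with significance from simultaneous row/column permutations of
#' A. The default Spearman variant rank-transforms each matrix's off-diagonal
#' vector before computing the partial product-moment correlation.
#'
#' The empirical p-value follows the add-one rule `(1 + b) / (perms + 1)`
#' (never 0); the default tail is one-sided `"greater"`.
#'
#' @param A,B,C symmetric numeric matrices of the same dimension (n >= 4).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param perms number of permutations (default 1000).
#' @param seed RNG seed.
#' @param tail `"greater"` (default) or `"two_sided"`.
#' @return object of class `mantel_result`: list with `statistic`, `p_value`,
#'   `perms`, `method`, `tail`.
#' @export
partial_mantel <- function(A, B, C, method = c("spearman", "pearson"),
                           perms = 1000, seed = NULL, tail = c("greater", "two_sided")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  for (m in list(A, B, C)) {
    stop_if_not(is.matrix(m) && nrow(m) == ncol(m), "inputs must be square matrices")
    stop_if_not(isTRUE(all.equal(m, t(m))), "inputs must be symmetric")
  }
  n <- nrow(A)
  stop_if_not(nrow(B) == n && nrow(C) == n, "matrices must have matching dimensions")
  stop_if_not(n >= 4, "need at least 4 objects")
  low <- lower.tri(A)
  xf <- if (method == "spearman") function(v) rank(v) else identity

  zscore <- function(v) {
    v <- v - mean(v)
    s <- sqrt(sum(v^2))
    if (s == 0) stop("constant distance vector: correlation undefined", call. = FALSE)
    v / s
  }
  partial_r <- function(za, zb, zc) {
    rab <- sum(za * zb); rac <- sum(za * zc); rbc <- sum(zb * zc)
    den <- sqrt((1 - rac^2) * (1 - rbc^2))
    if (den == 0) return(0)
    (rab - rac * rbc) / den
  }

  zb <- zscore(xf(B[low]))
  zc <- zscore(xf(C[low]))
  # Rank-transform A once, in matrix form: permuting objects permutes the
  # entries, so the ranks travel with them and need not be recomputed.
  Am <- matrix(0, n, n)
  Am[low] <- xf(A[low])
  Am <- Am + t(Am)
  za <- zscore(Am[low])
  obs <- partial_r(za, zb, zc)

  null <- with_seed(seed, vapply(seq_len(perms), function(i) {
    idx <- sample.int(n)
    partial_r(zscore(Am[idx, idx][low]), zb, zc)
  }, numeric(1)))
  b <- switch(tail,
              greater = sum(null >= obs),
              two_sided = sum(abs(null) >= abs(obs)))
  structure(list(statistic = obs, p_value = (1 + b) / (perms + 1),
                 perms = perms, method = method, tail = tail),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> partial r (%s) = %0.4f, p (%s, %d perms) = %0.4g\n",
              x$method, x$statistic, x$tail, x$perms, x$p_value))
  invisible(x)
}
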