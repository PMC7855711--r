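#' Pearson correlation with a two-sided p-value
#'
#' Pairwise-deletes missing entries, then computes the sample Pearson
#' coefficient and its two-sided p-value from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (the classical test, as implemented by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @return A one-row tibble with columns `r`, `p`, `n` (jointly non-missing
#'   sample count).
#' @examples
#' pearson_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop_cs("x and y must have the same length", "validation")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop_cs(paste0("need at least 3 jointly non-missing pairs, got ", n), "insufficient_data")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_cs("zero variance in one of the vectors", "degenerate_input")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts raw p-values by the false-discovery-rate step-up procedure,
#' returning q-values in the input order. Each q-value is at least its raw
#' p-value and at most 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (length(pvalues) == 0) {
    return(numeric(0))
  }
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_cs("p-values must lie in [0, 1]", "domain")
  }
  p.adjust(pvalues, method = "BH")
}

# Vectorised pairwise-complete correlation screen between two row sets of a
# feature x sample matrix. Returns one row per (a, b) pair with n >= 3 and a
# defined coefficient; p from the t-transform with per-pair n.
cor_screen <- function(values, rows_a, rows_b) {
  A <- t(values[rows_a, , drop = FALSE])
  B <- t(values[rows_b, , drop = FALSE])
  suppressWarnings(r <- cor(A, B, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(A), !is.na(B))
  res <- tibble(
    feature_a = rep(rows_a, times = length(rows_b)),
    feature_b = rep(rows_b, each = length(rows_a)),
    r = as.vector(r),
    n = as.vector(n)
  )
  res <- res[!is.na(res$r) & res$n >= 3, , drop = FALSE]
  # clamp |r| slightly inside 1 so the t-transform stays finite
  r_c <- pmin(pmax(res$r, -1), 1)
  tstat <- r_c * sqrt((res$n - 2) / pmax(1 - r_c^2, .Machine$double.eps))
  res$p <- 2 * pt(abs(tstat), df = res$n - 2, lower.tail = FALSE)
  res$p[abs(r_c) == 1] <- 0
  res[, c("feature_a", "feature_b", "r", "p", "n")]
}
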