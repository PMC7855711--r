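# Brute-force statistical oracles, coded independently of the package
# implementations they check.

oracle_pearson <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2), n = n)
}

# literal step-up: q_(i) = min_{j >= i} min(m * p_(j) / j, 1), mapped back
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(pmin(m * p[o][js] / js, 1))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

oracle_t_unpaired <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = n1 + n2 - 2, p = 2 * stats::pt(-abs(tval), df = n1 + n2 - 2))
}

oracle_t_paired <- function(a, b) {
  d <- a - b
  n <- length(d)
  tval <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * stats::pt(-abs(tval), df = n - 1))
}

# two-group one-way ANOVA F by the textbook sums-of-squares decomposition
oracle_anova_f <- function(a, b) {
  g <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - g)^2 + length(b) * (mean(b) - g)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  df2 <- length(a) + length(b) - 2
  f <- (ssb / 1) / (ssw / df2)
  list(f = f, p = stats::pf(f, 1, df2, lower.tail = FALSE))
}
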