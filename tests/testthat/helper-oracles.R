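# Independent brute-force oracles used to cross-check the package's
# estimators on small instances. Deliberately written as plain loops
# over the defining formulas, sharing no code with the implementation.

oracle_magnitude <- function(x, y, z) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- sqrt(x[i]^2 + y[i]^2 + z[i]^2)
  out
}

oracle_window_starts <- function(n, len, step) {
  starts <- integer(0)
  s <- 1L
  while (s + len - 1L <= n) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}

# sample entropy by explicit template counting (Chebyshev distance,
# self-matches excluded, templates limited to the first n - m starts)
oracle_sampen <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  nb <- n - m
  cheb <- function(i, j, len) {
    d <- 0
    for (k in 0:(len - 1L)) d <- max(d, abs(x[i + k] - x[j + k]))
    d
  }
  A <- 0L
  B <- 0L
  for (i in 1:(nb - 1L)) {
    for (j in (i + 1L):nb) {
      if (cheb(i, j, m) <= r) B <- B + 1L
      if (cheb(i, j, m + 1L) <= r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(0)
  -log(A / B)
}

# Higuchi curve length by direct summation, slope by lm()
oracle_higuchi <- function(x, k_max = 10L) {
  n <- length(x)
  lk <- numeric(k_max)
  for (k in 1:k_max) {
    lengths_m <- numeric(k)
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      s <- 0
      for (q in 2:length(idx)) s <- s + abs(x[idx[q]] - x[idx[q - 1L]])
      norm <- (n - 1) / ((length(idx) - 1L) * k)
      lengths_m[m] <- s * norm / k
    }
    lk[k] <- mean(lengths_m)
  }
  unname(coef(lm(log(lk) ~ log(1 / (1:k_max))))[2])
}

oracle_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1L])^2
  sqrt(s / (length(x) - 1L))
}

# AUROC as the proportion of concordant positive/negative pairs
# (ties counted 1/2) — the Mann-Whitney identity
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}
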