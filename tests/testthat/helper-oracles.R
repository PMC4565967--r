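# Independent oracles, deliberately kept on different code paths from the
# implementation: exact binomial enumeration for the hypergeometric tail,
# textbook sum formulas for Pearson/Spearman, and the literal step-up
# definition for Benjamini-Hochberg.

# Exact upper-tail hypergeometric by direct enumeration. For N <= 30 every
# binomial coefficient and product is an exact integer in double precision,
# so this is an exact rational evaluation.
hyper_oracle <- function(k, K, n, N) {
  k <- unname(k)
  K <- unname(K)
  n <- unname(n)
  N <- unname(N)
  if (k == 0) {
    return(1)
  }
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Textbook Pearson correlation from sum formulas (no stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Spearman via mean ranks then the Pearson oracle.
spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# OLS slope by the closed form Sxy / Sxx.
slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Literal Benjamini-Hochberg step-up: sort, p_(i) * m / i, running minimum
# from the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Random valid hypergeometric quadruples with N <= n_max.
random_hyper_cases <- function(n_cases, n_max = 30L) {
  t(vapply(seq_len(n_cases), function(i) {
    N <- sample(2:n_max, 1L)
    K <- sample(0:N, 1L)
    n <- sample(0:N, 1L)
    k <- sample(0:min(n, K), 1L)
    c(k = k, K = K, n = n, N = N)
  }, integer(4)))
}
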