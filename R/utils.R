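# shared numeric helpers

# population moments with the zero-variance convention (skewness and kurtosis
# of a constant sample are defined as 0 so downstream selection stays total)
moment_stats <- function(v) {
  n <- length(v)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 <= 0) {
    c(mean = mu, variance = 0, skewness = 0, kurtosis = 0)
  } else {
    s <- sqrt(s2)
    c(mean = mu,
      variance = s2,
      skewness = mean((v - mu)^3) / s^3,
      kurtosis = mean((v - mu)^4) / s2^2 - 3)
  }
}

# order-statistic percentile: value at rank ceiling(p * n) of the sorted sample
percentile <- function(v, p) {
  sv <- sort(v)
  sv[pmax(1L, ceiling(p * length(sv)))]
}

# 0 * log(0) == 0 entropy convention, natural logarithm
entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# derive a 31-bit child seed from a parent seed and index path (deterministic,
# order-insensitive across unrelated paths; keeps values < 2^31 for set.seed)
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in idx) {
    x <- (x * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
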