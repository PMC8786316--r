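# Internal helpers.

# Run code under a temporary seed when one is supplied; otherwise use the
# current RNG stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Deterministic sub-seed from a master seed and a stage name, kept within
# 32-bit integer range. Adding stages never perturbs existing ones.
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Pearson correlation with the two-sided t-test p-value, vectorized over
# pairs of columns. Returns list(r, p, n). Zero-variance inputs give NA.
pearson_rp <- function(x, y) {
  ok <- stats::sd(x) > 0 && stats::sd(y) > 0
  if (!ok) return(list(r = NA_real_, p = NA_real_, n = length(x)))
  n <- length(x)
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2), n = n)
}
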