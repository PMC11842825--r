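# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's vectorized code paths.

# Scale-dependent variance by explicit loops over blocks.
oracle_scale_variance <- function(x, sizes, min_block_coverage = 0.8,
                                  population = FALSE) {
  n <- length(x)
  vapply(sizes, function(w) {
    vs <- c()
    for (b in seq_len(n %/% w)) {
      blk <- x[((b - 1) * w + 1):(b * w)]
      valid <- blk[!is.na(blk)]
      if (length(valid) / w >= min_block_coverage && length(valid) >= 2) {
        m <- sum(valid) / length(valid)
        ss <- sum((valid - m)^2)
        vs <- c(vs, ss / (if (population) length(valid) else length(valid) - 1))
      }
    }
    if (length(vs)) mean(vs) else NA_real_
  }, numeric(1))
}

# Unweighted OLS slope/intercept from the closed-form normal equations.
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# Percentile trim by direct enumeration (quantile type 7, keep boundary).
oracle_trimmed_mean <- function(x) {
  q <- stats::quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
  mean(x[x >= q[1] & x <= q[2]])
}

# A gapless power-law leg at a given seed (shared study conditions).
powerlaw_leg <- function(beta, seed, n = 500, ...) {
  gen_powerlaw_series(transect_config(beta = beta, n_samples = n,
                                      seed = seed, ...))
}

default_sizes <- as.integer(window_scheme())
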