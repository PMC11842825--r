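test_that("identical config and seed give bit-identical output", {
  cfg <- transect_config(beta = 5/3, n_samples = 200, gap_fraction = 0.1,
                         marginal = "lognormal", mean_level = 0.3,
                         amplitude = 0.1, noise_floor = 0.05, seed = 11)
  expect_identical(gen_powerlaw_series(cfg), gen_powerlaw_series(cfg))
})

test_that("configuration errors are caught", {
  expect_error(transect_config(beta = Inf), "finite")
  expect_error(transect_config(beta = 1, n_samples = 2), "n_samples")
  expect_error(transect_config(beta = 1, gap_fraction = 0.6), "gap_fraction")
  expect_error(transect_config(beta = 1, amplitude = 0), "amplitude")
  expect_error(transect_config(beta = 1, marginal = "lognormal",
                               mean_level = 0), "mean_level")
})

test_that("white noise has negligible lag-1 autocorrelation", {
  r1 <- vapply(1:100, function(i) {
    x <- powerlaw_leg(beta = 0, seed = i)
    stats::cor(x[-1], x[-length(x)])
  }, numeric(1))
  expect_lt(abs(mean(r1)), 0.1)
})

test_that("generated series follow the target spectral slope", {
  # Hann-tapered periodogram: a rectangular window cannot resolve slopes
  # steeper than about -2, so fidelity is checked with a taper.
  pgram_slope <- function(x) {
    n <- length(x)
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    p <- Mod(stats::fft((x - mean(x)) * w))^2 / n
    k <- 2:(n %/% 2)
    unname(oracle_ols(log10(k), log10(p[1 + k]))["slope"])
  }
  for (beta in c(1, 5/3, 2, 3)) {
    slopes <- vapply(1:40, function(i)
      pgram_slope(powerlaw_leg(beta, seed = 7000 + i, n = 4096)), numeric(1))
    expect_lt(abs(mean(slopes) + beta), 0.15)
  }
})

test_that("gap accounting is exact for both patterns", {
  for (pat in c("random_single", "random_blocks")) {
    for (gf in c(0.05, 0.2, 0.5)) {
      x <- gen_powerlaw_series(transect_config(
        beta = 1, n_samples = 500, gap_fraction = gf, gap_pattern = pat,
        seed = 3))
      expect_equal(sum(is.na(x)), round(gf * 500))
    }
  }
})

test_that("lognormal marginal is strictly positive with the target moments", {
  cfg <- transect_config(beta = 1.5, n_samples = 2000,
                         marginal = "lognormal", mean_level = 0.25,
                         amplitude = 0.075, seed = 5)
  x <- gen_powerlaw_series(cfg)
  expect_true(all(x > 0))
  expect_equal(mean(x), 0.25, tolerance = 0.1)
  expect_equal(sd(x), 0.075, tolerance = 0.25)
})

test_that("noise floor adds the stated variance fraction", {
  base <- transect_config(beta = 2, n_samples = 4000, seed = 9)
  noisy <- transect_config(beta = 2, n_samples = 4000, seed = 9,
                           noise_floor = 1)
  v0 <- var(gen_powerlaw_series(base))
  v1 <- var(gen_powerlaw_series(noisy))
  expect_equal(v1 / v0, 2, tolerance = 0.1)
})
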