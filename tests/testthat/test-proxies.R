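wl_grid <- seq(400, 750, by = 5)

test_that("line height vanishes for flat and for linear spectra", {
  expect_equal(chl_line_height(wl_grid, rep(0.2, length(wl_grid))), 0)
  expect_equal(chl_line_height(wl_grid, 0.001 * wl_grid - 0.1), 0,
               tolerance = 1e-12)
})

test_that("line height of a constructed Gaussian peak matches the closed form", {
  # 1 nm grid so 650/676/715 nm are exact grid points and the closed form
  # applies without interpolation error
  wl_fine <- seq(400, 750, by = 1)
  peak_amp <- 0.01; sigma <- 10
  gauss <- function(l) peak_amp * exp(-(l - 676)^2 / (2 * sigma^2))
  ap <- 0.0005 * wl_fine + gauss(wl_fine)
  # expected: peak minus the interpolated baseline through the Gaussian
  # tails at 650 and 715 nm (the affine part cancels exactly)
  frac <- (676 - 650) / (715 - 650)
  expected <- gauss(676) - (gauss(650) + frac * (gauss(715) - gauss(650)))
  expect_equal(chl_line_height(wl_fine, ap), expected, tolerance = 1e-12)
})

test_that("line height is invariant to adding an affine function of wavelength", {
  set.seed(42)
  ap <- 0.02 + 0.005 * exp(-(wl_grid - 676)^2 / 200) + runif(length(wl_grid), 0, 1e-3)
  lh0 <- chl_line_height(wl_grid, ap)
  lh1 <- chl_line_height(wl_grid, ap + 0.3 - 0.002 * wl_grid)
  expect_equal(lh0, lh1, tolerance = 1e-12)
})

test_that("line height over a coverage gap is missing", {
  ap <- rep(0.1, length(wl_grid))
  ap[wl_grid >= 670 & wl_grid <= 680] <- NA
  expect_true(is.na(chl_line_height(wl_grid, ap)))
})

test_that("gamma recovers exact power laws and degenerate cases", {
  cp1 <- (550 / wl_grid)^1.0
  expect_equal(particle_size_gamma(wl_grid, cp1), 1, tolerance = 1e-10)
  expect_equal(particle_size_gamma(wl_grid, rep(0.3, length(wl_grid))), 0,
               tolerance = 1e-12)
  cp07 <- 2.5 * (550 / wl_grid)^0.7
  expect_equal(particle_size_gamma(wl_grid, cp07), 0.7, tolerance = 1e-10)
})

test_that("gamma is invariant to positive scaling and robust to mild noise", {
  cp <- (550 / wl_grid)^0.7
  expect_equal(particle_size_gamma(wl_grid, cp),
               particle_size_gamma(wl_grid, 17.3 * cp), tolerance = 1e-12)
  est <- vapply(1:100, function(i) {
    set.seed(i)
    particle_size_gamma(wl_grid, cp * exp(rnorm(length(wl_grid), 0, 0.01)))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.7), 0.05)
})

test_that("gamma declines missing when too few positive points remain", {
  cp <- rep(-1, length(wl_grid))
  cp[1:4] <- 1
  expect_true(is.na(particle_size_gamma(wl_grid, cp)))
})

test_that("cp_at interpolates linearly and returns grid points unchanged", {
  expect_equal(cp_at(c(440, 444), c(0.10, 0.14), 443), 0.13)
  expect_equal(cp_at(c(440, 443, 446), c(1, 2, 3), 443), 2)
  expect_true(is.na(cp_at(c(450, 500), c(1, 2), 443)))
})

test_that("proxies from long-form tables match the per-spectrum functions", {
  cp <- (550 / wl_grid)^0.9
  ap <- 0.01 + 0.004 * exp(-(wl_grid - 676)^2 / 200)
  long <- tibble::tibble(minute = 1, wavelength_nm = wl_grid,
                         ap_1_m = ap, cp_1_m = cp)
  out <- derive_proxies(long)
  expect_equal(out$gamma_cp, particle_size_gamma(wl_grid, cp))
  expect_equal(out$chl_lh, chl_line_height(wl_grid, ap))
  expect_equal(out$cp443, cp_at(wl_grid, cp))
})
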