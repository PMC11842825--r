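# Hand-built binned object: two filtered periods bracketing total minutes.
toy_binned <- function(fil_vals = c(0.1, 0.2), nw = 3) {
  minutes <- 1:61
  filt <- minutes <= 1 | minutes >= 61
  ap <- matrix(NA_real_, 61, nw)
  ap[1, ] <- fil_vals[1]; ap[61, ] <- fil_vals[2]
  ap[2:60, ] <- 0.5
  structure(
    list(minute = minutes, filtered = filt,
         wavelengths = seq(410, 740, length.out = nw),
         ap = ap, cp = ap, ap_sd = ap * 0, cp_sd = ap * 0,
         n_used = matrix(1, 61, nw)),
    class = "acs_binned"
  )
}

test_that("linear baseline interpolates between filtered medians", {
  part <- derive_particulate(toy_binned(), method = "linear")
  # t = 31 is midway between period mid-times 1 and 61
  i <- which(part$minute == 31)
  expect_equal(part$baseline_ap[i, 1], 0.15)
  expect_equal(part$ap[i, 1], 0.5 - 0.15)
})

test_that("flat fCDOM collapses fcdom_scaled onto the linear method", {
  b <- toy_binned()
  lin <- derive_particulate(b, "linear")
  fcd <- derive_particulate(b, "fcdom_scaled", fcdom = rep(2, 61))
  expect_equal(fcd$baseline_ap, lin$baseline_ap, tolerance = 1e-12)
})

test_that("fCDOM-scaled baseline follows the fCDOM excursion", {
  b <- toy_binned()
  fcdom <- rep(0, 61); fcdom[61] <- 1; fcdom[31] <- 0.75
  out <- derive_particulate(b, "fcdom_scaled", fcdom = fcdom)
  i <- which(out$minute == 31)
  expect_equal(out$baseline_ap[i, 1], 0.1 + 0.75 * (0.2 - 0.1))
})

test_that("baseline plus particulate reconstructs the total exactly", {
  wl <- seq(408, 744, by = 16)
  cfg <- acs_config(duration_min = 130, sample_rate_hz = 1, wavelengths = wl,
                    chl_profile = runif(130, 0.1, 0.6), noise_sd = 1e-4,
                    seed = 5)
  binned <- bin_acs(gen_acs_stream(cfg))
  part <- derive_particulate(binned, "linear")
  expect_equal(part$ap + part$baseline_ap, part$total_ap, tolerance = 1e-12)
  expect_equal(part$cp + part$baseline_cp, part$total_cp, tolerance = 1e-12)
})

test_that("particulate absorption is recovered within 2% of generator truth", {
  wl <- seq(408, 744, by = 8)
  nmin <- 130
  cfg <- acs_config(duration_min = nmin, sample_rate_hz = 4, wavelengths = wl,
                    chl_profile = seq(0.3, 0.6, length.out = nmin),
                    cdom_profile = seq(0.02, 0.025, length.out = nmin),
                    noise_sd = 0, spike_rate = 0, seed = 6)
  st <- gen_acs_stream(cfg)
  part <- derive_particulate(bin_acs(st), "fcdom_scaled",
                             fcdom = cfg$cdom_profile)
  truth <- st$truth$ap_part[part$minute, , drop = FALSE]
  # compare where the particulate signal is appreciable
  big <- truth > 0.005
  rel <- abs(part$ap[big] - truth[big]) / truth[big]
  expect_lt(stats::median(rel), 0.02)
})

test_that("fewer than two filtered periods is a processing error", {
  b <- toy_binned()
  b$filtered <- c(TRUE, rep(FALSE, 60))
  expect_error(derive_particulate(b, "linear"), "filtered periods")
  b$filtered <- rep(FALSE, 61)
  expect_error(derive_particulate(b, "linear"), "no filtered periods")
})
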