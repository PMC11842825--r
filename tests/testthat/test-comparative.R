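# A small gamma table with controllable slope columns.
toy_gamma_table <- function(g_a, g_b, lat = NULL, lon = NULL,
                            abs_a = NULL) {
  n <- length(g_a)
  dplyr::bind_rows(
    tibble::tibble(leg_id = seq_len(n), variable = "a", gamma = g_a,
                   valid = TRUE,
                   mean_abs_value = if (is.null(abs_a)) runif(n) else abs_a,
                   centroid_lat = lat %||% runif(n, -60, 60),
                   centroid_lon = lon %||% runif(n, -180, 180)),
    tibble::tibble(leg_id = seq_len(n), variable = "b", gamma = g_b,
                   valid = TRUE, mean_abs_value = runif(n),
                   centroid_lat = lat %||% runif(n, -60, 60),
                   centroid_lon = lon %||% runif(n, -180, 180))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("correlate_gammas: identity, affine relation, symmetry", {
  set.seed(1)
  g <- rnorm(30)
  t1 <- toy_gamma_table(g, g)
  out <- correlate_gammas(t1, "a", "b")
  expect_equal(out$r_squared, 1, tolerance = 1e-12)
  expect_lt(out$p_value, 1e-10)

  t2 <- toy_gamma_table(g, 2 * g + rnorm(30, 0, 1e-4))
  expect_gt(correlate_gammas(t2, "a", "b")$r_squared, 0.99)

  ab <- correlate_gammas(t2, "a", "b")
  ba <- correlate_gammas(t2, "b", "a")
  expect_equal(ab$r, ba$r)
  # row order invariance
  shuf <- t2[sample(nrow(t2)), ]
  expect_equal(correlate_gammas(shuf, "a", "b")$r, ab$r)
})

test_that("independent slope ensembles sit at the null R^2 level", {
  r2 <- vapply(1:200, function(i) {
    set.seed(i)
    correlate_gammas(toy_gamma_table(rnorm(30), rnorm(30)), "a", "b")$r_squared
  }, numeric(1))
  expect_equal(mean(r2), 1 / 29, tolerance = 0.3)
})

test_that("too few pairs is an error", {
  t1 <- toy_gamma_table(rnorm(2), rnorm(2))
  expect_error(correlate_gammas(t1, "a", "b"), ">= 3 legs")
  expect_error(correlate_gammas(t1, "a", "zz"), "not in table")
})

test_that("scale restriction: no-op at the full scheme, exact on power laws", {
  x <- powerlaw_leg(2, seed = 31)
  full <- leg_gamma(x)
  expect_equal(scale_restricted_gamma(x, 500)$gamma, full$gamma)
  # a scale-free curve keeps its exponent under any truncation
  w <- as.numeric(default_sizes)
  for (cut in c(25, 108, 500)) {
    keep <- w <= cut
    fit <- fit_gamma(tibble::tibble(window_samples = w[keep],
                                    v = w[keep]^1.3, n_blocks = 1L))
    expect_equal(fit$gamma, 1.3, tolerance = 1e-12)
  }
  expect_error(scale_restricted_gamma(x, 3), "fewer than 2")
})

test_that("restricted and full slopes correlate across an ensemble", {
  gs <- purrr::map_dfr(1:40, function(i) {
    x <- powerlaw_leg(5/3, seed = 40 + i)
    tibble::tibble(full = leg_gamma(x)$gamma,
                   small = scale_restricted_gamma(x, 25)$gamma)
  })
  expect_gt(cor(gs$full, gs$small), 0.2)
  expect_gt(sd(gs$full - gs$small), 0)     # but they are not equal
})

test_that("province means are exact on a hand-computed toy table", {
  tab <- tibble::tibble(
    leg_id = 1:6, variable = "a",
    gamma = c(1, 2, 3, 4, 5, 6), valid = TRUE,
    mean_abs_value = c(10, 20, 30, 40, 50, 60),
    centroid_lat = 0, centroid_lon = 0
  )
  mapping <- tibble::tibble(leg_id = 1:6,
                            province = rep(c("P1", "P2"), each = 3))
  out <- province_aggregate(tab, mapping, min_legs = 1)
  expect_equal(out$mean_gamma[out$province == "P1"], 2)
  expect_equal(out$mean_gamma[out$province == "P2"], 5)
  expect_equal(out$mean_abs_value[out$province == "P2"], 50)
})

test_that("the 25-leg province threshold is inclusive", {
  tab <- tibble::tibble(
    leg_id = 1:49, variable = "a", gamma = rnorm(49), valid = TRUE,
    mean_abs_value = 1, centroid_lat = 0, centroid_lon = 0
  )
  mapping <- tibble::tibble(leg_id = 1:49,
                            province = rep(c("big", "small"), c(25, 24)))
  out <- province_aggregate(tab, mapping)
  expect_equal(out$province, "big")
  # one province holding everything reproduces the global mean
  all_one <- province_aggregate(tab,
                                tibble::tibble(leg_id = 1:49, province = "x"))
  expect_equal(all_one$mean_gamma, mean(tab$gamma))
})

test_that("unmapped legs are dropped with a warning; empty mapping errors", {
  tab <- tibble::tibble(leg_id = 1:5, variable = "a", gamma = 1:5,
                        valid = TRUE, mean_abs_value = 1,
                        centroid_lat = 0, centroid_lon = 0)
  mapping <- tibble::tibble(leg_id = 1:3, province = "P")
  expect_warning(out <- province_aggregate(tab, mapping, min_legs = 1),
                 "dropped")
  expect_equal(out$mean_gamma, 2)
  expect_error(province_aggregate(tab, mapping[0, ]), "non-empty")
})

test_that("slope-magnitude relation recovers a constructed dependence", {
  set.seed(7)
  lvl <- runif(40, 0.1, 1)
  tab <- toy_gamma_table(g_a = 0.5 + lvl + rnorm(40, 0, 0.1),
                         g_b = rnorm(40), abs_a = lvl)
  out <- gamma_vs_magnitude(tab, "a")
  expect_equal(out$slope_sign, 1)
  expect_gt(out$r_squared, 0.5)
  # constant regressor is refused
  tab$mean_abs_value[tab$variable == "a"] <- 1
  expect_error(gamma_vs_magnitude(tab, "a"), "constant")
})

test_that("correlogram separates gradients from spatial noise", {
  n <- 60
  lat <- seq(-50, 50, length.out = n)
  lon <- rep(0, n)
  grad <- toy_gamma_table(g_a = lat / 50, g_b = rnorm(n),
                          lat = lat, lon = lon)
  cg <- spatial_autocorrelogram(grad, "a")
  good <- which(!cg$flagged & !is.na(cg$r))
  expect_gt(cg$r[good[1]], cg$r[good[length(good)]])

  set.seed(2)
  rand <- toy_gamma_table(g_a = rnorm(n), g_b = rnorm(n),
                          lat = runif(n, -50, 50), lon = runif(n, -50, 50))
  cr <- spatial_autocorrelogram(rand, "a")
  ok <- !cr$flagged & !is.na(cr$r)
  # pairs in a bin share legs, so the null envelope is wider than the
  # independent-pair 2/sqrt(n); 3/sqrt(n) covers the dependence
  expect_true(all(abs(cr$r[ok]) < 3 / sqrt(cr$n_pairs[ok])))
})

test_that("a single occupied distance bin flags the rest without crashing", {
  n <- 12
  tab <- toy_gamma_table(g_a = rnorm(n), g_b = rnorm(n),
                         lat = rep(c(0, 0.001), 6), lon = rep(0, n))
  cg <- spatial_autocorrelogram(tab, "a", lag_edges_km = c(0, 1, 10, 100))
  expect_true(any(cg$n_pairs > 0))
  expect_true(any(cg$flagged))
})
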