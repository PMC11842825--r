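stream_of <- function(n, step_km = 0.2, chl = NULL) {
  # straight eastward track at the equator: 1 deg lon = 111.195 km
  lon <- -30 + cumsum(c(0, rep(step_km, n - 1))) / 111.19493
  tibble::tibble(
    time = as.POSIXct("2021-06-01", tz = "UTC") + 60 * (seq_len(n) - 1),
    lat = 0, lon = lon,
    chl_mg_m3 = if (is.null(chl)) rep(0.3, n) else chl
  )
}

test_that("segmentation partitions the stream into floor(n/500) legs", {
  legs <- segment_legs(stream_of(1250))
  expect_equal(nrow(legs), 2)
  expect_equal(nrow(segment_legs(stream_of(499))), 0)
  # every kept minute belongs to exactly one leg
  kept <- dplyr::bind_rows(legs$data)
  expect_equal(nrow(kept), 1000)
  expect_equal(anyDuplicated(kept$time), 0)
})

test_that("leg metadata: distance, elapsed time, coverage", {
  legs <- segment_legs(stream_of(500, step_km = 0.2))
  expect_equal(legs$along_track_km, 499 * 0.2, tolerance = 1e-6)
  expect_equal(legs$elapsed_hours, 499 / 60, tolerance = 1e-12)
  expect_equal(legs$coverage_chl_mg_m3, 1)

  chl <- rep(0.3, 500); chl[1:120] <- NA
  legs2 <- segment_legs(stream_of(500, chl = chl))
  expect_equal(legs2$coverage_chl_mg_m3, 380 / 500)
})

test_that("missing rows stretch elapsed time", {
  s <- stream_of(600)
  s <- s[-(101:200), ]                       # 100 minutes never recorded
  legs <- segment_legs(s)
  expect_equal(nrow(legs), 1)
  expect_equal(legs$elapsed_hours, 599 / 60, tolerance = 1e-12)
})

test_that("qc_filter applies every rule with the documented reason codes", {
  legs <- tibble::tibble(
    leg_id = 1:5,
    along_track_km = c(25, 100, 160, 100, 100),
    elapsed_hours = c(8, 8, 8, 16.5, 8),
    coverage_chl_mg_m3 = c(1, 1, 1, 1, 0.79)
  )
  out <- qc_filter(legs, "chl_mg_m3")
  expect_equal(out$qc_pass, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$qc_reason[c(1, 3, 4, 5)],
               c("distance_short", "distance_long", "elapsed", "coverage"))
})

test_that("the coverage boundary is inclusive at exactly 80%", {
  legs <- tibble::tibble(leg_id = 1:2, along_track_km = 100,
                         elapsed_hours = 8,
                         coverage_chl_mg_m3 = c(0.80, 0.799))
  out <- qc_filter(legs, "chl_mg_m3")
  expect_equal(out$qc_pass, c(TRUE, FALSE))
})

test_that("relaxing any criterion never removes a kept leg (monotonicity)", {
  set.seed(1)
  legs <- tibble::tibble(
    leg_id = 1:40,
    along_track_km = runif(40, 10, 200),
    elapsed_hours = runif(40, 6, 20),
    coverage_chl_mg_m3 = runif(40, 0.5, 1)
  )
  strict <- qc_filter(legs, "chl_mg_m3")$qc_pass
  relaxed <- qc_filter(legs, "chl_mg_m3",
                       qc_criteria(min_distance_km = 20,
                                   max_distance_km = 180,
                                   min_coverage = 0.7,
                                   max_elapsed_hours = 18))$qc_pass
  expect_true(all(relaxed[strict]))
})

test_that("unknown variables are a configuration error", {
  legs <- segment_legs(stream_of(500))
  expect_error(qc_filter(legs, "nope"), "unknown variable")
})
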