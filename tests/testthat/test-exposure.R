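test_that("haversine distance matches closed-form great-circle values", {
  expect_equal(haversine_km(30, 110, 30, 110), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 0, 90), 6371 * pi / 2, tolerance = 1e-6)
  expect_equal(haversine_km(12, 34, -45, 100), haversine_km(-45, 100, 12, 34))
  expect_error(haversine_km(91, 0, 0, 0), "latitudes")
})

test_that("station matching picks the nearest admissible station", {
  stations <- tibble::tibble(
    station_id = c("B", "A", "C"),
    lat = c(32.0, 32.5, 33.4),
    lon = c(110.0, 110.5, 110.9)
  )
  pats <- tibble::tibble(
    patient_id = c("p_near", "p_far"),
    lat = c(32.52, 36.0), lon = c(110.52, 110.5)
  )
  m <- match_station(pats, stations, max_km = 50)
  expect_equal(m$station_id[1], "A")
  expect_false(m$excluded[1])
  expect_true(m$excluded[2])        # ~290 km from everything
  # exhaustive triangle check: assigned distance <= distance to every station
  for (i in seq_len(nrow(pats))) {
    d_all <- haversine_km(pats$lat[i], pats$lon[i], stations$lat, stations$lon)
    expect_lte(m$distance_km[i], min(d_all) + 1e-9)
  }
})

test_that("a patient just beyond the radius is excluded, ties break by id", {
  # two stations at identical coordinates: an exact distance tie that must
  # resolve to the lexicographically smallest id
  stations <- tibble::tibble(station_id = c("S2", "S1"),
                             lat = c(32, 32), lon = c(110.0, 110.0))
  pat <- tibble::tibble(patient_id = "p", lat = 32.1, lon = 110.2)
  m <- match_station(pat, stations, max_km = 50)
  expect_equal(m$station_id, "S1")
  far <- tibble::tibble(patient_id = "q", lat = 32.55, lon = 110.0)
  d <- haversine_km(32.55, 110, 32, 110)
  expect_true(d > 50 && d < 70)
  expect_true(match_station(far, stations, max_km = 50)$excluded)
})

test_that("lag matrix reproduces the backward window of an index series", {
  ser <- index_station(100)
  ev <- ser$timestamp[c(30, 50)]
  lm1 <- build_lag_matrix(ser, ev, "temp_c", max_lag = 24)
  expect_equal(lm1$Q[1, ], setNames(29 - (0:24), paste0("lag", 0:24)))
  expect_equal(unname(lm1$Q[2, ]), 49 - (0:24))
  lm0 <- build_lag_matrix(ser, ev, "temp_c", max_lag = 0)
  expect_equal(ncol(lm0$Q), 1L)
  expect_equal(unname(lm0$Q[, 1]), c(29, 49))
})

test_that("missing hours and out-of-range events surface as masks", {
  ser <- index_station(100)[-40, ]          # drop one interior hour
  ev <- index_station(100)$timestamp[50]
  lm1 <- build_lag_matrix(ser, ev, "temp_c", max_lag = 24)
  expect_equal(sum(is.na(lm1$Q)), 1L)       # exactly the dropped hour
  before <- build_lag_matrix(ser, utc("1999-01-01 00:00"), "temp_c", 24)
  expect_true(all(is.na(before$Q)))
})

test_that("double-loop reconstruction matches the vectorised lag matrix", {
  set.seed(11)
  ser <- index_station(80)
  ser$temp_c <- rnorm(80)
  ev <- sample(ser$timestamp, 10)
  lm1 <- build_lag_matrix(ser, ev, "temp_c", max_lag = 12)
  naive <- matrix(NA_real_, 10, 13)
  for (i in 1:10) for (l in 0:12) {
    hit <- which(ser$timestamp == ev[i] - l * 3600)
    if (length(hit)) naive[i, l + 1] <- ser$temp_c[hit]
  }
  expect_equal(unname(lm1$Q), naive)
})

test_that("trimming the integers 1..1000 masks the strict percentile tails", {
  lm1 <- raw_lag_matrix(matrix(1:1000, nrow = 40))
  tr <- trim_extremes(lm1)
  # type-7 percentiles of 1..1000: P1 = 10.99, P99 = 990.01; the values
  # strictly outside are 1..10 and 991..1000
  expect_equal(tr$bounds, c(10.99, 990.01))
  expect_identical(tr$n_masked, 20L)
  expect_identical(which(is.na(tr$lagmat$Q)), which(lm1$Q <= 10 | lm1$Q >= 991))
})

test_that("second-stage contrast values come from the surviving pool", {
  lm1 <- raw_lag_matrix(matrix(1:1000, nrow = 40))
  tr <- trim_extremes(lm1)
  surv <- (1:1000)[(1:1000) >= tr$bounds[1] & (1:1000) <= tr$bounds[2]]
  expect_equal(tr$x_ext, unname(quantile(surv, 0.01, type = 7)))
  expect_equal(tr$x_ref, unname(quantile(surv, 0.99, type = 7)))
})

test_that("retaining extremes is an identity mask", {
  lm1 <- raw_lag_matrix(matrix(rnorm(500, 15, 8), nrow = 20))
  tr <- trim_extremes(lm1, retain_extremes = TRUE)
  expect_identical(tr$lagmat$Q, lm1$Q)
  expect_identical(tr$n_masked, 0L)
  expect_true(all(is.na(tr$bounds)))
})

test_that("a constant pool masks nothing and fails the contrast contract", {
  lm1 <- raw_lag_matrix(matrix(5, 20, 10))
  expect_error(trim_extremes(lm1), "degenerate")
})

test_that("re-masking at the recorded bounds is idempotent", {
  set.seed(3)
  lm1 <- raw_lag_matrix(matrix(rnorm(3000, 15, 8), nrow = 120))
  tr <- trim_extremes(lm1)
  Q <- tr$lagmat$Q
  again <- !is.na(Q) & (Q < tr$bounds[1] | Q > tr$bounds[2])
  expect_identical(sum(again), 0L)
})

test_that("pollutant window means follow the arithmetic contract", {
  ser <- index_station(100)
  ev <- ser$timestamp[c(40, 60)]
  pm <- pollutant_means(ser, ev, max_lag = 24)
  expect_equal(pm$pm25, c(17.8, 17.8))
  expect_false(any(pm$flagged))
  # a ramp over the window: values t-24..t have mean t-12
  ser2 <- ser
  ser2$o3 <- seq_len(nrow(ser)) - 1
  pm2 <- pollutant_means(ser2, ser$timestamp[30], max_lag = 24)
  expect_equal(pm2$o3, 29 - 12)
  # fully masked window
  pm3 <- pollutant_means(ser, utc("1999-06-01 00:00"), max_lag = 24)
  expect_true(pm3$flagged)
  expect_true(is.na(pm3$pm25))
})

test_that("window completion interpolates masked interior cells", {
  Q <- matrix(as.numeric(1:20), 2, 10, byrow = TRUE)
  Q[1, 4] <- NA
  Q[2, 10] <- NA
  lm1 <- raw_lag_matrix(Q)
  filled <- complete_windows(lm1)
  expect_equal(filled$Q[1, 4], (Q[1, 3] + Q[1, 5]) / 2)
  expect_equal(filled$Q[2, 10], Q[2, 9])      # constant extension at the end
  expect_error(complete_windows(raw_lag_matrix(matrix(NA_real_, 1, 5))),
               "fully masked")
})
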