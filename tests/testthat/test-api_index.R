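test_that("sub-index values match the printed piecewise formulas", {
  expect_equal(sub_index("co", 9), 100)
  expect_equal(sub_index("co", 10), 100 + (10 - 9) * 16.66667)
  expect_equal(sub_index("so2", 0.3), 200)
  expect_equal(sub_index("pm10", 0), 0)
  expect_equal(sub_index("pm10", 125), 50 + 75 * 0.5)
  expect_equal(sub_index("o3", 0.1), 100)
})

test_that("breakpoints take the upper-segment value and are near-continuous", {
  breaks <- list(co = c(9, 15, 30), o3 = c(0.2, 0.4), no2 = c(0.17, 0.6, 1.2),
                 so2 = c(0.04, 0.3, 0.6), pm10 = c(50, 350, 420, 500))
  offsets <- list(co = c(100, 200, 300), o3 = c(200, 300),
                  no2 = c(100, 200, 300), so2 = c(100, 200, 300),
                  pm10 = c(50, 200, 300, 400))
  for (p in names(breaks)) {
    expect_equal(sub_index(p, breaks[[p]]), offsets[[p]])
    # left limit from the lower segment differs by < 0.01 (rounded slopes)
    eps <- breaks[[p]] * 1e-9
    left <- sub_index(p, breaks[[p]] - eps)
    expect_true(all(abs(left - offsets[[p]]) < 0.01),
                label = paste("near-continuity for", p))
  }
})

test_that("each sub-index is non-decreasing on its domain", {
  grids <- list(co = seq(0, 60, by = 0.05), o3 = seq(0, 1, by = 0.001),
                no2 = seq(0, 2.4, by = 0.002), so2 = seq(0, 1.2, by = 0.001),
                pm10 = seq(0, 800, by = 0.5))
  for (p in names(grids))
    expect_true(all(diff(sub_index(p, grids[[p]])) >= 0), label = p)
})

test_that("invalid sub-index inputs are rejected", {
  expect_error(sub_index("co", -1), "negative")
  expect_error(sub_index("pm2.5", 10), "unknown pollutant")
})

test_that("API is the max of available sub-indices, permutation-invariant", {
  r <- compute_api(c(50, 40, 30, 20, 10))
  expect_equal(r$api, 50)
  expect_equal(as.character(r$status), "Good")
  r2 <- compute_api(c(101))
  expect_equal(r2$api, 101)
  expect_equal(as.character(r2$status), "Unhealthy")
  expect_equal(compute_api(c(7, 7, 7, 7, 7))$api, 7)
  set.seed(11)
  for (i in 1:20) {
    v <- runif(5, 0, 400)
    v[sample(5, sample(0:3, 1))] <- NA
    expect_equal(compute_api(v)$api, compute_api(sample(v))$api)
    if (!all(is.na(v))) expect_equal(compute_api(v)$api, max(v, na.rm = TRUE))
  }
  allna <- compute_api(c(NA_real_, NA, NA))
  expect_true(allna$all_missing)
  expect_true(is.na(allna$api))
})

test_that("status bands follow the published table with real-valued edges", {
  expect_equal(as.character(classify_status(c(0, 50, 50.5, 100, 150, 200.5,
                                              300, 300.0001, 543))),
               c("Good", "Good", "Moderate", "Moderate", "Unhealthy",
                 "VeryUnhealthy", "VeryUnhealthy", "Hazardous", "Hazardous"))
  expect_error(classify_status(-3), "negative")
})

test_that("pollutant tables round-trip through the sub-index transform", {
  d <- data.frame(timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 3600 * 0:3,
                  co = c(2, NA, 9, 1), o3 = c(0.05, 0.1, NA, 0.01),
                  no2 = c(0.02, NA, 0.2, NA), so2 = c(0.01, 0.02, 0.3, NA),
                  pm10 = c(30, 260, NA, 40))
  out <- api_from_readings(d)
  expect_equal(out$api[1], max(sub_index("co", 2), sub_index("o3", 0.05),
                               sub_index("no2", 0.02), sub_index("so2", 0.01),
                               sub_index("pm10", 30)))
  expect_equal(out$api[2], 155)  # PM10 260 dominates
  expect_equal(as.character(out$status[2]), "Unhealthy")
  expect_equal(out$api[3], 200)  # SO2 at its 0.3 breakpoint
})
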