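hourly <- function(values, start = "2001-01-01 00:00:00") {
  index_series(as.POSIXct(start, tz = "UTC") + 3600 * seq_along(values) - 3600,
               values)
}

test_that("POT selection keeps exactly the strict exceedances in time order", {
  s <- hourly(c(90, 101, 99, 150))
  smp <- pot_exceedances(s, 100)
  expect_equal(smp$values, c(101, 150))
  expect_equal(smp$k, 2)
  expect_equal(smp$n_source, 4)
  expect_equal(pot_exceedances(hourly(c(90, 95, 100)), 100)$k, 0)
  expect_error(pot_exceedances(hourly(numeric(0)), 100), "empty")
})

test_that("clusters are maximal runs of consecutive exceedances", {
  cl <- form_clusters(hourly(c(101, 102, 99, 103)), 100)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$members$value, c(101, 102))
  expect_equal(cl[[2]]$members$value, 103)
  expect_equal(cl[[1]]$peak_value, 102)
  one <- form_clusters(hourly(c(90, 120, 90)), 100)
  expect_length(one, 1)
  expect_equal(one[[1]]$peak_value, 120)
  expect_length(form_clusters(hourly(c(90, 95)), 100), 0)
})

test_that("missing hours and timestamp gaps break runs", {
  s <- hourly(c(101, NA, 102))
  expect_length(form_clusters(s, 100), 2)
  ts <- as.POSIXct("2001-01-01", tz = "UTC") + 3600 * c(0, 1, 5, 6)
  s2 <- index_series(ts, c(101, 102, 103, 104))
  expect_length(form_clusters(s2, 100), 2)
})

test_that("declustering merges clusters closer than r, boundary exact", {
  # two clusters separated by exactly 240 h stay separate; 10 h merge
  v <- rep(50, 300)
  v[10] <- 110; v[250] <- 120  # gap = 240 h
  cl <- form_clusters(hourly(v), 100)
  expect_length(decluster(cl, 240), 2)
  v2 <- rep(50, 300)
  v2[10] <- 110; v2[21] <- 120  # gap = 11 h
  cl2 <- form_clusters(hourly(v2), 100)
  m <- decluster(cl2, 240)
  expect_length(m, 1)
  expect_equal(m[[1]]$peak_value, 120)
  expect_equal(nrow(m[[1]]$members), 2)
  expect_length(decluster(cl2[1], 240), 1)  # single cluster unchanged
  # drop action discards the later cluster instead
  d <- decluster(cl2, 240, action = "drop")
  expect_length(d, 1)
  expect_equal(d[[1]]$peak_value, 110)
})

test_that("declustering is idempotent and monotone in r and u", {
  for (seed in 1:5) {
    s <- random_toy_series(800, seed, u_range = c(60, 140))
    cl <- form_clusters(s, 100)
    d1 <- decluster(cl, 48)
    expect_equal(decluster(d1, 48), d1)
    n_r <- vapply(c(2, 24, 120, 480), function(r) length(decluster(cl, r)),
                  numeric(1))
    expect_true(all(diff(n_r) <= 0))
    k_u <- vapply(c(80, 100, 120), function(u) pot_exceedances(s, u)$k,
                  numeric(1))
    expect_true(all(diff(k_u) <= 0))
  }
})

test_that("cluster maxima are per-cluster peaks with earliest-tie timestamps", {
  v <- rep(50, 40)
  v[5:7] <- c(110, 115, 115)  # tie on the peak
  cl <- form_clusters(hourly(v), 100)
  smp <- cluster_maxima(cl, min_sep = 240)
  expect_equal(smp$method, "POT_BM")
  expect_equal(smp$values, 115)
  expect_equal(smp$timestamps, hourly(v)$timestamp[6])  # earliest of the tie
  expect_equal(cluster_maxima(list())$k, 0)
})

test_that("POT-BM maxima are a subset of POT exceedances and dominate members", {
  s <- random_toy_series(2000, 7, u_range = c(70, 140))
  pot <- pot_exceedances(s, 100)
  cl <- decluster(form_clusters(s, 100), 24)
  pb <- cluster_maxima(cl, 24)
  expect_true(all(pb$values %in% pot$values))
  for (c in cl) expect_true(all(c$members$value <= c$peak_value))
  expect_equal(sum(vapply(cl, function(c) nrow(c$members), numeric(1))), pot$k)
})

test_that("cluster formation and merging match the quadratic reference", {
  for (seed in 1:25) {
    s <- random_toy_series(sample(100:1200, 1), seed)
    expect_clusters_match_oracle(s, 100, sample(c(6, 24, 240), 1))
  }
})

test_that("annual block maxima pick one maximum per covered year", {
  n1 <- 8760
  set.seed(2)
  v <- runif(2 * n1, 40, 60)
  v[100] <- 150; v[n1 + 200] <- 130
  s <- index_series(as.POSIXct("2001-01-01", tz = "UTC") + 3600 * (0:(2 * n1 - 1)), v)
  bm <- annual_block_maxima(s)
  expect_equal(bm$method, "BM")
  expect_equal(bm$values, c(150, 130))
  # a year with insufficient coverage is skipped with a warning
  v2 <- v; v2[(n1 + 1):(2 * n1)] <- NA
  s2 <- index_series(s$timestamp, v2)
  expect_warning(bm2 <- annual_block_maxima(s2), "skipped")
  expect_equal(bm2$values, 150)
})

test_that("select_extremes dispatches to the three strategies consistently", {
  s <- random_toy_series(3000, 13, u_range = c(70, 140), gap_prob = 0)
  pot <- select_extremes(s, "pot", u = 100)
  expect_equal(pot$values, pot_exceedances(s, 100)$values)
  pb <- select_extremes(s, "potbm", u = 100, r = 24)
  expect_equal(pb$values,
               cluster_maxima(decluster(form_clusters(s, 100), 24))$values)
  expect_true(all(pb$values > 100))
  expect_equal(pb$min_sep, 24)
})
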