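# Independent reference implementations used as oracles in the tests.
# These deliberately use different algorithms from the package code paths.

# Direct evaluation of the unbiased probability-weighted-moment sums:
# b_r = (1/n) * sum_i [ (i-1)(i-2)...(i-r) / ((n-1)(n-2)...(n-r)) ] y_(i)
oracle_pwm <- function(x, r) {
  y <- sort(x)
  n <- length(y)
  s <- 0
  for (i in seq_len(n)) {
    w <- 1
    if (r > 0) for (j in seq_len(r)) w <- w * (i - j) / (n - j)
    s <- s + w * y[i]
  }
  s / n
}

oracle_lmoments <- function(x) {
  b0 <- oracle_pwm(x, 0)
  b1 <- oracle_pwm(x, 1)
  b2 <- oracle_pwm(x, 2)
  list(lambda1 = b0, lambda2 = 2 * b1 - b0, lambda3 = 6 * b2 - 6 * b1 + b0)
}

# Reference clustering + declustering: adjacency grouping of exceedance
# indices followed by fixed-point pairwise merging (merge the first adjacent
# pair closer than r, restart, repeat until stable) — quadratic, independent
# of the package's single-pass transitive merge.
oracle_potbm <- function(timestamps, values, u, r) {
  idx <- which(!is.na(values) & values > u)
  if (length(idx) == 0L) return(list(groups = list(), maxima = numeric(0)))
  hrs <- as.numeric(timestamps) / 3600
  groups <- list()
  cur <- idx[1L]
  if (length(idx) > 1L) for (i in 2:length(idx)) {
    if (idx[i] == idx[i - 1L] + 1L && hrs[idx[i]] - hrs[idx[i - 1L]] == 1) {
      cur <- c(cur, idx[i])
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- idx[i]
    }
  }
  groups[[length(groups) + 1L]] <- cur
  repeat {
    merged <- FALSE
    if (length(groups) > 1L) for (i in seq_len(length(groups) - 1L)) {
      gap <- hrs[groups[[i + 1L]][1L]] - hrs[tail(groups[[i]], 1L)]
      if (gap < r) {
        groups[[i]] <- c(groups[[i]], groups[[i + 1L]])
        groups <- groups[-(i + 1L)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  list(groups = groups,
       maxima = vapply(groups, function(g) max(values[g]), numeric(1)))
}

# double-loop sample autocorrelation with the biased 1/n denominator
oracle_acf <- function(x, max_lag) {
  n <- length(x)
  m <- mean(x)
  denom <- sum((x - m)^2)
  vapply(0:max_lag, function(l) {
    s <- 0
    for (t in seq_len(n - l)) s <- s + (x[t] - m) * (x[t + l] - m)
    s / denom
  }, numeric(1))
}

# random hourly toy series with occasional recording gaps and NA values
random_toy_series <- function(n, seed, u_range = c(80, 130), gap_prob = 0.01,
                              na_prob = 0.02) {
  set.seed(seed)
  incr <- 1 + stats::rbinom(n, 1, gap_prob) * sample(1:400, n, replace = TRUE)
  ts <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC") + 3600 * cumsum(incr)
  v <- stats::runif(n, u_range[1], u_range[2])
  v[stats::runif(n) < na_prob] <- NA
  index_series(ts, v)
}

expect_clusters_match_oracle <- function(series, u, r) {
  cl <- decluster(form_clusters(series, u), r)
  or <- oracle_potbm(series$timestamp, series$value, u, r)
  expect_equal(length(cl), length(or$groups))
  expect_equal(vapply(cl, function(c) c$peak_value, numeric(1)), or$maxima)
  expect_equal(unlist(lapply(cl, function(c) c$members$value)),
               unlist(lapply(or$groups, function(g) series$value[g])))
}
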