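test_that("GEV quantile and CDF are mutual inverses", {
  for (shape in c(-0.4, -0.1, 0, 0.2, 0.788)) {
    p <- c(1e-4, 0.1, 0.5, 0.9, 1 - 1e-4)
    q <- qgev(p, 100, 10, shape)
    expect_equal(pgev(q, 100, 10, shape), p, tolerance = 1e-10)
    y <- qgev(c(0.05, 0.5, 0.95), 100, 10, shape)
    expect_equal(qgev(pgev(y, 100, 10, shape), 100, 10, shape), y,
                 tolerance = 1e-10)
  }
})

test_that("Gumbel branch: quantile at p = 1/e is the location parameter", {
  expect_equal(qgev(exp(-1), 100, 10, 0), 100)
})

test_that("shape -> 0 limit agrees with the Gumbel branch", {
  p <- c(0.01, 0.25, 0.5, 0.9, 0.99)
  expect_equal(qgev(p, 100, 10, 1e-8), qgev(p, 100, 10, 0), tolerance = 1e-4)
  y <- qgev(p, 100, 10, 0)
  expect_equal(pgev(y, 100, 10, 1e-8), pgev(y, 100, 10, 0), tolerance = 1e-4)
})

test_that("GEV density integrates to 1 and CDF is monotone on support", {
  for (shape in c(-0.3, 0, 0.4)) {
    lo <- if (shape < 0) 100 + 10 / shape else -Inf
    hi <- if (shape > 0) 100 + 10 / shape else Inf
    q <- integrate(dgev, lo, hi, location = 100, scale = 10, shape = shape,
                   rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
    g <- seq(60, 140, length.out = 200)
    expect_true(all(diff(pgev(g, 100, 10, shape)) >= 0))
    expect_true(all(pgev(g, 100, 10, shape) >= 0 & pgev(g, 100, 10, shape) <= 1))
  }
})

test_that("out-of-support CDF evaluations return the proper tail value", {
  expect_equal(pgev(200, 100, 10, 0.5), 1)    # beyond bounded upper endpoint
  expect_equal(pgev(0, 100, 10, -0.5), 0)     # below heavy-tail lower endpoint
  expect_error(qgev(1.2, 100, 10, 0.1), "in \\(0, 1\\)")
})

test_that("L-moment GEV estimators invert population L-moments", {
  # Gumbel population L-skewness gives shape ~ 0
  tau3_gum <- log(9 / 8) / log(2)
  est <- extremeair:::.gev_lmom_params(
    list(lambda1 = 100, lambda2 = 10, tau3 = tau3_gum))
  expect_lt(abs(est$shape), 0.01)
  # c = 0 gives exactly zero shape (Gumbel branch)
  tau3_c0 <- 2 / (log(2) / log(3)) - 3
  est0 <- extremeair:::.gev_lmom_params(
    list(lambda1 = 0, lambda2 = 1, tau3 = tau3_c0))
  expect_identical(est0$shape, 0)
})

test_that("L-moment fit recovers GEV parameters within Monte-Carlo error", {
  truth <- c(location = 100, scale = 10, shape = 0.2)
  fits <- t(sapply(1:30, function(i) {
    y <- rgev(10000, truth[1], truth[2], truth[3], seed = 1000 + i)
    unlist(extremeair:::.gev_lmom_params(sample_lmoments(y)))
  }))
  mc_se <- apply(fits, 2, sd)
  y42 <- rgev(10000, truth[1], truth[2], truth[3], seed = 42)
  est <- unlist(fit_gev_lmoments(y42)[c("location", "scale", "shape")])
  expect_true(all(abs(est - truth) < 3 * mc_se))
})

test_that("MLE recovers parameters and reports information-based SEs", {
  y <- rgev(5000, 110.863, 12.911, 0.788, seed = 7)
  f <- fit_gev_mle(y)
  est <- c(f$location, f$scale, f$shape)
  expect_true(all(is.finite(f$se)))
  expect_true(all(abs(est - c(110.863, 12.911, 0.788)) < 3 * f$se))
  expect_equal(f$method, "MLE")
  expect_equal(f$n, 5000)
})

test_that("MLE on Gumbel data gives a small shape and beats the kappa=0 fit", {
  y <- rgev(2000, 50, 5, 0, seed = 21)
  f <- fit_gev_mle(y)
  expect_lt(abs(f$shape), 0.1)
  nll <- extremeair:::.gev_negloglik
  expect_gte(-nll(c(f$location, f$scale, f$shape), y),
             -nll(c(f$location, f$scale, 0), y))
})

test_that("scale MLE with other parameters fixed matches a 1-D grid maximizer", {
  y <- rgev(800, 100, 10, 0.2, seed = 3)
  nll <- extremeair:::.gev_negloglik
  f1 <- function(a) nll(c(100, a, 0.2), y)
  grid <- seq(7, 14, by = 0.001)
  a_grid <- grid[which.min(vapply(grid, f1, numeric(1)))]
  a_opt <- optimize(f1, c(5, 20), tol = 1e-9)$minimum
  expect_equal(a_opt, a_grid, tolerance = 2e-3)
})

test_that("return level is the (T-1)/T quantile, increasing in T", {
  f <- list(location = 100, scale = 10, shape = 0)
  expect_equal(gev_return_level(f, 2), 100 - 10 * log(-log(0.5)))
  expect_equal(gev_return_level(f, 10), 100 - 10 * log(-log(0.9)))
  lev <- gev_return_level(list(location = 100, scale = 10, shape = -0.2),
                          c(2, 5, 10, 50, 100))
  expect_true(all(diff(lev) > 0))
  expect_error(gev_return_level(f, 1), "> 1")
})

test_that("estimation error shrinks roughly as 1/sqrt(n)", {
  se_shape <- sapply(c(100, 1000, 10000), function(n) {
    f <- fit_gev_mle(rgev(n, 100, 10, 0.2, seed = 500 + n))
    f$se[["shape"]]
  })
  expect_true(all(diff(se_shape) < 0))
  ratio <- se_shape[1] / se_shape[3]
  expect_gt(ratio, 4)   # ~ sqrt(100) = 10 within sampling slack
  expect_lt(ratio, 25)
})
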