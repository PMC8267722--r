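# Diagnostic surfaces as data: mean-residual-life curve, autocorrelation,
# PP points, and a model-comparison table. Plots are optional renderings of
# the returned data frames.

#' Mean-residual-life curve
#'
#' Mean excess over each threshold in a grid,
#' \eqn{e(u) = \mathrm{mean}(x - u \mid x > u)}, with normal-approximation
#' confidence intervals \eqn{e(u) \pm 1.96\,\mathrm{sd}/\sqrt{n_u}}.
#' Approximate linearity of the curve above a threshold supports a GPD model
#' there. Thresholds with fewer than two exceedances are dropped.
#'
#' @param values Numeric vector (missing values ignored).
#' @param thresholds Numeric grid; defaults to 50 equally spaced values from
#'   the 50th to the 99.5th percentile of the data.
#' @param conf Confidence level (default 0.95).
#' @return Data frame of class `"mrl_curve"` with columns `threshold`,
#'   `mean_excess`, `ci_low`, `ci_high`, `n_exceed`.
#' @export
mean_residual_life <- function(values, thresholds = NULL, conf = 0.95) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("too few observations for a mean-residual-life curve")
  if (is.null(thresholds))
    thresholds <- seq(stats::quantile(x, 0.50), stats::quantile(x, 0.995),
                      length.out = 50)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(thresholds, function(u) {
    exc <- x[x > u] - u
    if (length(exc) < 2L) return(NULL)
    m <- mean(exc); s <- stats::sd(exc); k <- length(exc)
    data.frame(threshold = u, mean_excess = m,
               ci_low = m - zq * s / sqrt(k), ci_high = m + zq * s / sqrt(k),
               n_exceed = k)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no threshold in the grid has at least 2 exceedances")
  class(out) <- c("mrl_curve", "data.frame")
  out
}

#' @export
plot.mrl_curve <- function(x, ..., xlab = "Threshold u", ylab = "Mean excess") {
  plot(x$threshold, x$mean_excess, type = "l", xlab = xlab, ylab = ylab,
       ylim = range(c(x$ci_low, x$ci_high)), ...)
  graphics::lines(x$threshold, x$ci_low, lty = 2)
  graphics::lines(x$threshold, x$ci_high, lty = 2)
  invisible(x)
}

#' Sample autocorrelation function with white-noise band
#'
#' Standard sample ACF (biased 1/n denominator, as in [stats::acf()]) with
#' the approximate 95% white-noise confidence band \eqn{\pm 1.96/\sqrt{n}}.
#' Used to check the independence of extreme samples: raw threshold
#' exceedances from clustered episodes are strongly autocorrelated, while
#' declustered per-cluster maxima should behave like white noise.
#'
#' @param values Numeric vector; must not be constant.
#' @param max_lag Largest lag (`n > max_lag + 1`).
#' @return List of class `"acf_result"`: `lags` (0..max_lag), `acf`
#'   (`acf[1] == 1` at lag 0), `conf_band`, `n`.
#' @export
acf_diagnostic <- function(values, max_lag = 30) {
  x <- as.numeric(values)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n <= max_lag + 1) stop("series too short for the requested number of lags")
  if (stats::sd(x) == 0) stop("ACF undefined for a constant series")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(lags = 0:max_lag, acf = as.numeric(a$acf),
                 conf_band = 1.96 / sqrt(n), n = n),
            class = "acf_result")
}

#' @export
plot.acf_result <- function(x, ..., xlab = "Lag", ylab = "ACF") {
  plot(x$lags, x$acf, type = "h", ylim = c(min(-x$conf_band * 1.5, min(x$acf)), 1),
       xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(-1, 1) * x$conf_band, lty = 2, col = "blue")
  graphics::abline(h = 0)
  invisible(x)
}

#' Probability-probability (PP) points for a fitted model
#'
#' Pairs the empirical plotting positions \eqn{i/(n+1)} (Weibull) of the
#' order statistics with the fitted model CDF evaluated at them. Points close
#' to the diagonal indicate a good fit.
#'
#' @param x Numeric vector or [extreme_sample].
#' @param fit A `"gev_fit"` or `"gpd_fit"`.
#' @return Data frame with columns `empirical`, `model`, sorted, both in
#'   \[0, 1\].
#' @export
pp_points <- function(x, fit) {
  y <- sort(.sample_values(x))
  n <- length(y)
  emp <- seq_len(n) / (n + 1)
  model <- if (inherits(fit, "gev_fit")) {
    pgev(y, fit$location, fit$scale, fit$shape)
  } else if (inherits(fit, "gpd_fit")) {
    pgpd(y, fit$threshold, fit$scale, fit$shape)
  } else stop("fit must be a gev_fit or gpd_fit")
  data.frame(empirical = emp, model = model)
}

#' Model-comparison table across selection approaches
#'
#' Long-format table of parameter estimates and standard errors for a set of
#' fitted extreme-value models, one block of rows per approach (e.g. GEV/BM,
#' GPD/POT, GEV/POT-BM), for side-by-side precision comparison.
#'
#' @param fits List of `"gev_fit"` / `"gpd_fit"` objects.
#' @param labels Character labels, one per fit; defaults to `names(fits)` or
#'   the family/method.
#' @return Data frame with columns `model`, `family`, `method`, `k`,
#'   `parameter`, `estimate`, `std_error`.
#' @export
model_comparison_report <- function(fits, labels = NULL) {
  if (length(fits) == 0L) stop("at least one fit is required")
  if (is.null(labels)) labels <- names(fits)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "gev_fit")) {
      family <- "GEV"; pars <- c(location = f$location, scale = f$scale, shape = f$shape)
      k <- f$n
    } else if (inherits(f, "gpd_fit")) {
      family <- "GPD"; pars <- c(scale = f$scale, shape = f$shape)
      k <- f$k
    } else stop("fits must be gev_fit or gpd_fit objects")
    lab <- if (!is.null(labels) && !is.na(labels[i]) && nzchar(labels[i]))
      labels[i] else paste(family, f$method, sep = "/")
    data.frame(model = lab, family = family, method = f$method, k = k,
               parameter = names(pars), estimate = unname(pars),
               std_error = unname(f$se[names(pars)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
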