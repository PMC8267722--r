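# Return-level curves with delta-method confidence intervals, and
# nonparametric bootstrap standard errors.

.num_grad <- function(f, theta) {
  g <- numeric(length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    g[j] <- (f(tp) - f(tm)) / (2 * h)
  }
  g
}

#' Return-level curve with delta-method confidence intervals
#'
#' For a fitted GEV, `periods` are return periods in blocks (years for annual
#' or episode maxima). For a fitted GPD, `periods` are in years and are
#' converted to observation counts `m = periods * n_per_block`
#' (default 8760 h/yr for hourly data); the exceedance rate \eqn{\zeta_u}
#' enters the delta method with binomial variance
#' \eqn{\zeta_u(1-\zeta_u)/n}. Confidence intervals use the gradient of the
#' return level with respect to the parameters and the estimated parameter
#' covariance; when no covariance is available the curve is returned without
#' intervals, with a warning.
#'
#' @param fit A `"gev_fit"` or `"gpd_fit"` object.
#' @param periods Numeric vector of return periods (blocks for GEV, years for
#'   GPD).
#' @param n_per_block Observations per year for the GPD conversion.
#' @param conf Confidence level (default 0.95).
#' @return Data frame of class `"return_level_curve"` with columns `period`,
#'   `level`, `ci_low`, `ci_high`; attribute `model` is `"GEV"` or `"GPD"`.
#' @export
return_level_curve <- function(fit, periods, n_per_block = 8760, conf = 0.95) {
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  if (inherits(fit, "gev_fit")) {
    model <- "GEV"
    level <- gev_return_level(fit, periods)
    theta <- c(fit$location, fit$scale, fit$shape)
    cov <- fit$cov
    var_fun <- function(Ti) {
      g <- .num_grad(function(th) qgev((Ti - 1) / Ti, th[1], th[2], th[3]), theta)
      drop(t(g) %*% cov %*% g)
    }
  } else if (inherits(fit, "gpd_fit")) {
    model <- "GPD"
    m <- periods * n_per_block
    level <- gpd_return_level(fit, m)
    theta <- c(fit$scale, fit$shape, fit$zeta_u)
    cov <- NULL
    if (!is.null(fit$cov)) {
      cov <- matrix(0, 3, 3)
      cov[1:2, 1:2] <- fit$cov
      cov[3, 3] <- fit$zeta_u * (1 - fit$zeta_u) / fit$n
    }
    var_fun <- function(mi) {
      g <- .num_grad(function(th) {
        mz <- mi * th[3]
        if (abs(th[2]) < .SHAPE_EPS) fit$threshold + th[1] * log(mz)
        else fit$threshold + th[1] / th[2] * (mz^th[2] - 1)
      }, theta)
      drop(t(g) %*% cov %*% g)
    }
  } else stop("fit must be a gev_fit or gpd_fit")

  if (is.null(cov) || any(!is.finite(cov))) {
    warning("no parameter covariance available: curve returned without confidence intervals")
    ci_low <- ci_high <- rep(NA_real_, length(periods))
  } else {
    arg <- if (model == "GEV") periods else periods * n_per_block
    v <- vapply(arg, var_fun, numeric(1))
    v[v < 0] <- 0
    ci_low <- level - zq * sqrt(v)
    ci_high <- level + zq * sqrt(v)
  }
  out <- data.frame(period = periods, level = level,
                    ci_low = ci_low, ci_high = ci_high)
  class(out) <- c("return_level_curve", "data.frame")
  attr(out, "model") <- model
  attr(out, "conf") <- conf
  out
}

#' @export
plot.return_level_curve <- function(x, ..., log_x = TRUE,
                                    xlab = "Return period", ylab = "Return level") {
  plot(x$period, x$level, type = "l", log = if (log_x) "x" else "",
       xlab = xlab, ylab = ylab,
       ylim = range(c(x$level, x$ci_low, x$ci_high), na.rm = TRUE), ...)
  if (!all(is.na(x$ci_low))) {
    graphics::lines(x$period, x$ci_low, lty = 2)
    graphics::lines(x$period, x$ci_high, lty = 2)
  }
  invisible(x)
}

#' Nonparametric bootstrap standard errors for an extreme-value fit
#'
#' Resamples the extreme sample with replacement, refits with `fitter`, and
#' reports the standard deviation (and covariance) of the `B` refitted
#' parameter vectors. Refits that fail (e.g. degenerate resamples) are
#' dropped; more than 10% failures is an error.
#'
#' @param x Numeric vector or [extreme_sample].
#' @param fitter Function taking a numeric vector and returning a named
#'   numeric parameter vector.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; recorded in the output.
#' @return List with `se` (named vector), `cov`, `estimates` (B x p matrix of
#'   successful refits), `B`, `n_failed`, `seed`.
#' @export
bootstrap_se <- function(x, fitter, B = 1000, seed = NULL) {
  y <- .sample_values(x)
  y <- y[!is.na(y)]
  if (B < 100) stop("B must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    reps[[b]] <- suppressWarnings(
      tryCatch(fitter(y[sample.int(n, n, replace = TRUE)]),
               error = function(e) NULL))
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (mean(!ok) > 0.10)
    stop(sprintf("bootstrap failed: %.0f%% of refits errored", 100 * mean(!ok)))
  est <- do.call(rbind, reps[ok])
  list(se = apply(est, 2L, stats::sd), cov = stats::cov(est),
       estimates = est, B = B, n_failed = sum(!ok), seed = seed)
}
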