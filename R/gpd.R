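# Generalized Pareto distribution for threshold excesses, Coles convention:
#   G(y) = 1 - (1 + xi * y / sigma)^(-1/xi),  xi != 0,  y = x - u > 0
#   G(y) = 1 - exp(-y / sigma),               xi  = 0 (exponential limit)
# Positive xi gives a heavy (Pareto-type) upper tail; xi < 0 a finite upper
# endpoint at u - sigma/xi. Note the GEV functions in this package use the
# Hosking convention; the shape mapping is kappa_Hosking = -xi_Coles.

.check_gpd_params <- function(scale, shape) {
  if (!is.finite(scale) || !is.finite(shape) || scale <= 0)
    stop("invalid GPD parameters: scale must be > 0 and parameters finite")
}

#' GPD distribution function for exceedances over a threshold
#'
#' @param q Quantiles on the original data scale (`q >= threshold`).
#' @param threshold Threshold `u`; excesses are `q - threshold`.
#' @param scale,shape GPD scale (`> 0`) and shape (Coles convention).
#' @return `P(X <= q | X > threshold)`; 0 below the threshold, 1 beyond a
#'   finite upper endpoint.
#' @export
pgpd <- function(q, threshold = 0, scale, shape) {
  .check_gpd_params(scale, shape)
  y <- q - threshold
  if (abs(shape) < .SHAPE_EPS) return(ifelse(y < 0, 0, 1 - exp(-y / scale)))
  t <- 1 + shape * y / scale
  ifelse(y < 0, 0, ifelse(t > 0, 1 - t^(-1 / shape), 1))
}

#' GPD density
#' @inheritParams pgpd
#' @param x Quantiles on the original data scale.
#' @return Density values; 0 outside the support.
#' @export
dgpd <- function(x, threshold = 0, scale, shape) {
  .check_gpd_params(scale, shape)
  y <- x - threshold
  if (abs(shape) < .SHAPE_EPS)
    return(ifelse(y < 0, 0, exp(-y / scale) / scale))
  t <- 1 + shape * y / scale
  ifelse(y >= 0 & t > 0, t^(-1 / shape - 1) / scale, 0)
}

#' GPD quantile function
#' @param p Probabilities in (0, 1).
#' @inheritParams pgpd
#' @return Quantiles on the original data scale.
#' @export
qgpd <- function(p, threshold = 0, scale, shape) {
  .check_gpd_params(scale, shape)
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (abs(shape) < .SHAPE_EPS) return(threshold - scale * log(1 - p))
  threshold + scale / shape * ((1 - p)^(-shape) - 1)
}

#' Sample from the GPD by inverse-transform sampling
#' @param n Number of draws.
#' @inheritParams pgpd
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
rgpd <- function(n, threshold = 0, scale, shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qgpd(stats::runif(n), threshold, scale, shape)
}

# negative of log L = -k log sigma - (1 + 1/xi) sum log(1 + xi y_i / sigma)
.gpd_negloglik <- function(par, y) {
  scale <- par[1L]; shape <- par[2L]
  if (!all(is.finite(par)) || scale <= 0) return(1e10)
  k <- length(y)
  if (abs(shape) < .SHAPE_EPS)
    return(k * log(scale) + sum(y) / scale)
  t <- 1 + shape * y / scale
  if (any(t <= 0)) return(1e10 + sum(pmax(0, -t)))
  k * log(scale) + (1 + 1 / shape) * sum(log(t))
}

#' Fit a GPD to threshold excesses by maximum likelihood
#'
#' Maximizes the GPD log-likelihood
#' \deqn{\log L = -k\log\sigma - (1 + 1/\xi)\sum_i \log(1 + \xi y_i/\sigma)}
#' over the excesses \eqn{y_i = x_i - u} numerically, with method-of-moments
#' and exponential starts. The empirical exceedance rate
#' \eqn{\zeta_u = k/n} is stored for return-level computation. Standard errors
#' come from the inverse observed information. `shape_fixed = 0` fits the
#' exponential sub-model, whose MLE is the mean excess in closed form.
#'
#' @param x Exceedance values (all `> threshold`): numeric vector or an
#'   [extreme_sample] (which carries `n_source`).
#' @param threshold Threshold `u`.
#' @param n_total Number of raw observations behind the exceedances; taken
#'   from an `extreme_sample` if missing.
#' @param shape_fixed Optional fixed shape (only `0` supported): exponential
#'   closed form.
#' @return Object of class `"gpd_fit"` with `threshold`, `scale`, `shape`
#'   (Coles convention), `se`, `cov`, `zeta_u`, `n`, `k`, `loglik`, `data`
#'   (the excesses).
#' @export
fit_gpd_mle <- function(x, threshold, n_total = NULL, shape_fixed = NULL) {
  vals <- .sample_values(x)
  vals <- vals[!is.na(vals)]
  if (missing(threshold) && inherits(x, "extreme_sample") && !is.null(x$threshold))
    threshold <- x$threshold
  if (is.null(n_total)) {
    n_total <- if (inherits(x, "extreme_sample")) x$n_source else length(vals)
  }
  if (any(vals <= threshold)) stop("all values must exceed the threshold")
  y <- vals - threshold
  k <- length(y)
  if (k < 2L) stop("need at least 2 exceedances to fit a GPD")
  if (k < 10L && is.null(shape_fixed))
    warning("fewer than 10 exceedances: MLE may be unstable")
  zeta <- k / n_total
  if (!is.null(shape_fixed)) {
    if (shape_fixed != 0) stop("only shape_fixed = 0 (exponential) is supported")
    sc <- mean(y)
    ll <- -.gpd_negloglik(c(sc, 0), y)
    se <- c(scale = sc / sqrt(k), shape = NA_real_)
    return(.new_evd_fit("gpd_fit", list(threshold = threshold, scale = sc, shape = 0),
                        se, NULL, "MLE-exponential", n_total, ll, y,
                        extra = list(k = k, zeta_u = zeta)))
  }
  m <- mean(y); v <- stats::var(y)
  mom <- c(m * (m^2 / v + 1) / 2, (1 - m^2 / v) / 2)  # method-of-moments start
  starts <- list(mom, c(m, 0.05), c(m / 2, 0.4), c(2 * m, -0.2))
  best <- NULL
  for (st in starts) {
    if (st[1L] <= 0 || .gpd_negloglik(st, y) >= 1e10) next
    o <- tryCatch(
      stats::optim(st, .gpd_negloglik, y = y, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o)) next
    o2 <- tryCatch(
      stats::optim(o$par, .gpd_negloglik, y = y, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) o)
    if (o2$value <= o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    stop("GPD maximum-likelihood fit did not converge from any start")
  par <- best$par
  names(par) <- c("scale", "shape")
  hs <- .observed_info(.gpd_negloglik, par, y)
  .new_evd_fit("gpd_fit",
               list(threshold = threshold, scale = par[["scale"]],
                    shape = par[["shape"]]),
               hs$se, hs$cov, "MLE", n_total, -best$value, y,
               extra = list(k = k, zeta_u = zeta,
                            convergence = best$convergence))
}

#' Unconditional exceedance probability under a fitted GPD
#'
#' \deqn{P(X > y) = \zeta_u [1 + \xi (y-u)/\sigma]^{-1/\xi}} with the
#' empirical rate \eqn{\zeta_u = k/n}; exponential form when \eqn{\xi = 0}.
#'
#' @param y Level(s) at or above the threshold.
#' @param fit A `"gpd_fit"` object.
#' @return Probability that a raw observation exceeds `y`.
#' @export
gpd_exceedance_prob <- function(y, fit) {
  if (any(y < fit$threshold)) stop("y must be at or above the threshold")
  fit$zeta_u * (1 - pgpd(y, fit$threshold, fit$scale, fit$shape))
}

#' GPD return level
#'
#' Level exceeded on average once every `m` observations:
#' \deqn{y_m = u + (\sigma/\xi)[(m\zeta_u)^{\xi} - 1]}, or
#' \eqn{u + \sigma\log(m\zeta_u)} for \eqn{\xi = 0}. Requires
#' \eqn{m\zeta_u \ge 1}; below that the threshold itself is returned with a
#' warning.
#'
#' @param fit A `"gpd_fit"` object.
#' @param m Return period(s) in number of observations.
#' @return Numeric vector of return levels.
#' @export
gpd_return_level <- function(fit, m) {
  mz <- m * fit$zeta_u
  if (any(mz < 1)) {
    warning("return period below 1/zeta_u: level is below the threshold, returning u")
  }
  lev <- if (abs(fit$shape) < .SHAPE_EPS) {
    fit$threshold + fit$scale * log(mz)
  } else {
    fit$threshold + fit$scale / fit$shape * (mz^fit$shape - 1)
  }
  ifelse(mz < 1, fit$threshold, lev)
}

#' @export
print.gpd_fit <- function(x, ...) {
  cat("GPD fit (", x$method, ", Coles shape convention), threshold = ",
      x$threshold, "\n", sep = "")
  cat("k =", x$k, "exceedances of n =", x$n,
      sprintf("(zeta_u = %.5f)\n", x$zeta_u))
  est <- c(scale = x$scale, shape = x$shape)
  tab <- rbind(estimate = est, std_error = x$se[names(est)])
  print(round(tab, 4))
  cat("log-likelihood:", format(x$loglik, digits = 6), "\n")
  invisible(x)
}
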