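#' Sample L-moments via unbiased probability-weighted moments
#'
#' Computes the first three sample L-moments and the L-skewness ratio from the
#' unbiased probability-weighted-moment (PWM) estimators
#' \deqn{b_r = n^{-1} \sum_i \frac{(i-1)(i-2)\cdots(i-r)}{(n-1)(n-2)\cdots(n-r)} y_{(i)},}
#' with \eqn{\lambda_1 = b_0}, \eqn{\lambda_2 = 2 b_1 - b_0},
#' \eqn{\lambda_3 = 6 b_2 - 6 b_1 + b_0} and \eqn{\tau_3 = \lambda_3/\lambda_2}.
#'
#' @param x Numeric vector, `n >= 3` (the third L-moment needs `n >= 4` to be
#'   meaningful; it is still returned for `n = 3` as the PWM identity allows).
#' @return Object of class `"lmoments"`: list with `lambda1`, `lambda2`,
#'   `lambda3`, `tau3`, the PWMs `b0`, `b1`, `b2`, and `n`.
#' @export
sample_lmoments <- function(x) {
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations for L-moments")
  y <- sort(x)
  i <- seq_len(n)
  b0 <- mean(y)
  b1 <- mean((i - 1) / (n - 1) * y)
  b2 <- mean((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * y)
  lambda1 <- b0
  lambda2 <- 2 * b1 - b0
  lambda3 <- 6 * b2 - 6 * b1 + b0
  if (lambda2 <= 0)
    stop("degenerate sample: second L-moment is not positive (constant data?)")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 tau3 = lambda3 / lambda2, b0 = b0, b1 = b1, b2 = b2, n = n),
            class = "lmoments")
}

#' @export
print.lmoments <- function(x, ...) {
  cat("Sample L-moments (n =", x$n, ")\n")
  cat(sprintf("  lambda1 = %.6g  lambda2 = %.6g  lambda3 = %.6g  tau3 = %.6g\n",
              x$lambda1, x$lambda2, x$lambda3, x$tau3))
  invisible(x)
}
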