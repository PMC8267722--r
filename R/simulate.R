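# Seeded generator of synthetic hourly API-like series with clustered
# exceedance episodes, emulating the structure of urban hourly API records:
# a persistent healthy-air baseline (mean ~55, sd ~21) punctuated by rare
# haze-like episodes lasting hours to days during which the index exceeds
# the unhealthy level of 100, with heavy-tailed excesses.

.UNHEALTHY <- 100  # episode threshold on the API scale
.BASELINE_CAP <- 99  # baseline stays in the healthy regime by construction

#' Episode model for the synthetic API generator
#'
#' Defaults emulate the descriptive statistics typical of hourly urban
#' Malaysian API records (mean 55, sd 21, heavy right tail) and the fitted POT excess
#' distribution (GPD scale ~24, shape ~0.29): a clipped Gaussian AR(1)
#' baseline plus Poisson-arriving exceedance episodes with geometric-tailed
#' durations averaging three days.
#'
#' @param baseline_mean,baseline_sd Marginal mean and sd of the healthy-air
#'   baseline (index units).
#' @param ar1_phi Hourly AR(1) coefficient of the baseline, in (0, 1).
#' @param episode_rate Episode arrivals per year (Poisson).
#' @param episode_duration_mean Mean above-threshold episode duration, hours
#'   (geometric-tailed).
#' @param excess_scale,excess_shape GPD scale/shape (Coles convention) of the
#'   hourly excesses over 100 during episodes.
#' @param excess_ar1 Gaussian-copula AR(1) coefficient of the excesses within
#'   an episode, in \[0, 1): the marginal excess distribution stays exactly
#'   GPD while consecutive excesses are dependent, as in real haze episodes.
#'   Set to 0 for i.i.d. excesses.
#' @param span_years Series length in years of 8760 hours.
#' @param seed Integer seed; one seed drives all stochastic components.
#' @return Validated list of class `"episode_model"`.
#' @export
episode_model <- function(baseline_mean = 55, baseline_sd = 21, ar1_phi = 0.95,
                          episode_rate = 2, episode_duration_mean = 72,
                          excess_scale = 24, excess_shape = 0.29,
                          excess_ar1 = 0.8, span_years = 24, seed = 1) {
  m <- list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
            ar1_phi = ar1_phi, episode_rate = episode_rate,
            episode_duration_mean = episode_duration_mean,
            excess_scale = excess_scale, excess_shape = excess_shape,
            excess_ar1 = excess_ar1, span_years = span_years, seed = seed)
  bad <- !vapply(m, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                 logical(1))
  if (any(bad)) stop("non-numeric episode model field(s): ",
                     paste(names(m)[bad], collapse = ", "))
  if (baseline_sd <= 0) stop("baseline_sd must be positive")
  if (ar1_phi <= 0 || ar1_phi >= 1) stop("ar1_phi must be in (0, 1)")
  if (episode_rate <= 0) stop("episode_rate must be positive")
  if (episode_duration_mean < 1) stop("episode_duration_mean must be >= 1 hour")
  if (excess_scale <= 0) stop("excess_scale must be positive")
  if (excess_ar1 < 0 || excess_ar1 >= 1) stop("excess_ar1 must be in [0, 1)")
  if (span_years < 1) stop("span_years must be at least 1")
  structure(m, class = "episode_model")
}

#' Simulate a synthetic hourly API-like series
#'
#' Builds an hourly series over `span_years` years (from 1997-01-01 00:00
#' UTC) as a clipped Gaussian AR(1) baseline, capped just below the unhealthy
#' level of 100, overlaid with Poisson-arriving episodes. During an episode's
#' above-threshold core the value is `100 +` a GPD excess (exact marginal;
#' within-episode dependence through a Gaussian-copula AR(1) when
#' `excess_ar1 > 0`); a short rise (6 h) and decay (12 h) envelope pulls the
#' sub-threshold hours toward the threshold on the way in and out. All
#' randomness derives from the single model seed, so repeated calls are
#' bitwise identical.
#'
#' @param model An [episode_model()].
#' @return An [index_series].
#' @export
simulate_series <- function(model) {
  if (!inherits(model, "episode_model")) stop("model must be an episode_model")
  set.seed(model$seed)
  n <- model$span_years * 8760L
  times <- as.POSIXct("1997-01-01 00:00:00", tz = "UTC") + 3600 * (0:(n - 1))

  # stationary AR(1) baseline
  innov_sd <- model$baseline_sd * sqrt(1 - model$ar1_phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  b <- as.numeric(stats::filter(e, model$ar1_phi, method = "recursive",
                                init = stats::rnorm(1, 0, model$baseline_sd)))
  values <- pmin(pmax(model$baseline_mean + b, 0), .BASELINE_CAP)

  # Poisson episode arrivals (exponential inter-arrival gaps, in hours)
  hourly_rate <- model$episode_rate / 8760
  arrivals <- integer(0)
  t_cur <- 0
  repeat {
    t_cur <- t_cur + stats::rexp(1, hourly_rate)
    if (t_cur > n) break
    arrivals <- c(arrivals, as.integer(ceiling(t_cur)))
  }
  rise_len <- 6L; decay_len <- 12L
  for (h0 in arrivals) {
    dur <- stats::rgeom(1, 1 / model$episode_duration_mean) + 1L
    core <- h0:min(h0 + dur - 1L, n)
    # exact-GPD-marginal excesses with within-episode copula dependence
    w <- as.numeric(stats::filter(
      stats::rnorm(length(core), 0, sqrt(1 - model$excess_ar1^2)),
      model$excess_ar1, method = "recursive", init = stats::rnorm(1)))
    p <- pmin(pmax(stats::pnorm(w), 1e-12), 1 - 1e-12)  # guard double rounding
    exc <- qgpd(p, 0, model$excess_scale, model$excess_shape)
    values[core] <- pmax(values[core], .UNHEALTHY + exc)
    # sub-threshold rise and decay envelope
    rise <- (h0 - rise_len):(h0 - 1L)
    frac_r <- seq_len(rise_len) / (rise_len + 1)
    ok <- rise >= 1L
    values[rise[ok]] <- pmax(values[rise[ok]],
                             pmin(values[rise[ok]] +
                                    frac_r[ok] * (.UNHEALTHY - values[rise[ok]]),
                                  .BASELINE_CAP))
    dec <- (core[length(core)] + 1L):(core[length(core)] + decay_len)
    frac_d <- rev(seq_len(decay_len)) / (decay_len + 1)
    ok <- dec <= n
    values[dec[ok]] <- pmax(values[dec[ok]],
                            pmin(values[dec[ok]] +
                                   frac_d[ok] * (.UNHEALTHY - values[dec[ok]]),
                                 .BASELINE_CAP))
  }
  index_series(times, values)
}
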