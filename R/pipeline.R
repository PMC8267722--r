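# End-to-end pipeline: select extremes -> fit -> diagnostics -> return levels.

.pipeline_error <- function(msg, exit_code) {
  structure(class = c("extremeair_error", "error", "condition"),
            list(message = msg, call = NULL, exit_code = exit_code))
}

#' Run the full extreme-value analysis pipeline
#'
#' Reads (or accepts) an hourly index series, selects an extreme sample by
#' the requested method, fits the matching extreme-value model (GEV for BM
#' and POT-BM, GPD for POT), computes diagnostics and a return-level curve,
#' and writes everything under `output_dir` as CSV/JSON. With
#' `estimation = "auto"`, BM samples (small k) are fitted by L-moments with
#' bootstrap standard errors and POT / POT-BM samples by maximum likelihood.
#'
#' @param input Path to a series CSV (columns `timestamp`, `value`) or an
#'   [index_series].
#' @param output_dir Directory for the report files (created if needed).
#' @param method `"potbm"`, `"pot"` or `"bm"`.
#' @param threshold POT threshold `u` (default 100).
#' @param min_sep_hours Declustering separation `r` in hours (default 240).
#' @param estimation `"auto"`, `"lmoments"` or `"mle"`.
#' @param bootstrap_B Bootstrap replicates for L-moment standard errors.
#' @param seed Seed for bootstrap resampling (recorded in the fit report).
#' @param n_per_block Observations per year (default 8760, hourly data).
#' @param periods Return periods in years for the return-level curve.
#' @param decluster_action Passed to [decluster()].
#' @return Invisibly, a list with the `sample`, `fit`, diagnostics, the
#'   return-level `curve` and the written file `paths`. Errors carry class
#'   `"extremeair_error"` with an `exit_code` field (2 validation,
#'   3 convergence, 4 insufficient extremes).
#' @export
run_pipeline <- function(input, output_dir,
                         method = c("potbm", "pot", "bm"),
                         threshold = 100, min_sep_hours = 240,
                         estimation = c("auto", "lmoments", "mle"),
                         bootstrap_B = 1000, seed = 1, n_per_block = 8760,
                         periods = c(2, 5, 10, 20, 50, 100),
                         decluster_action = "merge") {
  method <- match.arg(method)
  estimation <- match.arg(estimation)
  if (threshold <= 0) stop(.pipeline_error("threshold must be positive", 2L))
  if (min_sep_hours <= 0) stop(.pipeline_error("min_sep_hours must be positive", 2L))
  series <- if (is.character(input)) {
    tryCatch(read_index_series(input),
             error = function(e) stop(.pipeline_error(conditionMessage(e), 2L)))
  } else .as_index_series(input)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  smp <- select_extremes(series, method, u = threshold, r = min_sep_hours,
                         decluster_action = decluster_action)
  if (smp$k == 0L)
    stop(.pipeline_error("no exceedances above the threshold", 4L))
  if (smp$k < 4L)
    stop(.pipeline_error(sprintf("only %d extreme points selected: need at least 4",
                                 smp$k), 4L))
  message(sprintf("selected %d extreme points by %s", smp$k, smp$method))

  use_lmom <- estimation == "lmoments" ||
    (estimation == "auto" && method == "bm")
  fit <- tryCatch({
    if (method == "pot") {
      fit_gpd_mle(smp, threshold = threshold)
    } else if (use_lmom) {
      fit_gev_lmoments(smp, se = "bootstrap", B = bootstrap_B, seed = seed)
    } else {
      fit_gev_mle(smp)
    }
  }, error = function(e) {
    if (inherits(e, "extremeair_error")) stop(e)
    stop(.pipeline_error(paste("model fitting failed:", conditionMessage(e)), 3L))
  })

  mrl <- mean_residual_life(series$value)
  acf_sample <- acf_diagnostic(smp$values,
                               max_lag = min(30L, smp$k - 2L))
  pp <- pp_points(smp, fit)
  curve <- return_level_curve(fit, periods, n_per_block = n_per_block)

  paths <- list(
    sample = file.path(output_dir, "sample.csv"),
    fit = file.path(output_dir, "fit.json"),
    mrl = file.path(output_dir, "mrl.csv"),
    acf = file.path(output_dir, "acf_sample.csv"),
    pp = file.path(output_dir, "pp.csv"),
    return_levels = file.path(output_dir, "return_levels.csv"))
  smp_df <- as.data.frame(smp)
  smp_df$timestamp <- format(smp_df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(smp_df, paths$sample, row.names = FALSE, na = "")
  write_fit_report(fit, paths$fit, seed = seed)
  utils::write.csv(as.data.frame(unclass(mrl)), paths$mrl, row.names = FALSE)
  utils::write.csv(data.frame(lag = acf_sample$lags, acf = acf_sample$acf,
                              conf_band = acf_sample$conf_band),
                   paths$acf, row.names = FALSE)
  utils::write.csv(pp, paths$pp, row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(curve))[
    c("period", "level", "ci_low", "ci_high")],
    paths$return_levels, row.names = FALSE)
  message("report written to ", output_dir)
  invisible(list(sample = smp, fit = fit, mrl = mrl, acf = acf_sample,
                 pp = pp, curve = curve, paths = paths))
}
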