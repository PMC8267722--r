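#' extremeair: extreme-value modeling of unhealthy air pollution events
#'
#' Computes the Malaysian Air Pollution Index (API) from pollutant
#' concentrations, selects extreme observations by block maxima (BM),
#' peaks-over-threshold (POT) or the mixed POT-BM scheme with declustering,
#' fits GEV/GPD models by L-moments or maximum likelihood, and estimates
#' return levels with delta-method confidence intervals.
#'
#' @keywords internal
#' @aliases extremeair-package
"_PACKAGE"

# Piecewise sub-index segments, one matrix row per segment:
# lower breakpoint, offset, slope. Value = offset + (conc - lower) * slope.
# Segments are closed on the left; slope constants are the Malaysian
# Department of Environment published (rounded) coefficients.
.sub_index_segments <- list(
  co = rbind(
    c(0,    0,   11.11111),
    c(9,    100, 16.66667),
    c(15,   200, 6.66667),
    c(30,   300, 10)
  ),
  o3 = rbind(
    c(0,    0,   1000),
    c(0.2,  200, 500),
    c(0.4,  300, 1000)
  ),
  no2 = rbind(
    c(0,    0,   588.23529),
    c(0.17, 100, 232.56),
    c(0.6,  200, 166.667),
    c(1.2,  300, 250)
  ),
  so2 = rbind(
    c(0,    0,   2500),
    c(0.04, 100, 384.61),
    c(0.3,  200, 333.333),
    c(0.6,  300, 500)
  ),
  pm10 = rbind(
    c(0,    0,   1),
    c(50,   50,  0.5),
    c(350,  200, 1.4286),
    c(420,  300, 1.25),
    c(500,  400, 1)
  )
)

#' Malaysian sub-API index for a single pollutant
#'
#' Transforms a pollutant concentration onto the common API scale using the
#' piecewise-linear breakpoint formulas published by the Department of
#' Environment Malaysia. Gaseous pollutants (CO, O3, NO2, SO2) are in ppm;
#' PM10 is in micrograms per cubic metre. Each linear segment is closed on
#' the left, so the value at a breakpoint comes from the upper segment.
#'
#' @param pollutant One of `"co"`, `"o3"`, `"no2"`, `"so2"`, `"pm10"`
#'   (case-insensitive).
#' @param concentration Numeric vector of non-negative concentrations;
#'   `NA` passes through as `NA`.
#' @return Numeric vector of sub-index values (dimensionless, >= 0).
#' @examples
#' sub_index("co", 9)      # 100
#' sub_index("pm10", 125)  # 87.5
#' @export
sub_index <- function(pollutant, concentration) {
  pollutant <- tolower(as.character(pollutant))
  if (length(pollutant) != 1L || !pollutant %in% names(.sub_index_segments))
    stop("unknown pollutant: must be one of co, o3, no2, so2, pm10")
  if (!is.numeric(concentration))
    stop("concentration must be numeric")
  if (any(concentration < 0, na.rm = TRUE))
    stop("negative concentration is not allowed")
  seg <- .sub_index_segments[[pollutant]]
  # closed-left membership: last segment whose lower breakpoint is <= conc
  i <- findInterval(concentration, seg[, 1L])
  out <- seg[i, 2L] + (concentration - seg[i, 1L]) * seg[i, 3L]
  out[is.na(concentration)] <- NA_real_
  unname(out)
}

#' Air-quality status for an API value
#'
#' Maps API values onto the Malaysian air-quality status bands: up to 50 Good,
#' (50, 100] Moderate, (100, 200] Unhealthy, (200, 300] Very Unhealthy and
#' above 300 Hazardous. API values are real-valued, so the integer band edges
#' published in the official table are read as upper limits.
#'
#' @param api Numeric vector of non-negative API values; `NA` passes through.
#' @return Factor with levels `Good`, `Moderate`, `Unhealthy`,
#'   `VeryUnhealthy`, `Hazardous`.
#' @export
classify_status <- function(api) {
  if (!is.numeric(api)) stop("api must be numeric")
  if (any(api < 0, na.rm = TRUE)) stop("negative API value")
  cut(api, breaks = c(-Inf, 50, 100, 200, 300, Inf),
      labels = c("Good", "Moderate", "Unhealthy", "VeryUnhealthy", "Hazardous"),
      right = TRUE)
}

#' Combine sub-indices into the API
#'
#' The API at a given hour is the maximum over the available pollutant
#' sub-indices. Missing sub-indices are skipped, not imputed; a row with all
#' sub-indices missing yields a missing API, flagged in the result.
#'
#' @param sub_indices Numeric vector (one observation) or data frame / matrix
#'   with one column per pollutant sub-index and one row per observation.
#' @return Data frame with columns `api` (numeric), `status` (factor) and
#'   `all_missing` (logical flag).
#' @export
compute_api <- function(sub_indices) {
  if (is.null(dim(sub_indices))) sub_indices <- matrix(as.numeric(sub_indices), nrow = 1L)
  m <- as.matrix(sub_indices)
  if (!is.numeric(m)) stop("sub-indices must be numeric")
  all_na <- apply(m, 1L, function(r) all(is.na(r)))
  api <- rep(NA_real_, nrow(m))
  api[!all_na] <- apply(m[!all_na, , drop = FALSE], 1L, max, na.rm = TRUE)
  data.frame(api = api, status = classify_status(api), all_missing = all_na)
}

#' API table from raw pollutant readings
#'
#' Applies the five sub-index transforms to a table of hourly pollutant
#' readings and appends the combined API and air-quality status.
#'
#' @param readings Data frame with columns `co`, `o3`, `no2`, `so2`, `pm10`
#'   (any may contain `NA`) and optionally `timestamp`.
#' @return The input with appended columns `idx_co`, `idx_o3`, `idx_no2`,
#'   `idx_so2`, `idx_pm10`, `api`, `status`.
#' @export
api_from_readings <- function(readings) {
  pols <- c("co", "o3", "no2", "so2", "pm10")
  if (!all(pols %in% names(readings)))
    stop("readings must have columns co, o3, no2, so2, pm10")
  idx <- lapply(pols, function(p) sub_index(p, readings[[p]]))
  names(idx) <- paste0("idx_", pols)
  res <- compute_api(as.data.frame(idx))
  if (any(res$all_missing))
    warning(sum(res$all_missing), " record(s) with all pollutants missing")
  cbind(readings, as.data.frame(idx), res[c("api", "status")])
}
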