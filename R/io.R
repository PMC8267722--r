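# CSV I/O: comma-separated, UTF-8, mandatory header, ISO-8601 timestamps,
# missing values as empty fields.

.parse_timestamps <- function(x, path) {
  x <- as.character(x)
  ts <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    na <- is.na(ts)
    if (!any(na)) break
    ts[na] <- as.POSIXct(x[na], tz = "UTC", format = fmt)
  }
  if (any(is.na(ts))) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("unparseable timestamp in %s at data line %d: '%s'",
                 path, bad, x[bad]))
  }
  ts
}

#' Read an hourly index series from CSV
#'
#' Expects a header with columns `timestamp` (ISO-8601) and `value` (or
#' `api`); empty fields are missing values.
#'
#' @param path CSV file path.
#' @return An [index_series].
#' @export
read_index_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcol <- intersect(c("value", "api"), names(d))[1]
  if (!"timestamp" %in% names(d) || is.na(vcol))
    stop("CSV must have columns 'timestamp' and 'value' (or 'api'): ", path)
  index_series(.parse_timestamps(d$timestamp, path), as.numeric(d[[vcol]]))
}

#' Write an hourly index series to CSV
#' @param series An [index_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_series <- function(series, path) {
  series <- .as_index_series(series)
  d <- data.frame(timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"),
                  value = series$value)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read hourly pollutant readings from CSV
#'
#' Expects columns `timestamp`, `co`, `o3`, `no2`, `so2`, `pm10` (gases in
#' ppm, PM10 in ug/m3); empty fields are missing.
#'
#' @param path CSV file path.
#' @return Data frame with a POSIXct `timestamp` column.
#' @export
read_pollutant_readings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "co", "o3", "no2", "so2", "pm10")
  if (!all(need %in% names(d)))
    stop("CSV must have columns ", paste(need, collapse = ", "), ": ", path)
  d$timestamp <- .parse_timestamps(d$timestamp, path)
  for (p in need[-1]) d[[p]] <- as.numeric(d[[p]])
  d
}

# structured text report of a fit (JSON)
.fit_report <- function(fit, seed = NULL) {
  fam <- if (inherits(fit, "gev_fit")) "GEV" else "GPD"
  conv <- if (fam == "GEV") "hosking" else "coles"
  params <- if (fam == "GEV") {
    list(location = fit$location, scale = fit$scale, shape = fit$shape)
  } else {
    list(threshold = fit$threshold, scale = fit$scale, shape = fit$shape,
         zeta_u = fit$zeta_u)
  }
  list(family = fam, convention = conv, params = params,
       se = as.list(fit$se),
       cov = if (!is.null(fit$cov)) unclass(fit$cov) else NULL,
       n = fit$n, k = if (!is.null(fit$k)) fit$k else fit$n,
       method = fit$method, loglik = fit$loglik, seed = seed)
}

#' Serialize a fit as a JSON report
#' @param fit A `"gev_fit"` or `"gpd_fit"`.
#' @param path Output path.
#' @param seed Seed to record in the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  jsonlite::write_json(.fit_report(fit, seed), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
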