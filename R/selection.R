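# Extreme-data selection: annual block maxima (BM), raw peaks-over-threshold
# (POT), and the mixed POT-BM scheme in which maximal runs of threshold
# exceedances are declustered with a minimum separation r (in hours) and the
# per-cluster maximum is retained as the extreme sample.

#' Hourly index series
#'
#' Container for a timestamped hourly index series: a data frame with columns
#' `timestamp` (POSIXct, strictly increasing, on an hourly lattice — gaps are
#' allowed) and `value` (non-negative or `NA`).
#'
#' @param timestamps POSIXct vector (or coercible character), strictly
#'   increasing, spaced in whole hours.
#' @param values Numeric vector of the same length; `NA` marks missing hours.
#' @return Data frame of class `c("index_series", "data.frame")`.
#' @export
index_series <- function(timestamps, values) {
  if (!inherits(timestamps, "POSIXct"))
    timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (length(timestamps) != length(values))
    stop("timestamps and values must have the same length")
  if (length(timestamps) == 0L) stop("empty series")
  d <- diff(as.numeric(timestamps))
  if (any(d <= 0)) stop("timestamps must be strictly increasing")
  if (any(d %% 3600 != 0))
    stop("timestamps must lie on an hourly lattice (gaps in whole hours)")
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) stop("index values must be non-negative")
  structure(data.frame(timestamp = timestamps, value = values),
            class = c("index_series", "data.frame"))
}

.as_index_series <- function(series) {
  if (!inherits(series, "index_series")) {
    if (is.data.frame(series) && all(c("timestamp", "value") %in% names(series)))
      series <- index_series(series$timestamp, series$value)
    else stop("series must be an index_series or data frame with timestamp, value")
  }
  series
}

.new_extreme_sample <- function(method, values, timestamps, threshold = NULL,
                                min_sep = NULL, n_source, cluster_id = NULL) {
  structure(list(method = method, values = values, timestamps = timestamps,
                 threshold = threshold, min_sep = min_sep,
                 n_source = n_source, k = length(values),
                 cluster_id = cluster_id),
            class = "extreme_sample")
}

#' @export
print.extreme_sample <- function(x, ...) {
  cat("Extreme sample (", x$method, "): k = ", x$k,
      " of n = ", x$n_source, " observations", sep = "")
  if (!is.null(x$threshold)) cat(", threshold =", x$threshold)
  if (!is.null(x$min_sep)) cat(", min separation =", x$min_sep, "h")
  cat("\n")
  invisible(x)
}

#' Raw peaks-over-threshold selection
#'
#' Returns every observation strictly exceeding the threshold `u`, in time
#' order. Missing values are treated as below threshold.
#'
#' @param series An [index_series] (or data frame with `timestamp`, `value`).
#' @param u Threshold (>= 0); `u = 100` marks unhealthy air pollution events
#'   on the Malaysian API scale.
#' @return An `"extreme_sample"` with `method = "POT"`. No exceedances gives
#'   an empty (k = 0) sample.
#' @export
pot_exceedances <- function(series, u) {
  series <- .as_index_series(series)
  if (u < 0) stop("threshold must be non-negative")
  keep <- !is.na(series$value) & series$value > u
  .new_extreme_sample("POT", series$value[keep], series$timestamp[keep],
                      threshold = u, n_source = nrow(series))
}

#' Form exceedance clusters (POT blocks)
#'
#' Groups threshold exceedances into maximal runs of consecutive
#' above-threshold observations: a run breaks at any observation at or below
#' `u`, including missing hours. Consecutive means adjacent rows of the
#' series, so a recording gap also breaks a run.
#'
#' @inheritParams pot_exceedances
#' @return List of class `"cluster_list"`; each element has `start`, `end`
#'   (timestamps of first/last member), `members` (data frame
#'   `timestamp`, `value`), `peak_value` and `peak_time` (earliest timestamp
#'   on ties). Attributes `threshold` and `n_source` are set.
#' @export
form_clusters <- function(series, u) {
  series <- .as_index_series(series)
  if (u < 0) stop("threshold must be non-negative")
  exceed <- !is.na(series$value) & series$value > u
  # also break runs across timestamp gaps: an absent hour is a missing hour
  gap_before <- c(FALSE, diff(as.numeric(series$timestamp)) > 3600)
  run_id <- cumsum(exceed & (!c(FALSE, exceed[-length(exceed)]) | gap_before))
  idx <- which(exceed)
  clusters <- lapply(split(idx, run_id[idx]), function(ii) {
    mem <- data.frame(timestamp = series$timestamp[ii], value = series$value[ii])
    pk <- which.max(mem$value)  # earliest index on ties
    list(start = mem$timestamp[1L], end = mem$timestamp[nrow(mem)],
         members = mem, peak_value = mem$value[pk], peak_time = mem$timestamp[pk])
  })
  names(clusters) <- NULL
  structure(clusters, class = "cluster_list",
            threshold = u, n_source = nrow(series))
}

#' Decluster exceedance clusters by a minimum separation
#'
#' Enforces a minimum separation of `r` hours between retained clusters.
#' Separation is measured in wall-clock hours from the last exceedance of one
#' cluster to the first exceedance of the next, so data gaps count toward it.
#' Clusters closer than `r` are merged left-to-right transitively (all
#' members kept); a gap of exactly `r` hours keeps clusters separate.
#' `action = "drop"` instead discards the later cluster of each close pair.
#'
#' @param clusters A `"cluster_list"` from [form_clusters()], time-ordered.
#' @param r Minimum separation in hours (> 0); 240 h is the conventional
#'   separation for extreme air pollution events.
#' @param action `"merge"` (default) or `"drop"`.
#' @return A `"cluster_list"` satisfying the separation rule. Idempotent:
#'   declustering a declustered list changes nothing.
#' @export
decluster <- function(clusters, r, action = c("merge", "drop")) {
  action <- match.arg(action)
  if (r <= 0) stop("minimum separation r must be positive")
  if (length(clusters) <= 1L) return(clusters)
  out <- list(clusters[[1L]])
  for (cl in clusters[-1L]) {
    last <- out[[length(out)]]
    gap <- as.numeric(difftime(cl$start, last$end, units = "hours"))
    if (gap < 0) stop("clusters must be time-ordered and non-overlapping")
    if (gap < r) {
      if (action == "merge") {
        mem <- rbind(last$members, cl$members)
        pk <- which.max(mem$value)
        out[[length(out)]] <- list(start = last$start, end = cl$end,
                                   members = mem,
                                   peak_value = mem$value[pk],
                                   peak_time = mem$timestamp[pk])
      }
      # action == "drop": discard the later cluster
    } else {
      out[[length(out) + 1L]] <- cl
    }
  }
  structure(out, class = "cluster_list",
            threshold = attr(clusters, "threshold"),
            n_source = attr(clusters, "n_source"))
}

#' Per-cluster maxima: the mixed POT-BM extreme sample
#'
#' Applies the block-maxima idea to declustered POT blocks: one observation —
#' the cluster peak — is retained per cluster, giving extreme data points
#' that are approximately independent and GEV-distributed.
#'
#' @param clusters A (declustered) `"cluster_list"`.
#' @param min_sep Separation used in declustering (recorded in the sample).
#' @return An `"extreme_sample"` with `method = "POT_BM"`, one value and
#'   timestamp per cluster, plus a `cluster_id` vector.
#' @export
cluster_maxima <- function(clusters, min_sep = NULL) {
  vals <- vapply(clusters, function(cl) cl$peak_value, numeric(1))
  ts <- do.call(c, lapply(clusters, function(cl) cl$peak_time))
  if (length(clusters) == 0L) ts <- as.POSIXct(character(0), tz = "UTC")
  .new_extreme_sample("POT_BM", vals, ts,
                      threshold = attr(clusters, "threshold"),
                      min_sep = min_sep,
                      n_source = attr(clusters, "n_source") %||% NA_integer_,
                      cluster_id = seq_along(clusters))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annual block maxima
#'
#' One maximum per calendar year. A year is used only if at least
#' `min_coverage` of its hours are non-missing (hours absent from the series
#' count as missing); otherwise it is skipped with a warning. Ties take the
#' earliest timestamp.
#'
#' @inheritParams pot_exceedances
#' @param min_coverage Minimum fraction of the year's hours that must be
#'   observed (default 0.5).
#' @return An `"extreme_sample"` with `method = "BM"`, one value per retained
#'   year.
#' @export
annual_block_maxima <- function(series, min_coverage = 0.5) {
  series <- .as_index_series(series)
  yr <- as.integer(format(series$timestamp, "%Y", tz = "UTC"))
  vals <- numeric(0)
  ts <- as.POSIXct(character(0), tz = "UTC")
  for (y in sort(unique(yr))) {
    sub <- series[yr == y, , drop = FALSE]
    hours_in_year <- ifelse(y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0),
                            8784, 8760)
    n_obs <- sum(!is.na(sub$value))
    if (n_obs / hours_in_year < min_coverage) {
      warning(sprintf("year %d skipped: only %.1f%% of hours observed",
                      y, 100 * n_obs / hours_in_year))
      next
    }
    pk <- which.max(sub$value)  # NA-safe: which.max ignores NA
    vals <- c(vals, sub$value[pk])
    ts <- c(ts, sub$timestamp[pk])
  }
  .new_extreme_sample("BM", vals, ts, n_source = nrow(series))
}

#' Select an extreme sample by method
#'
#' Convenience wrapper dispatching to [annual_block_maxima()],
#' [pot_exceedances()], or the POT-BM chain
#' [form_clusters()] + [decluster()] + [cluster_maxima()].
#'
#' @inheritParams pot_exceedances
#' @param method `"bm"`, `"pot"` or `"potbm"`.
#' @param u Threshold for POT / POT-BM (default 100, the unhealthy-API level).
#' @param r Minimum cluster separation in hours for POT-BM (default 240).
#' @param decluster_action Passed to [decluster()].
#' @return An `"extreme_sample"`.
#' @export
select_extremes <- function(series, method = c("potbm", "pot", "bm"),
                            u = 100, r = 240,
                            decluster_action = c("merge", "drop")) {
  method <- match.arg(method)
  switch(method,
         bm = annual_block_maxima(series),
         pot = pot_exceedances(series, u),
         potbm = {
           cl <- decluster(form_clusters(series, u), r,
                           action = match.arg(decluster_action))
           cluster_maxima(cl, min_sep = r)
         })
}

#' Convert an extreme sample to a data frame
#' @param x An `"extreme_sample"`.
#' @param ... Unused.
#' @return Data frame with `timestamp`, `value` and, for POT-BM, `cluster_id`.
#' @export
as.data.frame.extreme_sample <- function(x, ...) {
  d <- data.frame(timestamp = x$timestamps, value = x$values)
  if (!is.null(x$cluster_id)) d$cluster_id <- x$cluster_id
  d
}
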