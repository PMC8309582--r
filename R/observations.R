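# Data model: mobile observations, the fixed reference station, grids.
#
# Conventions used throughout the package:
#   * coordinates are planar metres east (x) / north (y) of a local origin;
#   * time t is seconds since the campaign epoch (t = 0), as a double;
#   * values are ug/m3 once calibrated, raw sensor units (ppb) before.

#' Build an observation set
#'
#' An `observation_set` holds one mobile campaign: one row per sensed
#' value, plus the campaign epoch (the absolute time of `t = 0`) and,
#' optionally, the WGS84 origin of the local planar frame.
#'
#' @param obs A data.frame with columns `sensor_id`, `x`, `y`, `t`,
#'   `value` and optionally `calibrated` (logical, default `FALSE`) and
#'   `route_id` (defaults to `sensor_id`).
#' @param epoch POSIXct of `t = 0` (default 2016-02-28 00:00 UTC).
#' @param origin Optional `c(lat, lon)` of the local planar origin.
#' @return An object of class `observation_set`, sorted by `t`.
#' @export
observation_set <- function(obs,
                            epoch = as.POSIXct("2016-02-28 00:00:00", tz = "UTC"),
                            origin = NULL) {
  required <- c("sensor_id", "x", "y", "t", "value")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop_stkrige("stkrige_schema_error",
                 paste0("missing observation columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  obs$sensor_id <- as.character(obs$sensor_id)
  if (is.null(obs$calibrated)) obs$calibrated <- FALSE
  if (is.null(obs$route_id)) obs$route_id <- obs$sensor_id
  for (col in c("x", "y", "t", "value")) assert_finite(obs[[col]], col)
  if (any(obs$t < 0)) {
    stop_stkrige("stkrige_invalid_input", "observation times must be >= 0")
  }
  if (any(!obs$calibrated & obs$value < 0)) {
    warn_stkrige("stkrige_negative_raw",
                 sprintf("%d raw (uncalibrated) values are negative",
                         sum(!obs$calibrated & obs$value < 0)))
  }
  key <- paste(obs$sensor_id, format(obs$t, digits = 17))
  if (anyDuplicated(key)) {
    stop_stkrige("stkrige_invalid_input",
                 "duplicate (sensor_id, t) pairs in observation set")
  }
  obs <- obs[order(obs$t, obs$sensor_id), , drop = FALSE]
  rownames(obs) <- NULL
  structure(list(obs = obs, epoch = epoch, origin = origin),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("<observation_set: %d observations, %d sensors, %.1f h span%s>\n",
              nrow(x$obs), length(unique(x$obs$sensor_id)),
              diff(range(x$obs$t)) / 3600,
              if (all(x$obs$calibrated)) ", calibrated" else ""))
  invisible(x)
}

#' @export
as.data.frame.observation_set <- function(x, ...) x$obs

#' Number of observations in an observation set
#' @param x An `observation_set`.
#' @return Integer count.
#' @export
n_obs <- function(x) nrow(x$obs)

#' Subset an observation set by row index
#' @param x An `observation_set`.
#' @param idx Integer or logical row index into the (time-sorted) rows.
#' @return A new `observation_set`.
#' @export
subset_obs <- function(x, idx) {
  out <- x
  out$obs <- x$obs[idx, , drop = FALSE]
  rownames(out$obs) <- NULL
  out
}

#' Build a fixed-station hourly series
#'
#' The reference series F(t): node times in seconds since the campaign
#' epoch (hourly spacing expected), node values in ug/m3. Values between
#' nodes come from linear interpolation; the series is never
#' extrapolated.
#'
#' @param times Strictly increasing numeric node times (seconds).
#' @param values Numeric node values (ug/m3).
#' @param x,y Station position in local metres (default origin).
#' @return An object of class `station_series`.
#' @export
station_series <- function(times, values, x = 0, y = 0) {
  if (length(times) < 2L) {
    stop_stkrige("stkrige_invalid_input", "a station series needs >= 2 nodes")
  }
  if (length(times) != length(values)) {
    stop_stkrige("stkrige_invalid_input", "times and values differ in length")
  }
  assert_finite(times, "times"); assert_finite(values, "values")
  if (any(diff(times) <= 0)) {
    stop_stkrige("stkrige_invalid_input", "node times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 x = x, y = y),
            class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("<station_series: %d nodes, %.1f h span, mean %.1f ug/m3>\n",
              length(x$times), diff(range(x$times)) / 3600, mean(x$values)))
  invisible(x)
}

#' Interpolate the fixed-station series at arbitrary times
#'
#' Piecewise-linear interpolation through the hourly nodes, exact at the
#' nodes. Times outside the node span raise an extrapolation error: the
#' series is a measured reference, not a model, so it is never extended.
#'
#' @param series A `station_series`.
#' @param t Numeric vector of times (seconds since epoch).
#' @return Numeric vector of interpolated values (ug/m3).
#' @export
station_value <- function(series, t) {
  assert_finite(t, "t")
  if (any(t < series$times[1] | t > series$times[length(series$times)])) {
    stop_stkrige("stkrige_extrapolation",
                 "requested time outside the station series span")
  }
  stats::approx(series$times, series$values, xout = t, method = "linear",
                ties = "ordered")$y
}

#' Which times fall inside the station span
#' @param series A `station_series`.
#' @param t Numeric vector of times.
#' @return Logical vector.
#' @export
in_station_span <- function(series, t) {
  t >= series$times[1] & t <= series$times[length(series$times)]
}

#' Prediction grid specification
#'
#' @param x_min,y_min Lower-left corner of the grid frame (metres);
#'   cell centres sit half a cell inward.
#' @param n_x,n_y Cell counts (>= 1).
#' @param cell_size Cell edge length in metres (> 0).
#' @param times Increasing vector of prediction times (seconds).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x_min, y_min, n_x, n_y, cell_size, times) {
  if (n_x < 1 || n_y < 1) stop_stkrige("stkrige_invalid_input", "n_x, n_y must be >= 1")
  if (cell_size <= 0) stop_stkrige("stkrige_invalid_input", "cell_size must be > 0")
  if (!length(times) || any(diff(times) <= 0)) {
    stop_stkrige("stkrige_invalid_input", "times must be nonempty and increasing")
  }
  structure(list(x_min = x_min, y_min = y_min, n_x = as.integer(n_x),
                 n_y = as.integer(n_y), cell_size = cell_size,
                 times = as.numeric(times)),
            class = "grid_spec")
}

# Cell centres of a grid, lower-left cell first, row-major by y.
grid_centers <- function(grid) {
  xs <- grid$x_min + (seq_len(grid$n_x) - 0.5) * grid$cell_size
  ys <- grid$y_min + (seq_len(grid$n_y) - 0.5) * grid$cell_size
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

.parse_iso8601 <- function(ts) {
  ts <- sub("T", " ", ts, fixed = TRUE)
  ts <- sub("Z$", "", ts)
  # strptime parses per element, so one malformed row cannot sink the rest
  out <- as.POSIXct(strptime(ts, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(ts[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

.format_iso8601 <- function(time) {
  format(time, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
}

#' Read mobile observations from CSV
#'
#' Expected columns: `sensor_id`, `timestamp` (ISO-8601 UTC), either
#' `lat`/`lon` or `x`/`y`, `value`, and optionally `unit` (`ppb` or
#' `ugm3`) and `route_id`. Malformed rows (unparsable timestamp,
#' non-finite value) are dropped with a logged count. With
#' `convert = TRUE`, rows whose unit is ppb are converted to ug/m3.
#'
#' @param path CSV file path.
#' @param epoch POSIXct of `t = 0`; default: midnight (UTC) of the
#'   earliest timestamp in the file.
#' @param origin `c(lat, lon)` local origin, required when the file has
#'   lat/lon columns; default: mean position in the file.
#' @param convert Convert ppb rows to ug/m3 (default `FALSE`).
#' @param molecular_weight Molecular weight used for conversion (48, ozone).
#' @param schema `"default"` or `"opensense"` (maps the archive-style
#'   column names `sensor`, `time`, `latitude`, `longitude`, `ozone`).
#' @return An `observation_set`.
#' @export
read_observations <- function(path, epoch = NULL, origin = NULL,
                              convert = FALSE, molecular_weight = 48,
                              schema = c("default", "opensense")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_stkrige("stkrige_io_error", paste0("no such file: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop_stkrige("stkrige_empty_input", "observation file has no rows")
  if (schema == "opensense") {
    map <- c(sensor = "sensor_id", time = "timestamp",
             latitude = "lat", longitude = "lon", ozone = "value")
    hit <- names(raw) %in% names(map)
    names(raw)[hit] <- map[names(raw)[hit]]
    if (is.null(raw$unit)) raw$unit <- "ppb"
  }
  needed <- c("sensor_id", "timestamp", "value")
  missing_cols <- setdiff(needed, names(raw))
  has_xy <- all(c("x", "y") %in% names(raw))
  has_ll <- all(c("lat", "lon") %in% names(raw))
  if (!has_xy && !has_ll) missing_cols <- c(missing_cols, "lat/lon or x/y")
  if (length(missing_cols)) {
    stop_stkrige("stkrige_schema_error",
                 paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  time <- .parse_iso8601(as.character(raw$timestamp))
  value <- suppressWarnings(as.numeric(raw$value))
  ok <- !is.na(time) & is.finite(value)
  if (has_xy) {
    ok <- ok & is.finite(suppressWarnings(as.numeric(raw$x))) &
      is.finite(suppressWarnings(as.numeric(raw$y)))
  } else {
    ok <- ok & is.finite(suppressWarnings(as.numeric(raw$lat))) &
      is.finite(suppressWarnings(as.numeric(raw$lon)))
  }
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    log_event("core_io", "dropped_malformed_rows", n = n_bad, file = basename(path))
  }
  raw <- raw[ok, , drop = FALSE]; time <- time[ok]; value <- value[ok]
  if (nrow(raw) == 0L) stop_stkrige("stkrige_empty_input", "no well-formed rows")
  if (is.null(epoch)) epoch <- trunc(min(time), units = "days")
  if (has_xy) {
    x <- as.numeric(raw$x); y <- as.numeric(raw$y)
  } else {
    if (is.null(origin)) {
      origin <- c(mean(as.numeric(raw$lat)), mean(as.numeric(raw$lon)))
    }
    xy <- project_to_local(as.numeric(raw$lat), as.numeric(raw$lon), origin)
    x <- xy$x; y <- xy$y
  }
  unit <- if (!is.null(raw$unit)) as.character(raw$unit) else rep("ugm3", nrow(raw))
  calibrated <- unit != "ppb"
  if (convert) {
    is_ppb <- unit == "ppb"
    value[is_ppb] <- ppb_to_ugm3(value[is_ppb], molecular_weight)
    calibrated[is_ppb] <- FALSE   # converted but still uncalibrated sensor data
  }
  obs <- data.frame(sensor_id = as.character(raw$sensor_id), x = x, y = y,
                    t = as.numeric(difftime(time, epoch, units = "secs")),
                    value = value, calibrated = calibrated,
                    stringsAsFactors = FALSE)
  if (!is.null(raw$route_id)) obs$route_id <- as.character(raw$route_id)
  observation_set(obs, epoch = epoch, origin = origin)
}

#' Write mobile observations to CSV
#'
#' Columns: `sensor_id`, `timestamp` (ISO-8601 UTC with microseconds),
#' `x`, `y`, `value`, `unit`, `route_id`. Numeric columns are printed
#' with 15 significant digits so a read/write round trip preserves them
#' to float-formatting precision.
#'
#' @param x An `observation_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path) {
  d <- x$obs
  out <- data.frame(
    sensor_id = d$sensor_id,
    timestamp = .format_iso8601(x$epoch + d$t),
    x = formatC(d$x, digits = 15, format = "g"),
    y = formatC(d$y, digits = 15, format = "g"),
    value = formatC(d$value, digits = 15, format = "g"),
    unit = ifelse(d$calibrated, "ugm3", "ppb"),
    route_id = d$route_id,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fixed-station series from CSV
#'
#' Expected columns: `timestamp` (ISO-8601 UTC) and `value` (ug/m3).
#'
#' @inheritParams read_observations
#' @param x,y Station position in local metres.
#' @return A `station_series`.
#' @export
read_station <- function(path, epoch = NULL, x = 0, y = 0) {
  if (!file.exists(path)) stop_stkrige("stkrige_io_error", paste0("no such file: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "value") %in% names(raw))) {
    stop_stkrige("stkrige_schema_error", "station CSV needs timestamp and value columns")
  }
  time <- .parse_iso8601(as.character(raw$timestamp))
  if (anyNA(time)) stop_stkrige("stkrige_schema_error", "unparsable station timestamps")
  if (is.null(epoch)) epoch <- trunc(min(time), units = "days")
  station_series(as.numeric(difftime(time, epoch, units = "secs")),
                 as.numeric(raw$value), x = x, y = y)
}

#' Write a fixed-station series to CSV
#'
#' @param series A `station_series`.
#' @param path Output CSV path.
#' @param epoch POSIXct of `t = 0`.
#' @return `path`, invisibly.
#' @export
write_station <- function(series, path,
                          epoch = as.POSIXct("2016-02-28 00:00:00", tz = "UTC")) {
  out <- data.frame(
    timestamp = .format_iso8601(epoch + series$times),
    value = formatC(series$values, digits = 15, format = "g")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
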