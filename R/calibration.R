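# Per-sensor linear calibration against the fixed reference station.
#
# For each sensor i, ordinary least squares of the interpolated station
# value on the sensor's raw signal,
#     F(t) = a_i + b_i * X_i(x, t) + eps,
# estimated once per sensor over all of its data; the same (a_i, b_i)
# then calibrate the sensor via Z_i = a_i + b_i * X_i. The additive bias
# pulls every sensor's mean toward the station mean -- a known property
# of this scheme, kept as-is.

#' Fit per-sensor linear calibrations
#'
#' @param raw An uncalibrated `observation_set`.
#' @param station A `station_series` giving the reference F(t).
#' @return An object of class `sensor_calibration`: a data.frame with
#'   one row per sensor (`sensor_id`, `a`, `b`, `n_points`,
#'   `residual_sd`, `n_outside`), where `n_outside` counts observations
#'   excluded because their times fall outside the station span.
#' @examples
#' st <- station_series(c(0, 3600, 7200), c(10, 30, 20))
#' obs <- observation_set(data.frame(
#'   sensor_id = "s1", x = 0, y = 0, t = seq(0, 7200, by = 600),
#'   value = (station_value(st, seq(0, 7200, by = 600)) - 3) / 2))
#' coef(calibrate_sensors(obs, st))   # recovers a = 3, b = 2
#' @export
calibrate_sensors <- function(raw, station) {
  d <- raw$obs
  sensors <- unique(d$sensor_id)
  rows <- lapply(sensors, function(s) {
    di <- d[d$sensor_id == s, , drop = FALSE]
    inside <- in_station_span(station, di$t)
    n_out <- sum(!inside)
    if (n_out > 0) {
      log_event("calibration", "outside_station_span", sensor = s, n = n_out)
    }
    di <- di[inside, , drop = FALSE]
    if (nrow(di) < 2L) {
      stop_stkrige("stkrige_insufficient_data",
                   sprintf("sensor %s: fewer than 2 usable observations", s))
    }
    xv <- di$value
    if (stats::var(xv) == 0) {
      stop_stkrige("stkrige_degenerate_regressor",
                   sprintf("sensor %s: raw values have zero variance", s))
    }
    Fv <- station_value(station, di$t)
    fit <- stats::lm.fit(cbind(1, xv), Fv)
    res <- fit$residuals
    data.frame(sensor_id = s, a = fit$coefficients[1], b = fit$coefficients[2],
               n_points = nrow(di),
               residual_sd = sqrt(sum(res^2) / max(nrow(di) - 2, 1)),
               n_outside = n_out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensor_calibration", "data.frame")
  out
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat("Per-sensor linear calibration (F = a + b * X):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.sensor_calibration <- function(object, ...) {
  m <- as.matrix(object[, c("a", "b")])
  rownames(m) <- object$sensor_id
  m
}

#' Apply fitted calibrations to raw observations
#'
#' Transforms each value via `a + b * value` with its sensor's
#' coefficients and marks the result calibrated. Order and count are
#' preserved. Calibrated values may be negative: a linear calibration
#' can undershoot, and clamping would bias the kriging mean.
#'
#' @param raw An uncalibrated `observation_set`.
#' @param calibration A `sensor_calibration` covering every sensor.
#' @return A calibrated `observation_set`.
#' @export
apply_calibration <- function(raw, calibration) {
  d <- raw$obs
  idx <- match(d$sensor_id, calibration$sensor_id)
  if (anyNA(idx)) {
    stop_stkrige("stkrige_missing_calibration",
                 paste0("no calibration for sensor(s): ",
                        paste(unique(d$sensor_id[is.na(idx)]), collapse = ", ")))
  }
  d$value <- calibration$a[idx] + calibration$b[idx] * d$value
  d$calibrated <- TRUE
  out <- raw
  out$obs <- d
  out
}

#' @export
predict.sensor_calibration <- function(object, newdata, ...) {
  apply_calibration(newdata, object)
}

#' Write calibration coefficients to CSV
#' @param calibration A `sensor_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  utils::write.csv(as.data.frame(calibration), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read calibration coefficients from CSV
#' @param path Input path.
#' @return A `sensor_calibration`.
#' @export
read_calibration <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sensor_id", "a", "b", "n_points", "residual_sd")
  if (!all(needed %in% names(out))) {
    stop_stkrige("stkrige_schema_error", "not a calibration file")
  }
  class(out) <- c("sensor_calibration", "data.frame")
  out
}
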