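# Synthetic mobile campaigns.
#
# The generator emulates the structure the analysis assumes: a handful
# of sensors riding fixed back-and-forth tram routes, a latent
# ozone-like field with a strong diurnal mean peaking mid-afternoon and
# a metric spatio-temporal covariance (temporal variability dominating
# spatial variability at city scale), per-sensor additive/multiplicative
# bias with measurement noise, and one fixed reference station measuring
# the same field realisation.

#' Define a tram-like route
#'
#' @param route_id Character id.
#' @param vertices Two-column matrix or data.frame of (x, y) polyline
#'   vertices in metres; at least two, with positive total length.
#' @param speed Vehicle speed in m/s (> 0), default 8 (tram-like).
#' @param sampling_interval Seconds between samples (> 0), default 40.
#' @param start_offset Seconds after the campaign start at which the
#'   vehicle's sampling clock starts (default 0). Staggered offsets
#'   across routes give the campaign pairs at sub-interval temporal
#'   lags, which is what pins down the anisotropy K of a variogram.
#' @return An object of class `route_spec`.
#' @export
route_spec <- function(route_id, vertices, speed = 8, sampling_interval = 40,
                       start_offset = 0) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L) {
    stop_stkrige("stkrige_invalid_route", "a route needs >= 2 vertices")
  }
  seg <- sqrt(diff(vertices[, 1])^2 + diff(vertices[, 2])^2)
  if (sum(seg) <= 0) {
    stop_stkrige("stkrige_invalid_route", "route polyline has zero length")
  }
  if (speed <= 0 || sampling_interval <= 0) {
    stop_stkrige("stkrige_invalid_route", "speed and sampling_interval must be > 0")
  }
  if (start_offset < 0) {
    stop_stkrige("stkrige_invalid_route", "start_offset must be >= 0")
  }
  structure(list(route_id = as.character(route_id), vertices = vertices,
                 speed = speed, sampling_interval = sampling_interval,
                 start_offset = start_offset,
                 length = sum(seg), cum_length = c(0, cumsum(seg))),
            class = "route_spec")
}

# Point on the polyline at arc-length a in [0, length].
.route_point <- function(route, a) {
  a <- pmin(pmax(a, 0), route$length)
  seg <- findInterval(a, route$cum_length, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(route$vertices) - 1L)
  frac <- (a - route$cum_length[seg]) /
    pmax(route$cum_length[seg + 1L] - route$cum_length[seg], .Machine$double.eps)
  cbind(route$vertices[seg, 1] + frac * (route$vertices[seg + 1L, 1] - route$vertices[seg, 1]),
        route$vertices[seg, 2] + frac * (route$vertices[seg + 1L, 2] - route$vertices[seg, 2]))
}

#' Sample back-and-forth trajectories along routes
#'
#' Each route is traversed end-to-end and back at constant speed
#' (period `2 * length / speed`) and sampled every `sampling_interval`
#' seconds, giving `floor(duration / interval) + 1` samples per route,
#' all lying exactly on the polyline.
#'
#' @param routes A `route_spec` or list of them.
#' @param duration Campaign duration in seconds (> 0).
#' @return A data.frame with columns `route_id`, `x`, `y`, `t`.
#' @export
generate_trajectories <- function(routes, duration) {
  if (inherits(routes, "route_spec")) routes <- list(routes)
  if (duration <= 0) stop_stkrige("stkrige_invalid_input", "duration must be > 0")
  out <- lapply(routes, function(r) {
    t <- seq(r$start_offset, duration, by = r$sampling_interval)
    a <- (r$speed * t) %% (2 * r$length)
    a <- ifelse(a > r$length, 2 * r$length - a, a)   # fold: back and forth
    xy <- .route_point(r, a)
    data.frame(route_id = r$route_id, x = xy[, 1], y = xy[, 2], t = t,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Latent-field specification
#'
#' The latent concentration decomposes into a deterministic diurnal mean
#' and a zero-mean Gaussian fluctuation:
#' `Z(x, t) = mu(t) + Y(x, t)`, with
#' `mu(t) = max(0, base + amplitude * cos(2*pi*(hour(t) - peak_hour)/24))`
#' and `Y` a Gaussian random field with the given metric spatio-temporal
#' variogram (bounded family required for simulation).
#'
#' @param base Base level in ug/m3.
#' @param amplitude Diurnal amplitude in ug/m3 (>= 0).
#' @param peak_hour Hour of day of the diurnal peak (default 14:00).
#' @param model A bounded `variogram_model` (default: exponential,
#'   sill 60, nugget 2, range 20 km, K 100 m/s -- city-scale ozone-like:
#'   temporal variability dominates spatial variability, the
#'   nugget-to-sill ratio is a few percent, and consecutive 40-s samples
#'   of one vehicle keep substantial correlation, as on real tram data).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(base = 45, amplitude = 25, peak_hour = 14,
                       model = variogram_model("exponential", sill = 60,
                                               nugget = 2, range = 20000,
                                               K = 100)) {
  if (amplitude < 0) stop_stkrige("stkrige_invalid_input", "amplitude must be >= 0")
  if (!inherits(model, "variogram_model")) {
    stop_stkrige("stkrige_invalid_input", "'model' must be a variogram_model")
  }
  structure(list(base = base, amplitude = amplitude, peak_hour = peak_hour,
                 model = model),
            class = "field_spec")
}

#' Diurnal mean of a field specification
#' @param field A `field_spec`.
#' @param t Times in seconds since midnight of day 0.
#' @return Mean concentrations in ug/m3 (clipped at 0).
#' @export
field_mean <- function(field, t) {
  hour <- (t / 3600) %% 24
  pmax(0, field$base + field$amplitude * cos(2 * pi * (hour - field$peak_hour) / 24))
}

#' Simulate the latent Gaussian field at space-time points
#'
#' Draws one realisation of `mu(t) + Y(x, t)` at the given points. Up to
#' `cap` points the smooth component is drawn exactly through a dense
#' Cholesky factorisation of the (nugget-free) covariance matrix, with a
#' small diagonal jitter escalated on failure. Beyond `cap` points, a
#' seeded random subset of size `cap` is drawn exactly and the remaining
#' points are drawn from their Gaussian conditional distribution given
#' the `knn` metrically-nearest support points (conditional mean plus
#' conditional-variance noise; off-support pairs are conditionally
#' independent given the support, so sub-support-scale correlation is
#' approximated -- see the methods vignette). The nugget is then added
#' everywhere as i.i.d. micro-scale noise.
#'
#' @param points Data.frame with columns `x`, `y`, `t`.
#' @param field A `field_spec`.
#' @param seed Integer seed; the draw is reproducible.
#' @param cap Dense-factorisation cap (default 8000 points; the default
#'   campaign is simulated exactly).
#' @param knn Support neighbours used beyond the cap (default 32).
#' @return Numeric vector of latent values (ug/m3) in row order.
#' @export
simulate_field <- function(points, field, seed = 1, cap = 8000, knn = 32) {
  n <- nrow(points)
  model <- field$model
  mu <- field_mean(field, points$t)
  set.seed(derive_seed(seed, 1L))
  smooth <- numeric(n)
  if (model$sill > 0 && n > 0) {
    if (n <= cap) {
      smooth <- .draw_smooth(points, model)
    } else {
      support <- sort(sample.int(n, cap))
      rest <- setdiff(seq_len(n), support)
      z_s <- .draw_smooth(points[support, , drop = FALSE], model)
      smooth[support] <- z_s
      smooth[rest] <- .conditional_draw(points, support, rest, z_s, model, knn)
      log_event("synthetic", "support_thinning", n = n, support = cap)
    }
  }
  set.seed(derive_seed(seed, 2L))
  nug <- if (model$nugget > 0) stats::rnorm(n, 0, sqrt(model$nugget)) else 0
  gc(FALSE)
  mu + smooth + nug
}

# Exact joint draw of the smooth component on <= cap points. Works on
# the half-distance vector and frees intermediates promptly: at the
# 8000-point cap the covariance matrix alone is ~0.5 GB.
.draw_smooth <- function(points, model) {
  n <- nrow(points)
  dv <- stats::dist(cbind(points$x, points$y, model$K * points$t))
  cv <- cov_smooth(model, as.numeric(dv))
  rm(dv)
  C <- matrix(0, n, n)
  C[lower.tri(C)] <- cv
  rm(cv)
  C <- C + t(C)
  diag(C) <- model$sill
  gc(FALSE)
  jitter <- 1e-10 * total_sill(model)
  for (attempt in 0:3) {
    L <- tryCatch(chol(C + diag(jitter * 10^attempt, n)), error = function(e) NULL)
    if (!is.null(L)) {
      if (attempt > 0) {
        log_event("synthetic", "jitter_escalation", attempts = attempt)
      }
      return(drop(crossprod(L, stats::rnorm(n))))
    }
  }
  stop_stkrige("stkrige_simulation_error",
               "covariance factorisation failed after jitter escalation")
}

# Conditional Gaussian draw of off-support points given the support
# draw: conditional mean plus independent conditional-variance noise.
.conditional_draw <- function(points, support, rest, z_s, model, knn) {
  sx <- points$x[support]; sy <- points$y[support]; st <- points$t[support]
  k <- min(knn, length(support))
  out <- numeric(length(rest))
  for (i in seq_along(rest)) {
    j <- rest[i]
    d <- metric_distance(points$x[j], points$y[j], points$t[j], sx, sy, st, model$K)
    nb <- order(d)[seq_len(k)]
    dn <- d[nb]
    nbx <- sx[nb]; nby <- sy[nb]; nbt <- st[nb]
    dd <- metric_distance(matrix(nbx, k, k), matrix(nby, k, k), matrix(nbt, k, k),
                          matrix(nbx, k, k, byrow = TRUE),
                          matrix(nby, k, k, byrow = TRUE),
                          matrix(nbt, k, k, byrow = TRUE), model$K)
    Cnn <- matrix(cov_smooth(model, as.vector(dd)), k, k) +
      diag(1e-8 * total_sill(model), k)
    c0 <- cov_smooth(model, dn)
    w <- solve(Cnn, c0)
    cond_var <- max(model$sill - sum(w * c0), 0)
    out[i] <- sum(w * z_s[nb]) + stats::rnorm(1, 0, sqrt(cond_var))
  }
  out
}

#' Per-sensor fault specification
#'
#' True additive bias `a` (ug/m3), multiplicative bias `b` (> 0) and raw-scale
#' measurement noise sd. The raw signal is the inverse of the linear
#' calibration: `X = (Z - a) / b + noise`.
#'
#' @param sensor_id Character vector of sensor ids.
#' @param a,b,noise_sd Numeric vectors (recycled) of fault parameters.
#' @return A data.frame of class `sensor_fault_spec`.
#' @export
sensor_fault_spec <- function(sensor_id, a = 0, b = 1, noise_sd = 0) {
  if (any(b <= 0)) stop_stkrige("stkrige_invalid_fault", "multiplicative bias b must be > 0")
  if (any(noise_sd < 0)) stop_stkrige("stkrige_invalid_fault", "noise_sd must be >= 0")
  out <- data.frame(sensor_id = as.character(sensor_id), a = a, b = b,
                    noise_sd = noise_sd, stringsAsFactors = FALSE)
  class(out) <- c("sensor_fault_spec", "data.frame")
  out
}

#' Corrupt latent values into raw sensor readings
#'
#' Applies the inverse of the per-sensor linear calibration:
#' `X = (Z - a) / b + eps`, `eps ~ N(0, noise_sd^2)` independently per
#' sample.
#'
#' @param latent Numeric vector of latent (true) concentrations.
#' @param sensor_id Character vector assigning each value to a sensor.
#' @param faults A `sensor_fault_spec` covering every sensor present.
#' @param seed Integer seed.
#' @return Numeric vector of raw readings, same order.
#' @export
corrupt_sensors <- function(latent, sensor_id, faults, seed = 1) {
  sensor_id <- as.character(sensor_id)
  idx <- match(sensor_id, faults$sensor_id)
  if (anyNA(idx)) {
    stop_stkrige("stkrige_invalid_fault",
                 paste0("no fault spec for sensor(s): ",
                        paste(unique(sensor_id[is.na(idx)]), collapse = ", ")))
  }
  set.seed(derive_seed(seed, 3L))
  (latent - faults$a[idx]) / faults$b[idx] +
    stats::rnorm(length(latent), 0, faults$noise_sd[idx])
}

#' Simulate a fixed-station series from a field specification
#'
#' Samples the latent field at the station location on a fine sub-hour
#' grid (default 6 per hour) and averages it into hourly nodes, node `k`
#' being the mean over the hour-wide window centred on `k * 3600` s
#' (clipped to the campaign span). Node count is
#' `floor(duration / 3600) + 1`.
#'
#' @param field A `field_spec`.
#' @param position `c(x, y)` station position in metres.
#' @param duration Campaign duration in seconds (>= 2 hours).
#' @param seed Integer seed.
#' @param per_hour Sub-hour samples per hour (default 6).
#' @param bbox Optional `c(x_min, x_max, y_min, y_max)`; a station
#'   outside it triggers a warning (not an error).
#' @return A `station_series`.
#' @export
station_series_from_field <- function(field, position = c(0, 0), duration,
                                      seed = 1, per_hour = 6, bbox = NULL) {
  if (duration < 7200) {
    stop_stkrige("stkrige_invalid_input", "duration must be >= 2 hours")
  }
  if (!is.null(bbox) &&
      (position[1] < bbox[1] || position[1] > bbox[2] ||
       position[2] < bbox[3] || position[2] > bbox[4])) {
    warn_stkrige("stkrige_station_outside_bbox",
                 "station position lies outside the configured bounding box")
  }
  dt <- 3600 / per_hour
  sub_t <- seq(dt / 2, duration - dt / 2, by = dt)
  vals <- simulate_field(data.frame(x = position[1], y = position[2], t = sub_t),
                         field, seed = seed)
  .hourly_nodes(sub_t, vals, duration, position)
}

# Average sub-hour samples into hourly nodes (window centred on each node).
.hourly_nodes <- function(sub_t, vals, duration, position) {
  node_t <- seq(0, floor(duration / 3600) * 3600, by = 3600)
  node_v <- vapply(node_t, function(tk) {
    inwin <- abs(sub_t - tk) <= 1800
    mean(vals[inwin])
  }, numeric(1))
  station_series(node_t, node_v, x = position[1], y = position[2])
}

# Four crossing city routes, 4-5 km each. Sampling clocks are partly
# staggered, as on a real tram schedule: cross-route pairs at 30/60 s
# lags resolve the anisotropy K, while the two lines sharing a clock
# (L4, L13) yield occasional simultaneous near-crossing samples whose
# near-zero metric distance anchors the nugget.
.default_routes <- function(sampling_interval = 40) {
  list(
    route_spec("L4", rbind(c(-2000, -2000), c(2000, -1200)),
               sampling_interval = sampling_interval, start_offset = 0),
    route_spec("L7", rbind(c(-1800, 2000), c(1400, -1600)),
               sampling_interval = sampling_interval, start_offset = 30),
    route_spec("L8", rbind(c(-2500, 500), c(2400, 700)),
               sampling_interval = sampling_interval, start_offset = 60),
    route_spec("L13", rbind(c(0, -2500), c(300, 2300)),
               sampling_interval = sampling_interval, start_offset = 0)
  )
}

.default_faults <- function(sensor_ids) {
  sensor_fault_spec(sensor_ids,
                    a = rep_len(c(-4, 2, 6, -1), length(sensor_ids)),
                    b = rep_len(c(1.9, 2.1, 2.0, 1.8), length(sensor_ids)),
                    noise_sd = 1)
}

#' Simulate a full synthetic mobile campaign
#'
#' One sensor rides each route daily between `day_start` and
#' `day_start + day_hours` o'clock; the fixed station records the same
#' latent field realisation continuously (mobile samples and station
#' sub-hour samples are part of a single joint Gaussian draw). Raw
#' readings are the latent values pushed through each sensor's inverse
#' calibration plus noise. The last campaign day is conventionally the
#' prediction day; earlier days feed variography.
#'
#' @param routes List of `route_spec` (default: 4 crossing city routes,
#'   4-5 km each).
#' @param field A `field_spec`.
#' @param faults A `sensor_fault_spec`, one row per route/sensor
#'   (default: biases `a` in [-4, 6] ug/m3, `b` around 2, noise sd 1).
#' @param n_days Number of campaign days (default 2; the last is the
#'   prediction day, and all days feed variography).
#' @param day_start,day_hours Daily sampling window (default 07:00 for
#'   10 h, covering the mid-afternoon ozone peak).
#' @param station_pos `c(x, y)` of the fixed station.
#' @param seed Integer seed; identical inputs give an identical campaign.
#' @param cap Dense-simulation cap passed to [simulate_field()].
#' @return An object of class `st_campaign`: a list with elements
#'   `raw` (uncalibrated `observation_set`), `truth` (latent values as a
#'   calibrated `observation_set`), `station` (`station_series`),
#'   `faults`, `routes`, `field`, `n_days`, `seed`.
#' @export
simulate_campaign <- function(routes = .default_routes(),
                              field = field_spec(),
                              faults = NULL,
                              n_days = 2, day_start = 7, day_hours = 10,
                              station_pos = c(0, 0), seed = 1, cap = 8000) {
  duration <- n_days * 86400
  traj <- generate_trajectories(routes, duration)
  hour <- (traj$t / 3600) %% 24
  traj <- traj[hour >= day_start & hour < day_start + day_hours, , drop = FALSE]
  traj$sensor_id <- paste0("sensor_", traj$route_id)
  if (is.null(faults)) faults <- .default_faults(unique(traj$sensor_id))

  dt <- 3600 / 6
  sub_t <- seq(dt / 2, duration - dt / 2, by = dt)
  station_pts <- data.frame(x = station_pos[1], y = station_pos[2], t = sub_t)
  all_pts <- rbind(traj[, c("x", "y", "t")], station_pts)
  latent <- simulate_field(all_pts, field, seed = seed, cap = cap)
  n_m <- nrow(traj)
  latent_mobile <- latent[seq_len(n_m)]
  station <- .hourly_nodes(sub_t, latent[(n_m + 1L):length(latent)],
                           duration, station_pos)

  raw_values <- corrupt_sensors(latent_mobile, traj$sensor_id, faults, seed = seed)
  base <- data.frame(sensor_id = traj$sensor_id, x = traj$x, y = traj$y,
                     t = traj$t, route_id = traj$route_id,
                     stringsAsFactors = FALSE)
  raw <- base; raw$value <- raw_values; raw$calibrated <- FALSE
  truth <- base; truth$value <- latent_mobile; truth$calibrated <- TRUE
  structure(list(
    raw = suppressWarnings(observation_set(raw)),
    truth = observation_set(truth),
    station = station,
    faults = faults, routes = routes, field = field,
    n_days = n_days, day_start = day_start, day_hours = day_hours,
    seed = seed
  ), class = "st_campaign")
}

#' @export
print.st_campaign <- function(x, ...) {
  cat(sprintf(
    "<st_campaign: %d days, %d sensors, %d observations, seed %d>\n",
    x$n_days, length(unique(x$raw$obs$sensor_id)), n_obs(x$raw), x$seed))
  invisible(x)
}

#' Select one campaign day from an observation set
#'
#' @param x An `observation_set`.
#' @param day Zero-based day index (e.g. `n_days - 1` for the last,
#'   prediction, day).
#' @return An `observation_set` restricted to `t` in
#'   `[day * 86400, (day + 1) * 86400)`.
#' @export
campaign_day <- function(x, day) {
  subset_obs(x, x$obs$t >= day * 86400 & x$obs$t < (day + 1) * 86400)
}

#' Write a campaign's CSV artefacts
#'
#' Emits `observations.csv` (raw), `truth.csv` (latent values) and
#' `station.csv` into `dir`.
#'
#' @param campaign An `st_campaign`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_observations(campaign$raw, file.path(dir, "observations.csv"))
  write_observations(campaign$truth, file.path(dir, "truth.csv"))
  write_station(campaign$station, file.path(dir, "station.csv"),
                epoch = campaign$raw$epoch)
  invisible(dir)
}
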