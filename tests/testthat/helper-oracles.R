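# Shared fixtures and independent oracles used across test files.
# Oracles are deliberately naive (double loops, generic dense solves) and
# never call the implementation paths they check.

# -- tiny fixtures -----------------------------------------------------------

obs_set <- function(x, y, t, value, sensor_id = "s1", ...) {
  suppressWarnings(observation_set(
    data.frame(sensor_id = sensor_id, x = x, y = y, t = t, value = value,
               calibrated = TRUE, ...)))
}

linear_station <- function(hours = 0:48, base = 30, slope = 5) {
  station_series(hours * 3600, base + slope * sin(hours / 3))
}

# Random scattered calibrated observations.
random_obs <- function(n, seed = 1, tmax = 7200, span = 3000) {
  set.seed(seed)
  obs_set(x = stats::runif(n, -span, span), y = stats::runif(n, -span, span),
          t = stats::runif(n, 0, tmax), value = stats::rnorm(n, 40, 8),
          sensor_id = sample(paste0("s", 1:4), n, replace = TRUE))
}

# A small, quick campaign shared by several test files (lazily built).
.small_campaign_cache <- new.env(parent = emptyenv())
small_campaign <- function(seed = 5) {
  key <- paste0("c", seed)
  if (is.null(.small_campaign_cache[[key]])) {
    routes <- list(
      route_spec("A", rbind(c(-1500, -800), c(1500, 400)),
                 sampling_interval = 60, start_offset = 0),
      route_spec("B", rbind(c(-900, 1200), c(700, -1300)),
                 sampling_interval = 60, start_offset = 20),
      route_spec("C", rbind(c(-1600, 300), c(1600, 500)),
                 sampling_interval = 60, start_offset = 0)
    )
    .small_campaign_cache[[key]] <- suppressWarnings(suppressMessages(
      simulate_campaign(routes = routes, n_days = 2, day_start = 8,
                        day_hours = 6, seed = seed)))
  }
  .small_campaign_cache[[key]]
}

# Calibration fixture with response-side noise: the station reports
# a + b * X + eps at its own node times, where X is the raw signal.
noisy_calib_fixture <- function(n, seed, a = 3, b = 2, sd = 1) {
  set.seed(seed)
  t <- seq(0, by = 60, length.out = n)
  xv <- stats::runif(n, 10, 40)
  Fv <- a + b * xv + stats::rnorm(n, 0, sd)
  list(obs = obs_set(x = seq_len(n), y = 0, t = t, value = xv),
       station = station_series(t, Fv))
}

# -- empirical variogram oracle: O(n^2) double loop --------------------------

bf_variogram <- function(d, s_edges, u_edges, hmax, umax,
                         direction = NULL, tolerance = 45) {
  nsb <- length(s_edges) - 1L; ntb <- length(u_edges) - 1L
  sums <- matrix(0, nsb, ntb); counts <- matrix(0, nsb, ntb)
  n <- nrow(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dx <- d$x[j] - d$x[i]; dy <- d$y[j] - d$y[i]
      h <- sqrt(dx^2 + dy^2); u <- abs(d$t[j] - d$t[i])
      if (h > hmax || u > umax) next
      if (!is.null(direction)) {
        ang <- (atan2(dx, dy) * 180 / pi) %% 180
        axis <- if (direction == "ns") 0 else 90
        delta <- min(abs(ang - axis), 180 - abs(ang - axis))
        zero <- dx == 0 && dy == 0
        keep <- if (direction == "ew") (delta <= tolerance) || zero
                else (delta < tolerance) && !zero
        if (!keep) next
      }
      sb <- findInterval(h, s_edges, rightmost.closed = TRUE)
      ub <- findInterval(u, u_edges, rightmost.closed = TRUE)
      sums[sb, ub] <- sums[sb, ub] + (d$value[j] - d$value[i])^2 / 2
      counts[sb, ub] <- counts[sb, ub] + 1
    }
  }
  list(sums = sums, counts = counts)
}

# -- kriging oracles: generic dense bordered-system solves -------------------

oracle_gamma <- function(model, p1, p2) {
  matrix(st_semivariance(model,
                         sqrt(outer(p1$x, p2$x, "-")^2 + outer(p1$y, p2$y, "-")^2),
                         abs(outer(p1$t, p2$t, "-"))),
         nrow(p1), nrow(p2))
}

# Target-to-data semivariance, limit-from-above convention (nugget at 0).
oracle_gamma0 <- function(model, nb, tg) {
  d0 <- sqrt((nb$x - tg$x)^2 + (nb$y - tg$y)^2 + (model$K * (nb$t - tg$t))^2)
  g <- st_semivariance(model, d0, 0)
  g[d0 == 0] <- model$nugget
  g
}

oracle_sk <- function(nb, station, model, tg) {
  n <- nrow(nb)
  dmat <- sqrt(outer(nb$x, nb$x, "-")^2 + outer(nb$y, nb$y, "-")^2 +
                 (model$K * outer(nb$t, nb$t, "-"))^2)
  C <- total_sill(model) - st_semivariance(model, dmat, 0)
  c0 <- total_sill(model) - oracle_gamma0(model, nb, tg)
  lambda <- solve(C, c0)
  r <- nb$value - station_value(station, nb$t)
  list(weights = lambda,
       prediction = station_value(station, tg$t) + sum(lambda * r),
       variance = total_sill(model) - sum(lambda * c0))
}

oracle_ok <- function(nb, model, tg) {
  n <- nrow(nb)
  G <- oracle_gamma(model, nb, nb)
  g0 <- oracle_gamma0(model, nb, tg)
  A <- rbind(cbind(G, rep(1, n)), c(rep(1, n), 0))
  z <- solve(A, c(g0, 1))
  list(weights = z[1:n], mu = z[n + 1],
       prediction = sum(z[1:n] * nb$value),
       variance = sum(z[1:n] * g0) + z[n + 1])
}

oracle_ked <- function(nb, station, model, tg) {
  n <- nrow(nb)
  G <- oracle_gamma(model, nb, nb)
  g0 <- oracle_gamma0(model, nb, tg)
  Fd <- cbind(1, station_value(station, nb$t))
  f0 <- c(1, station_value(station, tg$t))
  A <- rbind(cbind(G, Fd), cbind(t(Fd), matrix(0, 2, 2)))
  z <- solve(A, c(g0, f0))
  list(weights = z[1:n], multipliers = z[n + 1:2],
       prediction = sum(z[1:n] * nb$value),
       variance = sum(z[1:n] * g0) + sum(z[n + 1:2] * f0))
}

# Random kriging instance: n points + target + a bounded model.
random_instance <- function(seed, n_max = 15) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  nb <- data.frame(
    sensor_id = "s1",
    x = stats::runif(n, -2000, 2000), y = stats::runif(n, -2000, 2000),
    t = stats::runif(n, 0, 36000), value = stats::rnorm(n, 50, 8))
  model <- variogram_model(sample(c("spherical", "exponential", "bounded_linear"), 1),
                           sill = stats::runif(1, 20, 80),
                           nugget = stats::runif(1, 0, 10),
                           range = stats::runif(1, 2000, 20000),
                           K = stats::runif(1, 10, 200))
  tg <- list(x = stats::runif(1, -2000, 2000), y = stats::runif(1, -2000, 2000),
             t = stats::runif(1, 0, 36000))
  list(nb = nb, model = model, tg = tg,
       station = linear_station())
}
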