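# Empirical spatio-temporal variography.
#
# For every unordered observation pair within the lag limits, half the
# squared value difference is accumulated into a (spatial, temporal) lag
# bin; the surface gamma_hat is the per-bin mean. The spatial lag limit
# defaults to half the maximum pairwise spatial distance; the temporal
# limit is a configuration choice, with a helper that suggests the
# smallest limit at which the temporal margin levels off.

#' Empirical spatio-temporal variogram
#'
#' @param x An `observation_set` (values should be calibrated, or
#'   residuals, depending on the intended model).
#' @param n_spatial_bins,n_temporal_bins Equal-width bin counts
#'   (default 12 x 12).
#' @param max_spatial_lag Metres; `NULL` (default) uses half the maximum
#'   pairwise spatial distance in the data.
#' @param max_temporal_lag Seconds (default 1 h).
#' @param direction `NULL` (omnidirectional) or `"ns"`/`"ew"`: restrict
#'   to pairs whose spatial displacement azimuth lies within
#'   `tolerance` of the north-south / east-west axis. With the default
#'   45 degree tolerance the two axes partition all pairs; ties on the
#'   diagonal (and zero-displacement pairs, which have no azimuth) go to
#'   east-west.
#' @param tolerance Directional half-angle in degrees (default 45).
#' @return An object of class `empirical_variogram`: bin edges, the
#'   `gamma` matrix ((ug/m3)^2, spatial bins x temporal bins, `NA` where
#'   a bin holds no pairs), matching `counts`, and metadata.
#' @export
empirical_variogram <- function(x, n_spatial_bins = 12, n_temporal_bins = 12,
                                max_spatial_lag = NULL,
                                max_temporal_lag = 3600,
                                direction = NULL, tolerance = 45) {
  d <- x$obs
  if (nrow(d) < 2L) {
    stop_stkrige("stkrige_invalid_input", "need >= 2 observations")
  }
  dup <- duplicated(d[, c("x", "y", "t")])
  if (any(dup)) {
    log_event("variogram", "deduplicated_points", n = sum(dup))
    d <- d[!dup, , drop = FALSE]
  }
  if (is.null(max_spatial_lag)) max_spatial_lag <- max_pairwise_distance(d) / 2
  s_edges <- seq(0, max_spatial_lag, length.out = n_spatial_bins + 1)
  u_edges <- seq(0, max_temporal_lag, length.out = n_temporal_bins + 1)

  acc <- .accumulate_pairs(d, s_edges, u_edges, max_spatial_lag,
                           max_temporal_lag, direction, tolerance)
  counts <- matrix(acc$counts, n_spatial_bins, n_temporal_bins)
  gamma <- matrix(acc$sums, n_spatial_bins, n_temporal_bins) / counts
  mean_h <- matrix(acc$h_sums, n_spatial_bins, n_temporal_bins) / counts
  mean_u <- matrix(acc$u_sums, n_spatial_bins, n_temporal_bins) / counts
  gamma[counts == 0] <- NA_real_
  mean_h[counts == 0] <- NA_real_
  mean_u[counts == 0] <- NA_real_
  if (all(counts == 0)) {
    stop_stkrige("stkrige_empty_variogram", "no pairs fall inside the lag limits")
  }
  structure(list(
    s_edges = s_edges, u_edges = u_edges, gamma = gamma, counts = counts,
    mean_h = mean_h, mean_u = mean_u,
    max_spatial_lag = max_spatial_lag, max_temporal_lag = max_temporal_lag,
    direction = direction, tolerance = if (is.null(direction)) NA_real_ else tolerance,
    n_obs = nrow(d), value_var = stats::var(d$value)
  ), class = "empirical_variogram")
}

# Windowed pair sweep: observations are time-sorted, so for each anchor
# the admissible partners are a contiguous block.
.accumulate_pairs <- function(d, s_edges, u_edges, hmax, umax,
                              direction, tolerance) {
  n <- nrow(d)
  nsb <- length(s_edges) - 1L; ntb <- length(u_edges) - 1L
  sums <- numeric(nsb * ntb); counts <- numeric(nsb * ntb)
  h_sums <- numeric(nsb * ntb); u_sums <- numeric(nsb * ntb)
  xs <- d$x; ys <- d$y; ts <- d$t; zs <- d$value
  hi <- 1L
  for (i in seq_len(n - 1L)) {
    if (hi < i + 1L) hi <- i + 1L
    while (hi <= n && ts[hi] - ts[i] <= umax) hi <- hi + 1L
    if (hi == i + 1L) next
    j <- (i + 1L):(hi - 1L)
    dx <- xs[j] - xs[i]; dy <- ys[j] - ys[i]
    h <- sqrt(dx^2 + dy^2)
    keep <- h <= hmax
    if (!is.null(direction)) {
      keep <- keep & .direction_keep(dx, dy, direction, tolerance)
    }
    if (!any(keep)) next
    h <- h[keep]; u <- ts[j[keep]] - ts[i]
    sb <- findInterval(h, s_edges, rightmost.closed = TRUE)
    ub <- findInterval(u, u_edges, rightmost.closed = TRUE)
    idx <- sb + (ub - 1L) * nsb
    sq <- (zs[j[keep]] - zs[i])^2 / 2
    tab <- rowsum(cbind(sq, 1, h, u), idx)
    at <- as.integer(rownames(tab))
    sums[at] <- sums[at] + tab[, 1]
    counts[at] <- counts[at] + tab[, 2]
    h_sums[at] <- h_sums[at] + tab[, 3]
    u_sums[at] <- u_sums[at] + tab[, 4]
  }
  list(sums = sums, counts = counts, h_sums = h_sums, u_sums = u_sums)
}

# Directional filter on displacement azimuth, folded to [0, 180).
# Axis azimuths: north-south 0, east-west 90. Pairs exactly on the
# tolerance boundary, and zero-displacement pairs, count as east-west.
.direction_keep <- function(dx, dy, direction, tolerance) {
  ang <- (atan2(dx, dy) * 180 / pi) %% 180
  axis <- if (direction == "ns") 0 else 90
  delta <- abs(ang - axis)
  delta <- pmin(delta, 180 - delta)
  zero <- dx == 0 & dy == 0
  if (direction == "ew") (delta <= tolerance) | zero
  else (delta < tolerance) & !zero
}

# Maximum pairwise spatial distance; the diameter is attained on the
# convex hull, so only hull vertices are compared.
max_pairwise_distance <- function(d) {
  pts <- unique(cbind(d$x, d$y))
  if (nrow(pts) == 1L) return(0)
  if (nrow(pts) > 3L) pts <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  max(stats::dist(pts))
}

#' Both directional variograms (north-south and east-west)
#'
#' @inheritParams empirical_variogram
#' @return A list with elements `ns` and `ew`, each an
#'   `empirical_variogram`. With `tolerance = 45` the two partition all
#'   pairs, so their counts sum to the omnidirectional counts.
#' @export
directional_variograms <- function(x, n_spatial_bins = 12, n_temporal_bins = 12,
                                   max_spatial_lag = NULL,
                                   max_temporal_lag = 3600, tolerance = 45) {
  list(
    ns = empirical_variogram(x, n_spatial_bins, n_temporal_bins,
                             max_spatial_lag, max_temporal_lag, "ns", tolerance),
    ew = empirical_variogram(x, n_spatial_bins, n_temporal_bins,
                             max_spatial_lag, max_temporal_lag, "ew", tolerance)
  )
}

#' Suggest a temporal lag cutoff
#'
#' Computes the purely temporal margin of the variogram in `step`-wide
#' bins and returns the upper edge of the first bin at which the margin
#' stops increasing (relative slope below `slope_tol` per bin) -- the
#' step-by-step search for the lag at which a sill appears. The helper
#' suggests; the configuration decides.
#'
#' @param x An `observation_set`.
#' @param step Bin width in seconds (default 1 h).
#' @param max_limit Largest limit considered (default 12 h).
#' @param slope_tol Relative per-bin increase under which the margin is
#'   judged flat (default 0.05).
#' @return Suggested cutoff in seconds.
#' @export
suggest_temporal_cutoff <- function(x, step = 3600, max_limit = 12 * 3600,
                                    slope_tol = 0.05) {
  d <- x$obs
  edges <- seq(0, max_limit, by = step)
  sums <- numeric(length(edges) - 1L); counts <- numeric(length(edges) - 1L)
  ts <- d$t; zs <- d$value; n <- nrow(d)
  hi <- 1L
  for (i in seq_len(n - 1L)) {
    if (hi < i + 1L) hi <- i + 1L
    while (hi <= n && ts[hi] - ts[i] <= max_limit) hi <- hi + 1L
    if (hi == i + 1L) next
    j <- (i + 1L):(hi - 1L)
    ub <- findInterval(ts[j] - ts[i], edges, rightmost.closed = TRUE)
    tab <- rowsum(cbind((zs[j] - zs[i])^2 / 2, 1), ub)
    at <- as.integer(rownames(tab))
    sums[at] <- sums[at] + tab[, 1]
    counts[at] <- counts[at] + tab[, 2]
  }
  g <- sums / pmax(counts, 1)
  for (k in 2:length(g)) {
    if (counts[k] > 0 && counts[k - 1] > 0 &&
        (g[k] - g[k - 1]) / max(g[k - 1], .Machine$double.eps) < slope_tol) {
      return(edges[k + 1])
    }
  }
  warn_stkrige("stkrige_no_sill",
               "temporal margin still increasing at max_limit; returning it")
  max_limit
}

#' Subtract the station series from observations
#'
#' Residuals `Z(x, t) - F(t)` remove the temporal component carried by
#' the fixed station, leaving the spatial variability unchanged; this is
#' the working field for simple kriging and for the residual variogram.
#' Observations outside the station span are dropped with a logged count.
#'
#' @param x A calibrated `observation_set`.
#' @param station A `station_series`.
#' @return An `observation_set` of residual values.
#' @export
station_residuals <- function(x, station) {
  inside <- in_station_span(station, x$obs$t)
  if (any(!inside)) {
    log_event("variogram", "residuals_outside_span", n = sum(!inside))
  }
  out <- subset_obs(x, inside)
  out$obs$value <- out$obs$value - station_value(station, out$obs$t)
  out
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf(
    "<empirical_variogram: %dx%d bins, h <= %.0f m, u <= %.1f h, %d obs%s>\n",
    nrow(x$gamma), ncol(x$gamma), x$max_spatial_lag, x$max_temporal_lag / 3600,
    x$n_obs,
    if (!is.null(x$direction)) paste0(", direction ", x$direction) else ""))
  cat(sprintf("  pairs: %.0f total, %d empty bins\n",
              sum(x$counts), sum(x$counts == 0)))
  invisible(x)
}

#' @export
plot.empirical_variogram <- function(x, ...) {
  sc <- (x$s_edges[-1] + x$s_edges[-length(x$s_edges)]) / 2
  uc <- (x$u_edges[-1] + x$u_edges[-length(x$u_edges)]) / 2
  graphics::filled.contour(
    sc, uc / 3600, x$gamma,
    xlab = "spatial lag (m)", ylab = "temporal lag (h)",
    main = "Empirical spatio-temporal variogram", ...)
  invisible(x)
}

# Bin lag coordinates used when fitting a model to the surface:
# count-weighted mean pair lags per bin (the usual practice, unbiased
# when data sit on a sampling lattice) or geometric bin midpoints.
bin_lags <- function(emp, lag_summary = c("mean", "center")) {
  lag_summary <- match.arg(lag_summary)
  if (lag_summary == "mean" && !is.null(emp$mean_h)) {
    return(list(h = emp$mean_h, u = emp$mean_u))
  }
  bin_centers(emp)
}

# Geometric bin midpoints.
bin_centers <- function(emp) {
  sc <- (emp$s_edges[-1] + emp$s_edges[-length(emp$s_edges)]) / 2
  uc <- (emp$u_edges[-1] + emp$u_edges[-length(emp$u_edges)]) / 2
  list(h = matrix(sc, length(sc), length(uc)),
       u = matrix(uc, length(sc), length(uc), byrow = TRUE))
}
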