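# Fitting a metric model to an empirical variogram surface.
#
# The objective is the unweighted mean, over nonempty bins, of the
# squared deviation between the binned gamma_hat and the model evaluated
# at the bin centres; minimised over (sill, nugget, range, K) by
# L-BFGS-B from several jittered starts.

#' Fit a metric variogram model to an empirical surface
#'
#' @param emp An `empirical_variogram`.
#' @param family Joint model family (`"spherical"`, `"exponential"`,
#'   `"bounded_linear"`).
#' @param bounds Optional named list overriding the default box
#'   constraints, each element `c(lower, upper)` for `sill`, `nugget`,
#'   `range` (m) and `K` (m/s). Defaults: sill and nugget in
#'   `[0, 10 * var(values)]`, range in `[10, 10 * max metric lag]`,
#'   K in `[0.1, 1e4]`.
#' @param n_starts Number of multistart initialisations (default 8),
#'   the first at a moment-based heuristic, the rest jittered from it.
#' @param seed Seed for the jitter.
#' @param weighted Weight bins by pair counts (default `FALSE`: the
#'   plain average of squared deviations).
#' @param lag_summary How a bin's lag coordinates enter the objective:
#'   `"mean"` (default) uses the count-weighted mean pair lags, which is
#'   unbiased when observations sit on a sampling lattice; `"center"`
#'   uses geometric bin midpoints.
#' @return An object of class `variogram_fit`: the best `model`, its
#'   `objective`, optimizer `convergence`, and the `starts` table.
#' @export
fit_variogram <- function(emp, family = "exponential", bounds = NULL,
                          n_starts = 8, seed = 1, weighted = FALSE,
                          lag_summary = c("mean", "center")) {
  ok_bins <- is.finite(emp$gamma)
  if (sum(ok_bins) < 4L) {
    stop_stkrige("stkrige_insufficient_data",
                 "need >= 4 nonempty bins to fit 4 parameters")
  }
  bc <- bin_lags(emp, lag_summary)
  h <- bc$h[ok_bins]; u <- bc$u[ok_bins]; g <- emp$gamma[ok_bins]
  w <- if (weighted) emp$counts[ok_bins] / sum(emp$counts[ok_bins]) else
    rep(1 / sum(ok_bins), sum(ok_bins))

  b <- .fit_bounds(emp, bounds)
  lower <- vapply(b, `[`, numeric(1), 1L)
  upper <- vapply(b, `[`, numeric(1), 2L)

  objective <- function(par) {
    m <- list(family = family, sill = par[1], nugget = par[2],
              range = par[3], K = par[4])
    class(m) <- "variogram_model"
    gm <- gamma_metric(m, sqrt(h^2 + (m$K * u)^2))
    sum(w * (g - gm)^2)
  }

  starts <- .fit_starts(emp, g, n_starts, seed, lower, upper)
  records <- vector("list", nrow(starts))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    par0 <- as.numeric(starts[s, ])
    res <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(parscale = pmax(abs(par0), 1e-3),
                                  maxit = 500)),
      error = function(e) NULL)
    records[[s]] <- data.frame(
      start_sill = par0[1], start_nugget = par0[2], start_range = par0[3],
      start_K = par0[4],
      objective = if (is.null(res)) NA_real_ else res$value,
      convergence = if (is.null(res)) NA_integer_ else res$convergence)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop_stkrige("stkrige_fit_failure",
                 "optimizer failed from every start",
                 starts = do.call(rbind, records))
  }
  model <- variogram_model(family, sill = best$par[1], nugget = best$par[2],
                           range = best$par[3], K = best$par[4])
  structure(list(model = model, objective = best$value,
                 convergence = best$convergence,
                 starts = do.call(rbind, records),
                 weighted = weighted, n_bins = sum(ok_bins),
                 range_convention = "practical (exponential reaches ~95% of the sill at `range`)"),
            class = "variogram_fit")
}

.fit_bounds <- function(emp, bounds) {
  max_metric_lag <- sqrt(emp$max_spatial_lag^2 + (1e4 * emp$max_temporal_lag)^2)
  default <- list(
    sill = c(0, 10 * emp$value_var),
    nugget = c(0, 10 * emp$value_var),
    range = c(10, 10 * max_metric_lag),
    K = c(0.1, 1e4)
  )
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), names(default))
    if (length(bad)) {
      stop_stkrige("stkrige_invalid_input",
                   paste0("unknown bound name(s): ", paste(bad, collapse = ", ")))
    }
    default[names(bounds)] <- bounds
  }
  default
}

# Heuristic start: sill from the high-lag plateau, small nugget, range
# at half the spatial span scaled into metric units, K matching the two
# lag limits; remaining starts are log-normal jitters of it.
.fit_starts <- function(emp, g, n_starts, seed, lower, upper) {
  K0 <- max(emp$max_spatial_lag / max(emp$max_temporal_lag, 1), lower[4])
  start0 <- c(sill = max(stats::quantile(g, 0.9) - min(g), 1e-3),
              nugget = max(min(g), 1e-3),
              range = emp$max_spatial_lag,
              K = K0)
  set.seed(derive_seed(seed, 11L))
  starts <- matrix(rep(start0, each = n_starts), n_starts, 4)
  if (n_starts > 1) {
    jit <- matrix(stats::rlnorm(4 * (n_starts - 1), 0, 0.6), n_starts - 1, 4)
    starts[-1, ] <- starts[-1, , drop = FALSE] * jit
  }
  colnames(starts) <- c("sill", "nugget", "range", "K")
  starts <- pmin(pmax(starts, matrix(lower, n_starts, 4, byrow = TRUE)),
                 matrix(upper, n_starts, 4, byrow = TRUE))
  as.data.frame(starts)
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat("Metric spatio-temporal variogram fit (L-BFGS-B, multistart):\n  ")
  print(x$model)
  cat(sprintf("  objective (mean sq. dev. over %d bins): %.6g | convergence %d\n",
              x$n_bins, x$objective, x$convergence))
  invisible(x)
}

#' @export
coef.variogram_fit <- function(object, ...) coef(object$model)

#' @export
predict.variogram_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
summary.variogram_fit <- function(object, ...) {
  cat(sprintf("family: %s (range convention: %s)\n",
              object$model$family, object$range_convention))
  print(coef(object))
  cat(sprintf("objective %.6g over %d bins (%s)\n", object$objective,
              object$n_bins, if (object$weighted) "count-weighted" else "unweighted"))
  cat("multistart objectives:\n")
  print(object$starts$objective)
  invisible(object)
}

#' Fit the per-method variogram models for a campaign
#'
#' Convenience wrapper for the usual model line-up: ordinary kriging
#' uses a variogram of the calibrated data itself, while simple kriging
#' and kriging with external drift use the variogram of the station
#' residuals `Z - F(t)`. With `families = "auto"` (the default) each
#' surface gets the joint family (spherical, exponential or
#' bounded-linear) with the smallest fitting objective; a named vector
#' such as `c(sk = "spherical", ok = "bounded_linear",
#' ked = "exponential")` pins the families instead.
#'
#' @param obs A calibrated `observation_set` (the variography days).
#' @param station A `station_series`.
#' @param families `"auto"` or a named character vector mapping the
#'   methods to families.
#' @param seed Seed for the fits.
#' @param n_starts Multistart count per fit (default 8).
#' @param ... Passed to [empirical_variogram()]
#'   (`n_spatial_bins`, `n_temporal_bins`, `max_temporal_lag`, ...).
#' @return Named list of `variogram_model` for `sk`, `ok`, `ked`.
#' @export
fit_method_models <- function(obs, station, families = "auto",
                              seed = 1, n_starts = 8, ...) {
  resid <- station_residuals(obs, station)
  emp_raw <- empirical_variogram(obs, ...)
  emp_res <- empirical_variogram(resid, ...)
  fit_one <- function(emp, method) {
    if (identical(families, "auto")) {
      fits <- lapply(.VGM_FAMILIES, function(fam) {
        fit_variogram(emp, fam, seed = seed, n_starts = n_starts)
      })
      best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
      log_event("variogram_fit", "family_selected", method = method,
                family = best$model$family)
      best$model
    } else {
      fit_variogram(emp, families[[method]], seed = seed,
                    n_starts = n_starts)$model
    }
  }
  list(sk = fit_one(emp_res, "sk"), ok = fit_one(emp_raw, "ok"),
       ked = fit_one(emp_res, "ked"))
}
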