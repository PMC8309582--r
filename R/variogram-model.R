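# Metric spatio-temporal variogram models.
#
# A metric model collapses a spatial lag h (metres) and temporal lag u
# (seconds) into one distance d = sqrt(h^2 + (K*u)^2), where the
# anisotropy parameter K (m/s) is the number of space units equivalent
# to one time unit, and applies a single joint variogram family to d.

.VGM_FAMILIES <- c("spherical", "exponential", "bounded_linear")

#' Construct a metric spatio-temporal variogram model
#'
#' @param family One of `"spherical"`, `"exponential"`,
#'   `"bounded_linear"`. The exponential range is the practical range
#'   (the lag at which ~95% of the sill is reached); `bounded_linear`
#'   rises linearly to the range and is flat beyond it.
#' @param sill Partial sill above the nugget, (ug/m3)^2, >= 0.
#' @param nugget Nugget, (ug/m3)^2, >= 0. `gamma(0, 0) = 0` exactly; the
#'   nugget is the limit from above.
#' @param range Range in metric distance (metres), > 0.
#' @param K Spatio-temporal anisotropy in m/s, > 0.
#' @return An object of class `variogram_model`.
#' @examples
#' m <- variogram_model("exponential", sill = 60, nugget = 2,
#'                      range = 10000, K = 100)
#' st_semivariance(m, h = 3000, u = 0)
#' @export
variogram_model <- function(family, sill, nugget, range, K) {
  family <- match.arg(family, .VGM_FAMILIES)
  if (sill < 0 || nugget < 0) {
    stop_stkrige("stkrige_invalid_input", "sill and nugget must be >= 0")
  }
  if (range <= 0) stop_stkrige("stkrige_invalid_input", "range must be > 0")
  if (K <= 0) stop_stkrige("stkrige_invalid_input", "K must be > 0")
  structure(list(family = family, sill = sill, nugget = nugget,
                 range = range, K = K),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "<variogram_model: %s | sill %.4g  nugget %.4g  range %.5g m  K %.4g m/s>\n",
    x$family, x$sill, x$nugget, x$range, x$K))
  invisible(x)
}

#' @export
coef.variogram_model <- function(object, ...) {
  c(sill = object$sill, nugget = object$nugget,
    range = object$range, K = object$K)
}

# Joint semivariance as a function of metric distance d >= 0.
# Preserves the shape (vector or matrix) of d.
gamma_metric <- function(model, d) {
  g <- d
  g[] <- 0
  pos <- d > 0
  dp <- d[pos]
  r <- model$range
  base <- switch(model$family,
    spherical = ifelse(dp < r,
                       model$sill * (1.5 * dp / r - 0.5 * (dp / r)^3),
                       model$sill),
    exponential = model$sill * (1 - exp(-3 * dp / r)),
    bounded_linear = model$sill * pmin(dp / r, 1)
  )
  g[pos] <- model$nugget + base
  g
}

# Semivariance limit from above: equals gamma for d > 0 but tends to the
# nugget, not 0, at d = 0. Used for target-to-data lags so that a
# positive nugget (micro-scale variation plus measurement error) makes
# the kriging predictors filter rather than reproduce noisy data.
gamma_metric_limit <- function(model, d) {
  g <- gamma_metric(model, d)
  g[d <= 0] <- model$nugget
  g
}

#' Evaluate a metric model's semivariance at spatio-temporal lags
#'
#' @param model A `variogram_model`.
#' @param h Spatial lags in metres, >= 0 (recycled against `u`).
#' @param u Temporal lags in seconds, >= 0.
#' @return Semivariances in (ug/m3)^2; exactly 0 at `(0, 0)`.
#' @export
st_semivariance <- function(model, h, u = 0) {
  if (any(h < 0) || any(u < 0)) {
    stop_stkrige("stkrige_invalid_input", "lags must be non-negative")
  }
  gamma_metric(model, sqrt(h^2 + (model$K * u)^2))
}

#' @export
predict.variogram_model <- function(object, newdata, ...) {
  st_semivariance(object, newdata$h, newdata$u %||% 0)
}

# Covariance form (requires a bounded family, which all three are):
# C(0) = sill + nugget, C(d) = sill + nugget - gamma(d) for d > 0.
cov_metric <- function(model, d) {
  model$sill + model$nugget - gamma_metric(model, d)
}

# Smooth covariance used by the field simulator: nugget excluded from
# the off-diagonal structure (it is simulated as i.i.d. micro-scale
# noise), diagonal equals the partial sill. gamma - nugget is the
# structured (smooth) part of the variogram.
cov_smooth <- function(model, d) {
  out <- numeric(length(d))
  pos <- d > 0
  out[!pos] <- model$sill
  out[pos] <- model$sill - (gamma_metric(model, d[pos]) - model$nugget)
  out
}

#' Total sill (sill + nugget) of a model
#' @param model A `variogram_model`.
#' @return Numeric scalar, the variogram plateau.
#' @export
total_sill <- function(model) model$sill + model$nugget

# Metric distance between two space-time point sets (vectorised).
metric_distance <- function(x1, y1, t1, x2, y2, t2, K) {
  sqrt((x1 - x2)^2 + (y1 - y2)^2 + (K * (t1 - t2))^2)
}
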