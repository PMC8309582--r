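# Kriging predictors and the IDW baseline.
#
# All three kriging systems work on the metric distance
# d = sqrt(dx^2 + dy^2 + (K dt)^2) of the fitted variogram model:
#   * simple kriging (SK) on station residuals, solved in covariance
#     form (the model must be bounded, which all three families are);
#   * ordinary kriging (OK) in variogram form with the sum-to-one
#     constraint through a Lagrange multiplier;
#   * kriging with external drift (KED) in variogram form with drift
#     functions f0 = 1 and f1(x, t) = F(t), the station series.
# Prediction is local: systems are solved over the n_max
# metrically-nearest neighbours of each target.

#' Select the metrically nearest observations to a target
#'
#' Distance is `sqrt(dx^2 + dy^2 + (K dt)^2)`; ties are broken by
#' earlier time, then sensor id.
#'
#' @param x An `observation_set`.
#' @param target Named list or vector with `x`, `y`, `t`.
#' @param n_max Neighbourhood size (default 50).
#' @param K Metric anisotropy in m/s (from the variogram model).
#' @param radius Optional maximum metric distance.
#' @return Integer row indices into `x$obs`, nearest first.
#' @export
select_neighbors <- function(x, target, n_max = 50, K, radius = NULL) {
  d <- x$obs
  if (nrow(d) == 0L) stop_stkrige("stkrige_empty_neighborhood", "no observations")
  dist <- metric_distance(d$x, d$y, d$t, target[["x"]], target[["y"]],
                          target[["t"]], K)
  keep <- if (is.null(radius)) seq_len(nrow(d)) else which(dist <= radius)
  if (!length(keep)) {
    stop_stkrige("stkrige_empty_neighborhood", "no observation within radius")
  }
  ord <- keep[order(dist[keep], d$t[keep], d$sensor_id[keep])]
  ord[seq_len(min(n_max, length(ord)))]
}

# Pairwise metric distance matrix among neighbour rows.
.pair_metric <- function(nb, K) {
  n <- nrow(nb)
  metric_distance(matrix(nb$x, n, n), matrix(nb$y, n, n), matrix(nb$t, n, n),
                  matrix(nb$x, n, n, byrow = TRUE),
                  matrix(nb$y, n, n, byrow = TRUE),
                  matrix(nb$t, n, n, byrow = TRUE), K)
}

# Solve A z = b with diagonal jitter escalation on the leading n x n
# (data) block. Used by every kriging system.
.solve_kriging <- function(A, b, n_data, scale) {
  jitter <- 1e-10 * scale
  for (attempt in 0:3) {
    J <- A
    if (attempt > 0) {
      diag(J)[seq_len(n_data)] <- diag(J)[seq_len(n_data)] + jitter * 10^(attempt - 1)
    }
    z <- tryCatch(solve(J, b), error = function(e) NULL)
    if (!is.null(z)) {
      if (attempt > 0) log_event("kriging", "jitter_escalation", attempts = attempt)
      return(z)
    }
  }
  stop_stkrige("stkrige_singular_system", "kriging system singular after jitter escalation")
}

.clamp_variance <- function(v) {
  if (v < 0) {
    if (v < -1e-6) {
      warn_stkrige("stkrige_negative_variance",
                   sprintf("kriging variance %.3g clamped to 0", v))
    }
    v <- 0
  }
  v
}

.as_solution <- function(method, weights, multipliers, prediction, variance) {
  structure(list(method = method, weights = weights,
                 multipliers = multipliers, prediction = prediction,
                 variance = .clamp_variance(variance)),
            class = "kriging_solution")
}

#' @export
print.kriging_solution <- function(x, ...) {
  cat(sprintf("<kriging_solution [%s]: prediction %.4g, variance %.4g, %d weights>\n",
              x$method, x$prediction, x$variance, length(x$weights)))
  invisible(x)
}

#' Simple kriging on station residuals
#'
#' Treats `r_i = Z_i - F(t_i)` as a zero-mean second-order stationary
#' field and solves the SK system in covariance form,
#' `C(d) = sill + nugget - gamma(d)` for `d > 0` and
#' `C(0) = sill + nugget`. Target-to-data semivariances use the limit
#' from above (the nugget at zero lag), so a positive nugget --
#' micro-scale variation plus measurement error -- makes all three
#' kriging predictors smooth rather than reproduce noisy data; with a
#' zero nugget they are exact. The prediction adds the station value back:
#' `Z* = F(t0) + sum(lambda_i r_i)`; the variance is
#' `(sill + nugget) - sum(lambda_i C(d_i0))`. A literal variogram-form
#' solve (no constraint) is available for comparison via
#' `covariance_form = FALSE`.
#'
#' @param neighbors Data.frame of neighbour rows (`x`, `y`, `t`, `value`,
#'   calibrated values).
#' @param station A `station_series` (all times must lie in its span).
#' @param model A bounded `variogram_model`.
#' @param target Named list/vector with `x`, `y`, `t`.
#' @param covariance_form Solve in covariance form (default `TRUE`).
#' @return A `kriging_solution`.
#' @export
krige_sk <- function(neighbors, station, model, target, covariance_form = TRUE) {
  if (nrow(neighbors) == 0L) stop_stkrige("stkrige_empty_neighborhood", "no neighbours")
  Ft <- station_value(station, c(neighbors$t, target[["t"]]))
  r <- neighbors$value - Ft[-length(Ft)]
  d0 <- metric_distance(neighbors$x, neighbors$y, neighbors$t,
                        target[["x"]], target[["y"]], target[["t"]], model$K)
  dmat <- .pair_metric(neighbors, model$K)
  if (covariance_form) {
    C <- matrix(cov_metric(model, as.vector(dmat)), nrow(neighbors))
    c0 <- total_sill(model) - gamma_metric_limit(model, d0)
    lambda <- .solve_kriging(C, c0, nrow(neighbors), total_sill(model))
    pred <- Ft[length(Ft)] + sum(lambda * r)
    var <- total_sill(model) - sum(lambda * c0)
  } else {
    G <- matrix(gamma_metric(model, as.vector(dmat)), nrow(neighbors))
    g0 <- gamma_metric_limit(model, d0)
    lambda <- .solve_kriging(G, g0, nrow(neighbors), total_sill(model))
    pred <- Ft[length(Ft)] + sum(lambda * r)
    var <- 2 * sum(lambda * g0) - drop(t(lambda) %*% G %*% lambda)
  }
  .as_solution("sk", lambda, NULL, pred, var)
}

#' Ordinary kriging
#'
#' Solves the variogram-form system with the sum-to-one constraint:
#' `sum_j lambda_j gamma_ij + mu = gamma_i0`, `sum lambda = 1`.
#' Prediction `sum(lambda_i Z_i)`; variance
#' `sum(lambda_i gamma_i0) + mu`. Exactly duplicated neighbour points
#' are deduplicated if the system is singular.
#'
#' @inheritParams krige_sk
#' @return A `kriging_solution` (`multipliers` holds the Lagrange mu).
#' @export
krige_ok <- function(neighbors, model, target) {
  if (nrow(neighbors) == 0L) stop_stkrige("stkrige_empty_neighborhood", "no neighbours")
  sol <- tryCatch(.ok_solve(neighbors, model, target), error = function(e) e)
  if (inherits(sol, "stkrige_singular_system")) {
    dup <- duplicated(neighbors[, c("x", "y", "t")])
    if (any(dup)) {
      log_event("kriging", "deduplicated_neighbors", n = sum(dup))
      sol <- .ok_solve(neighbors[!dup, , drop = FALSE], model, target)
    } else {
      stop(sol)
    }
  } else if (inherits(sol, "error")) {
    stop(sol)
  }
  sol
}

.ok_solve <- function(neighbors, model, target) {
  n <- nrow(neighbors)
  G <- matrix(gamma_metric(model, as.vector(.pair_metric(neighbors, model$K))), n)
  g0 <- gamma_metric_limit(model, metric_distance(
    neighbors$x, neighbors$y, neighbors$t,
    target[["x"]], target[["y"]], target[["t"]], model$K))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  z <- .solve_kriging(A, c(g0, 1), n, max(total_sill(model), 1))
  lambda <- z[seq_len(n)]; mu <- z[n + 1L]
  .as_solution("ok", lambda, c(mu = mu),
               sum(lambda * neighbors$value),
               sum(lambda * g0) + mu)
}

#' Kriging with external drift
#'
#' The unknown mean is `a0 + a1 * F(t)`; weights satisfy the two
#' unbiasedness constraints `sum w_i f_l(x_i, t_i) = f_l(x, t)` for
#' `f0 = 1` and `f1 = F(t)`, solved through the bordered variogram-form
#' system. Variance is `sum(w_i gamma_i0) + sum(m_l f_l(target))` with
#' `m_l` the drift multipliers. All `F(t_i)` equal (a rank-deficient
#' drift matrix) raises a drift-degenerate error; callers may catch it
#' and fall back to ordinary kriging.
#'
#' @inheritParams krige_sk
#' @param drift_fns Optional list of extra drift functions
#'   `function(x, y, t)` appended after `f1 = F(t)`.
#' @return A `kriging_solution` (`multipliers` holds one value per
#'   drift function).
#' @export
krige_ked <- function(neighbors, station, model, target, drift_fns = NULL) {
  n <- nrow(neighbors)
  if (n < 2L) stop_stkrige("stkrige_insufficient_data", "KED needs >= 2 neighbours")
  Fd <- cbind(1, station_value(station, neighbors$t))
  f0 <- c(1, station_value(station, target[["t"]]))
  for (fn in drift_fns) {
    Fd <- cbind(Fd, fn(neighbors$x, neighbors$y, neighbors$t))
    f0 <- c(f0, fn(target[["x"]], target[["y"]], target[["t"]]))
  }
  p <- ncol(Fd)
  if (qr(Fd)$rank < p) {
    stop_stkrige("stkrige_drift_degenerate",
                 "drift matrix rank-deficient (station values constant over the neighbourhood?)")
  }
  G <- matrix(gamma_metric(model, as.vector(.pair_metric(neighbors, model$K))), n)
  g0 <- gamma_metric_limit(model, metric_distance(
    neighbors$x, neighbors$y, neighbors$t,
    target[["x"]], target[["y"]], target[["t"]], model$K))
  A <- rbind(cbind(G, Fd), cbind(t(Fd), matrix(0, p, p)))
  z <- .solve_kriging(A, c(g0, f0), n, max(total_sill(model), 1))
  w <- z[seq_len(n)]; m <- z[n + seq_len(p)]
  .as_solution("ked", w, m, sum(w * neighbors$value), sum(w * g0) + sum(m * f0))
}

#' Spatio-temporal inverse distance weighting
#'
#' `d_i = sqrt(dx^2 + dy^2 + C dt^2)`; weights are `d_i^-p` normalised.
#' A target within 1e-9 of an observation returns that observation's
#' value.
#'
#' @param neighbors Data.frame of neighbour rows.
#' @param target Named list/vector with `x`, `y`, `t`.
#' @param C Temporal scaling inside the squared distance (>= 0), in
#'   (m/s)^2-like units.
#' @param p Power (default 2).
#' @return Numeric prediction.
#' @export
idw_predict <- function(neighbors, target, C, p = 2) {
  if (nrow(neighbors) == 0L) stop_stkrige("stkrige_empty_neighborhood", "no neighbours")
  if (C < 0 || p <= 0) stop_stkrige("stkrige_invalid_input", "need C >= 0 and p > 0")
  d <- sqrt((neighbors$x - target[["x"]])^2 + (neighbors$y - target[["y"]])^2 +
              C * (neighbors$t - target[["t"]])^2)
  hit <- which(d < 1e-9)
  if (length(hit)) return(neighbors$value[hit[1]])
  w <- d^(-p)
  sum(w * neighbors$value) / sum(w)
}

#' Tune the IDW temporal scaling C by cross-validation
#'
#' Grid search minimising the mean RMSE of [idw_predict()] over a
#' seeded k-fold random-point split of the training data; ties go to the
#' smaller C. With more than `max_n` observations a seeded subsample is
#' used to keep the search cheap.
#'
#' @param train A calibrated `observation_set`.
#' @param grid Candidate C values (default 10 values log-spaced in
#'   `[1e-4, 1e4]`).
#' @param folds Number of folds (default 4, >= 2).
#' @param seed Integer seed.
#' @param p IDW power (default 2).
#' @param max_n Subsample cap for the search (default 1000).
#' @return The selected C (numeric scalar) with attribute `"rmse"`
#'   giving the per-candidate mean RMSE.
#' @export
tune_idw_c <- function(train, grid = 10^seq(-4, 4, length.out = 10),
                       folds = 4, seed = 1, p = 2, max_n = 1000) {
  if (!length(grid)) stop_stkrige("stkrige_invalid_input", "empty candidate grid")
  if (folds < 2) stop_stkrige("stkrige_invalid_input", "need >= 2 folds")
  d <- train$obs
  set.seed(derive_seed(seed, 21L))
  if (nrow(d) > max_n) d <- d[sort(sample.int(nrow(d), max_n)), , drop = FALSE]
  n <- nrow(d)
  fold_id <- sample(rep_len(seq_len(folds), n))
  if (min(tabulate(fold_id, folds)) == 0L) {
    stop_stkrige("stkrige_fold_error", "a fold is empty")
  }
  rmse <- vapply(grid, function(C) {
    errs <- unlist(lapply(seq_len(folds), function(f) {
      te <- d[fold_id == f, , drop = FALSE]
      tr <- d[fold_id != f, , drop = FALSE]
      preds <- vapply(seq_len(nrow(te)), function(i) {
        idw_predict(tr, te[i, ], C = C, p = p)
      }, numeric(1))
      preds - te$value
    }))
    sqrt(mean(errs^2))
  }, numeric(1))
  best <- which(rmse <= min(rmse) + 1e-12)   # ties toward smaller C
  C <- min(grid[best])
  structure(C, rmse = stats::setNames(rmse, format(grid, digits = 3)))
}

#' Batch point prediction
#'
#' Predicts every target with one method using local neighbourhoods.
#' For kriging methods the kriging variance is returned; for IDW it is
#' `NA`.
#'
#' @param train A calibrated `observation_set`.
#' @param targets Data.frame with columns `x`, `y`, `t`.
#' @param model A `variogram_model` (ignored for `method = "idw"`).
#' @param method One of `"sk"`, `"ok"`, `"ked"`, `"idw"`.
#' @param station A `station_series` (required for `sk` and `ked`).
#' @param n_max Neighbourhood size (default 50; `Inf` for global).
#' @param radius Optional metric-radius cutoff.
#' @param idw_c,idw_p IDW parameters (see [idw_predict()]).
#' @param ked_fallback_ok On a drift-degenerate KED neighbourhood, fall
#'   back to ordinary kriging and flag the row (default `FALSE`:
#'   the error propagates).
#' @return Data.frame `(x, y, t, prediction, variance, fallback)`.
#' @export
st_predict <- function(train, targets, model = NULL,
                       method = c("sk", "ok", "ked", "idw"),
                       station = NULL, n_max = 50, radius = NULL,
                       idw_c = 1, idw_p = 2, ked_fallback_ok = FALSE) {
  method <- match.arg(method)
  if (method %in% c("sk", "ked") && is.null(station)) {
    stop_stkrige("stkrige_invalid_input", paste0(method, " requires a station series"))
  }
  if (method != "idw" && is.null(model)) {
    stop_stkrige("stkrige_invalid_input", "kriging requires a variogram model")
  }
  if (method %in% c("sk", "ked")) {
    if (any(!in_station_span(station, c(train$obs$t, targets$t)))) {
      stop_stkrige("stkrige_extrapolation",
                   "data or target times outside the station span")
    }
  }
  n <- nrow(targets)
  pred <- numeric(n); var <- rep(NA_real_, n); fb <- logical(n)
  d <- train$obs
  if (method == "idw") {
    for (i in seq_len(n)) {
      pred[i] <- idw_predict(d, targets[i, ], C = idw_c, p = idw_p)
    }
  } else {
    for (i in seq_len(n)) {
      tg <- list(x = targets$x[i], y = targets$y[i], t = targets$t[i])
      nb <- d[select_neighbors(train, tg, n_max = n_max, K = model$K,
                               radius = radius), , drop = FALSE]
      sol <- switch(method,
        sk = krige_sk(nb, station, model, tg),
        ok = krige_ok(nb, model, tg),
        ked = if (ked_fallback_ok) {
          tryCatch(krige_ked(nb, station, model, tg),
                   stkrige_drift_degenerate = function(e) {
                     log_event("kriging", "ked_fallback_ok", target = i)
                     fb[i] <<- TRUE
                     krige_ok(nb, model, tg)
                   })
        } else {
          krige_ked(nb, station, model, tg)
        })
      pred[i] <- sol$prediction
      var[i] <- sol$variance
    }
  }
  data.frame(x = targets$x, y = targets$y, t = targets$t,
             prediction = pred, variance = var, fallback = fb)
}
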