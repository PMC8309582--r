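# Validation scenarios, performance indicators, and cross-validation.
#
# Three held-out designs mimic increasingly hard prediction problems:
#   * random_points    -- interpolation between sampled places;
#   * path_segments    -- extrapolation to places close to the sampling
#                         paths (contiguous runs of single-sensor data
#                         are held out);
#   * leave_line_out   -- extrapolation far from the sampling points
#                         (whole routes held out).
# "k-fold" here means k independent seeded re-draws per cell (training
# fractions vary per cell, so disjoint quarters are not applicable);
# leave_line_out instead cycles over the held-out routes.

#' Random-point train/test split
#'
#' @param x An `observation_set`.
#' @param fraction Training fraction in (0, 1); `round(fraction * n)`
#'   observations train, the rest test.
#' @param seed Integer seed.
#' @return List with `train` and `test` observation sets and the
#'   training row indices `idx`.
#' @export
split_random_points <- function(x, fraction, seed = 1) {
  n <- n_obs(x)
  if (n < 2L) stop_stkrige("stkrige_split_error", "need >= 2 observations")
  if (fraction <= 0 || fraction >= 1) {
    stop_stkrige("stkrige_split_error", "fraction must be in (0, 1)")
  }
  n_train <- round(fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop_stkrige("stkrige_split_error", "fraction yields an empty train or test set")
  }
  set.seed(derive_seed(seed, 31L))
  idx <- sort(sample.int(n, n_train))
  list(train = subset_obs(x, idx), test = subset_obs(x, -idx), idx = idx)
}

#' Path-segment train/test split
#'
#' Holds out contiguous-in-time runs of single-sensor observations,
#' run lengths drawn from a normal segment spec (in samples), until the
#' test size is within one observation of `(1 - fraction) * n`; the
#' last run is truncated to fit.
#'
#' @inheritParams split_random_points
#' @param segment_mean,segment_sd Segment-length distribution in
#'   samples (defaults 20 and 10).
#' @return List with `train`, `test`, and training indices `idx`.
#' @export
split_path_segments <- function(x, fraction, segment_mean = 20,
                                segment_sd = 10, seed = 1) {
  n <- n_obs(x)
  if (fraction <= 0 || fraction >= 1) {
    stop_stkrige("stkrige_split_error", "fraction must be in (0, 1)")
  }
  d <- x$obs
  by_sensor <- split(seq_len(n), d$sensor_id)
  if (segment_mean > max(lengths(by_sensor))) {
    stop_stkrige("stkrige_spec_error",
                 "mean segment length exceeds every sensor's track")
  }
  m <- round((1 - fraction) * n)
  if (m < 1L || m >= n) {
    stop_stkrige("stkrige_split_error", "fraction yields an empty train or test set")
  }
  set.seed(derive_seed(seed, 32L))
  taken <- logical(n)
  need <- m
  guard <- 0L
  while (need > 0L && guard < 100L * length(by_sensor)) {
    guard <- guard + 1L
    free_sensors <- names(by_sensor)[vapply(by_sensor, function(ix) any(!taken[ix]), logical(1))]
    if (!length(free_sensors)) break
    s <- sample(free_sensors, 1L)
    ix <- by_sensor[[s]]
    free_pos <- which(!taken[ix])
    start <- sample(free_pos, 1L)
    L <- min(max(1L, round(stats::rnorm(1, segment_mean, segment_sd))), need)
    run <- start
    while (length(run) < L && run[length(run)] + 1L <= length(ix) &&
           !taken[ix[run[length(run)] + 1L]]) {
      run <- c(run, run[length(run)] + 1L)
    }
    taken[ix[run]] <- TRUE
    need <- m - sum(taken)
  }
  idx <- which(!taken)
  list(train = subset_obs(x, idx), test = subset_obs(x, taken), idx = idx)
}

#' Leave-route-out train/test split
#'
#' @param x An `observation_set` (route ids in its `route_id` column).
#' @param routes Character vector of held-out route ids.
#' @return List with `train`, `test`, and training indices `idx`;
#'   deterministic.
#' @export
split_leave_line_out <- function(x, routes) {
  have <- unique(x$obs$route_id)
  unknown <- setdiff(routes, have)
  if (length(unknown)) {
    stop_stkrige("stkrige_lookup_error",
                 paste0("unknown route id(s): ", paste(unknown, collapse = ", ")))
  }
  test_mask <- x$obs$route_id %in% routes
  if (all(test_mask)) {
    stop_stkrige("stkrige_split_error", "holding out every route empties the training set")
  }
  idx <- which(!test_mask)
  list(train = subset_obs(x, idx), test = subset_obs(x, test_mask), idx = idx)
}

#' RMSE, bias, and correlation of predictions against truth
#'
#' `rmse = sqrt(mean((Z* - Z)^2))`, `bias = mean(Z* - Z)`, `corr` the
#' Pearson correlation, `NA` (undefined) when either side has zero
#' variance.
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @return Named list `rmse`, `bias`, `corr`, `n`.
#' @export
compute_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths) || !length(truths)) {
    stop_stkrige("stkrige_invalid_input", "prediction/truth length mismatch")
  }
  e <- predictions - truths
  corr <- if (stats::sd(predictions) == 0 || stats::sd(truths) == 0) NA_real_
          else stats::cor(predictions, truths)
  list(rmse = sqrt(mean(e^2)), bias = mean(e), corr = corr, n = length(e))
}

#' Scenario-based cross-validation of the four predictors
#'
#' For every scenario x training fraction x fold, the held-out
#' observations are predicted from that fold's training data with each
#' method, and RMSE/BIAS/CORR are recorded. Variogram models are fitted
#' once beforehand (on the full campaign) and reused across folds; the
#' IDW temporal scaling C is tuned once on the full day and frozen.
#' Drift-degenerate KED neighbourhoods fall back to ordinary kriging
#' with a logged flag.
#'
#' @param x The prediction-day calibrated `observation_set`.
#' @param station A `station_series`.
#' @param models Named list of `variogram_model` for `sk`, `ok`, `ked`
#'   (e.g. from [fit_method_models()]).
#' @param methods Methods to evaluate (default all four).
#' @param scenarios Subset of `c("random_points", "path_segments",
#'   "leave_line_out")`.
#' @param fractions Training fractions for the first two scenarios
#'   (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param holdout_routes For leave_line_out: list of character vectors,
#'   one per fold (default: each route held out singly).
#' @param k Folds, i.e. independent seeded re-draws per cell (default 4).
#' @param seed Integer seed controlling every split.
#' @param idw_c IDW temporal scaling; `NULL` (default) tunes it via
#'   [tune_idw_c()].
#' @param n_max Kriging neighbourhood size (default 50).
#' @param segment_mean,segment_sd Path-segment spec, in samples.
#' @return A `cv_report`: data.frame `(method, scenario, fraction, fold,
#'   rmse, bias, corr, n_test, n_fallback)` with the tuned `idw_c`,
#'   `k` and `seed` as attributes.
#' @export
cross_validate <- function(x, station, models,
                           methods = c("sk", "ok", "ked", "idw"),
                           scenarios = c("random_points", "path_segments",
                                         "leave_line_out"),
                           fractions = c(0.2, 0.4, 0.6, 0.8),
                           holdout_routes = NULL,
                           k = 4, seed = 1, idw_c = NULL, n_max = 50,
                           segment_mean = 20, segment_sd = 10) {
  if (k < 2) stop_stkrige("stkrige_invalid_input", "k must be >= 2")
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  if (is.null(idw_c) && "idw" %in% methods) {
    idw_c <- as.numeric(tune_idw_c(x, seed = seed))
    log_event("evaluation", "idw_c_tuned", C = format(idw_c))
  }
  rows <- list()
  for (scenario in scenarios) {
    cells <- if (scenario == "leave_line_out") {
      hr <- holdout_routes %||% as.list(unique(x$obs$route_id))
      data.frame(fraction = NA_real_, fold = seq_along(hr))
    } else {
      expand.grid(fraction = fractions, fold = seq_len(k))
    }
    for (ci in seq_len(nrow(cells))) {
      fold <- cells$fold[ci]; fraction <- cells$fraction[ci]
      sp <- switch(scenario,
        random_points = split_random_points(
          x, fraction, seed = derive_seed(seed, fold * 100L + round(fraction * 10))),
        path_segments = split_path_segments(
          x, fraction, segment_mean, segment_sd,
          seed = derive_seed(seed, fold * 100L + round(fraction * 10) + 50L)),
        leave_line_out = split_leave_line_out(
          x, (holdout_routes %||% as.list(unique(x$obs$route_id)))[[fold]]))
      if (n_obs(sp$test) == 0L) {
        stop_stkrige("stkrige_fold_error", "fold with empty test set")
      }
      targets <- sp$test$obs[, c("x", "y", "t")]
      for (method in methods) {
        pr <- st_predict(sp$train, targets,
                         model = models[[method]] %||% models[["ok"]],
                         method = method, station = station, n_max = n_max,
                         idw_c = idw_c %||% 1, ked_fallback_ok = TRUE)
        m <- compute_metrics(pr$prediction, sp$test$obs$value)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, scenario = scenario, fraction = fraction,
          fold = fold, rmse = m$rmse, bias = m$bias, corr = m$corr,
          n_test = m$n, n_fallback = sum(pr$fallback),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "idw_c") <- idw_c
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Summarise a cross-validation report
#'
#' Fold means per (method, scenario, fraction) and, where IDW was run,
#' the relative RMSE improvement of each kriging method over IDW,
#' `100 * (RMSE_idw - RMSE_method) / RMSE_idw` (percent).
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return Data.frame of fold means with an `improvement_vs_idw` column.
#' @export
summary.cv_report <- function(object, ...) {
  d <- as.data.frame(object)
  key <- interaction(d$method, d$scenario,
                     ifelse(is.na(d$fraction), "-", d$fraction), drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(method = g$method[1], scenario = g$scenario[1],
               fraction = g$fraction[1],
               rmse = mean(g$rmse), bias = mean(g$bias),
               corr = mean(g$corr, na.rm = TRUE),
               n_folds = nrow(g), n_fallback = sum(g$n_fallback),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$improvement_vs_idw <- NA_real_
  for (i in seq_len(nrow(agg))) {
    ref <- agg$rmse[agg$method == "idw" & agg$scenario == agg$scenario[i] &
                      (is.na(agg$fraction) & is.na(agg$fraction[i]) |
                         !is.na(agg$fraction) & !is.na(agg$fraction[i]) &
                         agg$fraction == agg$fraction[i])]
    if (length(ref) == 1L && agg$method[i] != "idw") {
      agg$improvement_vs_idw[i] <- 100 * (ref - agg$rmse[i]) / ref
    }
  }
  agg
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d cells, k = %s, idw C = %s>\n",
              nrow(x), attr(x, "k"), format(attr(x, "idw_c"))))
  print(summary(x), digits = 4)
  invisible(x)
}

#' Write a cross-validation report and its summary to CSV
#'
#' @param report A `cv_report`.
#' @param path Per-fold CSV path; the fold-mean summary goes to
#'   `sub(".csv", "_summary.csv", path)`.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  utils::write.csv(summary(report), sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  invisible(path)
}
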