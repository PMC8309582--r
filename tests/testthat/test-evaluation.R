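# Train/test scenarios, performance indicators, cross-validation report.

test_that("random-point splits: sizes, determinism, partition", {
  o <- random_obs(100, seed = 1)
  sp <- split_random_points(o, 0.8, seed = 4)
  expect_equal(n_obs(sp$train), 80)
  expect_equal(n_obs(sp$test), 20)
  sp2 <- split_random_points(o, 0.8, seed = 4)
  expect_identical(sp$idx, sp2$idx)
  expect_false(identical(sp$idx, split_random_points(o, 0.8, seed = 5)$idx))
  for (s in 1:50) {
    spl <- split_random_points(o, stats::runif(1, 0.1, 0.9), seed = s)
    key <- function(os) paste(os$obs$sensor_id, os$obs$t)
    expect_length(intersect(key(spl$train), key(spl$test)), 0)
    expect_setequal(c(key(spl$train), key(spl$test)), key(o))
  }
  expect_error(split_random_points(o, 0), class = "stkrige_split_error")
  expect_error(split_random_points(o, 1.2), class = "stkrige_split_error")
})

test_that("path-segment splits hold out contiguous single-sensor runs", {
  camp <- small_campaign()
  day <- campaign_day(camp$truth, 1)
  n <- n_obs(day)
  sp <- split_path_segments(day, 0.75, segment_mean = 12, segment_sd = 5, seed = 2)
  expect_lte(abs(n_obs(sp$test) - round(0.25 * n)), 1)
  expect_equal(n_obs(sp$train) + n_obs(sp$test), n)
  # contiguity: within each sensor, every held-out observation's
  # predecessor or successor is held out too (or it is a run of length >= 1
  # bounded by train/boundary on both sides only for single-sample runs)
  d <- day$obs
  key <- paste(d$sensor_id, d$t)
  test_key <- paste(sp$test$obs$sensor_id, sp$test$obs$t)
  in_test <- key %in% test_key
  runs <- split(in_test, d$sensor_id)
  run_lengths <- unlist(lapply(runs, function(v) {
    r <- rle(v); r$lengths[r$values]
  }))
  expect_gt(mean(run_lengths > 1), 0.5)   # held-out data comes in runs

  # hand-checked small case: one sensor, n = 10, one run of length 3
  o <- obs_set(1:10, 0, (1:10) * 60, (1:10) + 100)
  sp2 <- split_path_segments(o, 0.7, segment_mean = 3, segment_sd = 0, seed = 7)
  expect_equal(n_obs(sp2$test), 3)
  expect_equal(diff(sp2$test$obs$t), c(60, 60))       # contiguous
  expect_equal(n_obs(sp2$train), 7)
  expect_equal(sp2$train$obs$t, sort(sp2$train$obs$t)) # original order kept
  expect_error(split_path_segments(o, 0.5, segment_mean = 99),
               class = "stkrige_spec_error")
})

test_that("leave-line-out splits partition by route", {
  camp <- small_campaign()
  day <- campaign_day(camp$truth, 1)
  routes <- unique(day$obs$route_id)
  sp <- split_leave_line_out(day, routes[1])
  expect_setequal(unique(sp$test$obs$route_id), routes[1])
  expect_false(routes[1] %in% sp$train$obs$route_id)
  expect_equal(n_obs(sp$train) + n_obs(sp$test), n_obs(day))
  # equal-sized routes: one route is ~ 1/3 of the day (identical clocks differ
  # by start offsets, so allow a couple of samples)
  expect_lt(abs(n_obs(sp$test) - n_obs(day) / 3), 3)
  expect_error(split_leave_line_out(day, "no-such-route"),
               class = "stkrige_lookup_error")
  expect_error(split_leave_line_out(day, routes), class = "stkrige_split_error")
})

test_that("performance indicators match hand computations", {
  truth <- c(3, 7, 11, 2)
  m <- compute_metrics(truth, truth)
  expect_equal(unlist(m[c("rmse", "bias", "corr")]),
               c(rmse = 0, bias = 0, corr = 1))
  m2 <- compute_metrics(truth + 2, truth)
  expect_equal(unlist(m2[c("rmse", "bias", "corr")]),
               c(rmse = 2, bias = 2, corr = 1))
  m3 <- compute_metrics(c(1, 3), c(0, 4))
  expect_equal(unlist(m3[c("rmse", "bias", "corr")]),
               c(rmse = 1, bias = 0, corr = 1))
  expect_true(is.na(compute_metrics(c(5, 5), c(1, 2))$corr))
  expect_error(compute_metrics(1:3, 1:4), class = "stkrige_invalid_input")
  # rmse^2 = bias^2 + population variance of errors
  set.seed(20)
  for (i in 1:10) {
    p <- stats::rnorm(40); z <- stats::rnorm(40)
    mm <- compute_metrics(p, z)
    e <- p - z
    expect_equal(mm$rmse^2, mm$bias^2 + mean((e - mean(e))^2), tolerance = 1e-10)
    expect_gte(mm$rmse, abs(mm$bias))
  }
})

test_that("cross-validation report: fold means, determinism, improvement algebra", {
  camp <- small_campaign()
  obs <- campaign_day(camp$truth, 1)
  models <- list(sk = camp$field$model, ok = camp$field$model,
                 ked = camp$field$model)
  rep1 <- suppressMessages(cross_validate(
    obs, camp$station, models, methods = c("ok", "idw"),
    scenarios = c("random_points", "leave_line_out"),
    fractions = 0.7, k = 2, seed = 3, idw_c = 100, n_max = 25))
  rep2 <- suppressMessages(cross_validate(
    obs, camp$station, models, methods = c("ok", "idw"),
    scenarios = c("random_points", "leave_line_out"),
    fractions = 0.7, k = 2, seed = 3, idw_c = 100, n_max = 25))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  s <- summary(rep1)
  # fold means recompute
  d <- as.data.frame(rep1)
  for (i in seq_len(nrow(s))) {
    rows <- d$method == s$method[i] & d$scenario == s$scenario[i] &
      (is.na(d$fraction) == is.na(s$fraction[i])) &
      (is.na(d$fraction) | d$fraction %in% s$fraction[i])
    expect_equal(s$rmse[i], mean(d$rmse[rows]), tolerance = 1e-12)
  }
  # improvement identity vs the idw reference
  for (i in which(s$method != "idw")) {
    ref <- s$rmse[s$method == "idw" & s$scenario == s$scenario[i]]
    expect_equal(s$improvement_vs_idw[i], 100 * (ref - s$rmse[i]) / ref,
                 tolerance = 1e-10)
  }
  # a perfect method would show 100% improvement over any imperfect one
  fake <- compute_metrics(obs$obs$value, obs$obs$value)
  expect_equal(100 * (s$rmse[1] - fake$rmse) / s$rmse[1], 100)
})

test_that("cv report round-trips through its CSV export", {
  camp <- small_campaign()
  obs <- campaign_day(camp$truth, 1)
  models <- list(ok = camp$field$model)
  rep <- suppressMessages(cross_validate(
    obs, camp$station, models, methods = c("ok", "idw"),
    scenarios = "random_points", fractions = 0.8, k = 2, seed = 1,
    idw_c = 50, n_max = 15))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(rep, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", f)))
  back <- utils::read.csv(f)
  expect_equal(back$rmse, rep$rmse, tolerance = 1e-10)
})

test_that("held-out path segments are harder than held-out random points", {
  mk <- function(seed) {
    routes <- list(
      route_spec("A", rbind(c(-1500, -800), c(1500, 400)),
                 sampling_interval = 60, start_offset = 0),
      route_spec("B", rbind(c(-900, 1200), c(700, -1300)),
                 sampling_interval = 60, start_offset = 20),
      route_spec("C", rbind(c(-1600, 300), c(1600, 500)),
                 sampling_interval = 60, start_offset = 0))
    suppressWarnings(suppressMessages(
      simulate_campaign(routes = routes, n_days = 2, day_start = 8,
                        day_hours = 6, seed = seed)))
  }
  res <- sapply(1:10, function(s) {
    camp <- mk(900 + s)
    day <- campaign_day(camp$truth, 1)
    rep <- suppressMessages(cross_validate(
      day, camp$station, list(ok = camp$field$model), methods = "ok",
      scenarios = c("random_points", "path_segments"), fractions = 0.75,
      k = 2, seed = s, idw_c = 1, segment_mean = 12, segment_sd = 5))
    d <- as.data.frame(rep)
    c(random = mean(d$rmse[d$scenario == "random_points"]),
      path = mean(d$rmse[d$scenario == "path_segments"]))
  })
  # interpolation between scattered points beats extrapolation into
  # contiguous gaps, in median over 10 campaigns
  expect_lte(stats::median(res["random", ]), stats::median(res["path", ]))
})
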