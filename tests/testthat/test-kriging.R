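# Neighbour selection, the three kriging systems, and IDW.

test_that("neighbour selection: saturation, tie-breaks, brute-force kNN", {
  o <- random_obs(100, seed = 3)
  tg <- list(x = 0, y = 0, t = 3000)
  expect_length(select_neighbors(o, tg, n_max = 500, K = 10), 100)
  # brute-force k-nearest oracle
  d <- o$obs
  dist <- sqrt((d$x - tg$x)^2 + (d$y - tg$y)^2 + (10 * (d$t - tg$t))^2)
  for (k in c(1, 10, 33)) {
    got <- select_neighbors(o, tg, n_max = k, K = 10)
    expect_setequal(got, order(dist)[seq_len(k)])
    expect_equal(dist[got], sort(dist)[seq_len(k)])
  }
  # ties broken by earlier time
  tie <- obs_set(c(-100, 100), c(0, 0), c(500, 40), c(1, 2))
  got <- select_neighbors(tie, list(x = 0, y = 0, t = 0), n_max = 2, K = 0.0001)
  expect_equal(tie$obs$t[got[1]], 40)
  # radius cutoff
  expect_error(select_neighbors(o, tg, n_max = 5, K = 10, radius = 1e-6),
               class = "stkrige_empty_neighborhood")
})

test_that("simple kriging: exactness, mean reversion, and the covariance system", {
  st <- linear_station()
  m <- variogram_model("exponential", 40, 0, 5000, 50)
  nb <- data.frame(sensor_id = "a", x = 10, y = 20, t = 5000, value = 33)
  tg <- list(x = 10, y = 20, t = 5000)
  sol <- krige_sk(nb, st, m, tg)
  expect_equal(sol$weights, 1, tolerance = 1e-8)
  expect_equal(sol$prediction, 33, tolerance = 1e-8)
  expect_lt(sol$variance, 1e-6)
  # far target: weights vanish, prediction reverts to F(t), variance to the sill
  far <- list(x = 1e7, y = 0, t = 5000)
  sol2 <- krige_sk(nb, st, m, far)
  expect_lt(max(abs(sol2$weights)), 1e-6)
  expect_equal(sol2$prediction, station_value(st, 5000), tolerance = 1e-4)
  expect_equal(sol2$variance, total_sill(m), tolerance = 1e-4)
})

test_that("ordinary kriging: constraint, symmetry, one-point case", {
  m <- variogram_model("spherical", 30, 2, 4000, 80)
  one <- data.frame(sensor_id = "a", x = 5, y = 5, t = 100, value = 12)
  sol <- krige_ok(one, m, list(x = 900, y = 0, t = 300))
  expect_equal(sol$weights, 1, tolerance = 1e-12)
  expect_equal(sol$prediction, 12)
  # two neighbours symmetric about the target
  two <- data.frame(sensor_id = c("a", "b"), x = c(-500, 500), y = 0,
                    t = c(50, 50), value = c(10, 20))
  sol2 <- krige_ok(two, m, list(x = 0, y = 0, t = 50))
  expect_equal(sol2$weights, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(sol2$prediction, 15, tolerance = 1e-10)
  expect_equal(sum(sol2$weights), 1, tolerance = 1e-12)
})

test_that("KED: drift degeneracy, exactness under a linear-in-F field", {
  m <- variogram_model("exponential", 25, 0, 3000, 60)
  flat <- station_series(c(0, 50000), c(15, 15))   # constant F(t)
  nb <- data.frame(sensor_id = "a", x = c(0, 100, 300), y = c(0, 50, 10),
                   t = c(100, 300, 800), value = c(1, 2, 3))
  expect_error(krige_ked(nb, flat, m, list(x = 0, y = 0, t = 100)),
               class = "stkrige_drift_degenerate")
  expect_error(krige_ked(nb[1, ], linear_station(), m, list(x = 0, y = 0, t = 100)),
               class = "stkrige_insufficient_data")
  # field exactly alpha + beta * F(t): prediction at a datum reproduces it
  st <- linear_station()
  t <- c(1000, 6000, 15000, 23000, 39000)
  nb2 <- data.frame(sensor_id = "a", x = c(0, 800, -300, 400, -900),
                    y = c(100, -200, 500, 0, 300), t = t,
                    value = 4 + 1.5 * station_value(st, t))
  tg <- list(x = nb2$x[3], y = nb2$y[3], t = nb2$t[3])
  sol <- krige_ked(nb2, st, m, tg)
  expect_equal(sol$prediction, nb2$value[3], tolerance = 1e-8)
  # unbiasedness constraints
  Fd <- cbind(1, station_value(st, nb2$t))
  expect_equal(drop(t(Fd) %*% sol$weights),
               c(1, station_value(st, tg$t)), tolerance = 1e-8)
})

test_that("all three kriging systems match generic dense solves (random instances)", {
  for (s in 1:30) {
    inst <- random_instance(s)
    tol <- 1e-8 * max(1, total_sill(inst$model))
    got_ok <- krige_ok(inst$nb, inst$model, inst$tg)
    ref_ok <- oracle_ok(inst$nb, inst$model, inst$tg)
    expect_equal(got_ok$weights, ref_ok$weights, tolerance = tol)
    expect_equal(got_ok$prediction, ref_ok$prediction, tolerance = tol)
    expect_equal(sum(got_ok$weights), 1, tolerance = 1e-10)

    got_sk <- krige_sk(inst$nb, inst$station, inst$model, inst$tg)
    ref_sk <- oracle_sk(inst$nb, inst$station, inst$model, inst$tg)
    expect_equal(got_sk$weights, ref_sk$weights, tolerance = tol)
    expect_equal(got_sk$prediction, ref_sk$prediction, tolerance = tol)

    got_kd <- krige_ked(inst$nb, inst$station, inst$model, inst$tg)
    ref_kd <- oracle_ked(inst$nb, inst$station, inst$model, inst$tg)
    expect_equal(got_kd$weights, ref_kd$weights, tolerance = tol)
    expect_equal(got_kd$prediction, ref_kd$prediction, tolerance = tol)
  }
})

test_that("nugget-free kriging is exact; a positive nugget smooths", {
  st <- linear_station()
  set.seed(8)
  nb <- data.frame(sensor_id = "a", x = stats::rnorm(8, 0, 500),
                   y = stats::rnorm(8, 0, 500),
                   t = stats::runif(8, 1000, 30000),
                   value = stats::rnorm(8, 40, 6))
  tg <- list(x = nb$x[4], y = nb$y[4], t = nb$t[4])
  m0 <- variogram_model("spherical", 30, 0, 3000, 40)
  for (fn in list(function() krige_sk(nb, st, m0, tg),
                  function() krige_ok(nb, m0, tg),
                  function() krige_ked(nb, st, m0, tg))) {
    sol <- fn()
    expect_equal(sol$prediction, nb$value[4], tolerance = 1e-8)
    expect_lt(sol$variance, 1e-8 * total_sill(m0))
  }
  m1 <- variogram_model("spherical", 30, 6, 3000, 40)
  for (fn in list(function() krige_sk(nb, st, m1, tg),
                  function() krige_ok(nb, m1, tg),
                  function() krige_ked(nb, st, m1, tg))) {
    expect_gt(abs(fn()$prediction - nb$value[4]), 1e-6)
  }
})

test_that("translation invariance and the OK >= SK variance ordering", {
  st <- linear_station()
  m <- variogram_model("exponential", 35, 3, 6000, 70)
  set.seed(12)
  nb <- data.frame(sensor_id = "a", x = stats::rnorm(10, 0, 800),
                   y = stats::rnorm(10, 0, 800),
                   t = stats::runif(10, 1000, 40000),
                   value = stats::rnorm(10, 30, 5))
  tg <- list(x = 120, y = -60, t = 21000)
  nb_c <- nb; nb_c$value <- nb$value + 7
  ok1 <- krige_ok(nb, m, tg); ok2 <- krige_ok(nb_c, m, tg)
  expect_equal(ok2$prediction - ok1$prediction, 7, tolerance = 1e-9)
  idw1 <- idw_predict(nb, tg, C = 100); idw2 <- idw_predict(nb_c, tg, C = 100)
  expect_equal(idw2 - idw1, 7, tolerance = 1e-12)
  sk1 <- krige_sk(nb, st, m, tg); sk2 <- krige_sk(nb_c, st, m, tg)
  expect_equal(sk2$prediction - sk1$prediction, 7 * sum(sk1$weights),
               tolerance = 1e-9)
  # same model, same data: the extra OK constraint cannot reduce variance
  expect_gte(krige_ok(nb, m, tg)$variance + 1e-10, sk1$variance)
})

test_that("IDW: closed forms, exact hits, temporal invariance at C = 0", {
  nb <- data.frame(sensor_id = c("a", "b"), x = c(1, 2), y = 0, t = c(5, 9),
                   value = c(10, 40))
  tg <- list(x = 0, y = 0, t = 5)
  # distances 1 and 2 at C = 0, p = 2: weights 0.8 / 0.2
  expect_equal(idw_predict(nb, tg, C = 0, p = 2), 16)
  # equidistant points: the plain mean
  nb2 <- data.frame(sensor_id = letters[1:4], x = c(1, -1, 0, 0),
                    y = c(0, 0, 1, -1), t = 1:4, value = c(5, 10, 15, 20))
  expect_equal(idw_predict(nb2, list(x = 0, y = 0, t = 0), C = 0), 12.5)
  # exact hit returns the observation
  nb3 <- rbind(nb, data.frame(sensor_id = "c", x = 0, y = 0, t = 5, value = 99))
  expect_equal(idw_predict(nb3, tg, C = 1), 99)
  # C = 0 ignores time entirely
  nb4 <- nb; nb4$t <- nb$t + 12345
  expect_equal(idw_predict(nb, tg, C = 0), idw_predict(nb4, tg, C = 0))
  # weights are permutation-equivariant
  perm <- nb2[c(3, 1, 4, 2), ]
  expect_equal(idw_predict(perm, list(x = 0.3, y = 0.2, t = 1), C = 2, p = 3),
               idw_predict(nb2, list(x = 0.3, y = 0.2, t = 1), C = 2, p = 3))
})

test_that("IDW C tuning: degenerate grid, temporal field, ties", {
  camp <- small_campaign()
  day <- campaign_day(camp$truth, 1)
  expect_equal(as.numeric(tune_idw_c(day, grid = 42, folds = 2)), 42)
  # purely temporal values: a temporal term in the distance must win
  st <- linear_station()
  set.seed(4)
  tt <- stats::runif(400, 0, 40000)
  o <- obs_set(stats::runif(400, -500, 500), stats::runif(400, -500, 500),
               tt, station_value(st, tt))
  expect_gt(as.numeric(tune_idw_c(o, grid = c(0, 25), folds = 4, seed = 2)), 0)
  # exact ties break toward the smaller C: duplicate candidates tie trivially
  got <- tune_idw_c(day, grid = c(3, 3), folds = 2, seed = 1)
  expect_equal(as.numeric(got), 3)
  expect_error(tune_idw_c(day, grid = numeric(0)), class = "stkrige_invalid_input")
})

test_that("batch prediction is consistent with the per-point solvers", {
  camp <- small_campaign()
  obs <- campaign_day(camp$truth, 1)
  m <- camp$field$model
  targets <- data.frame(x = c(0, 500), y = c(0, -200),
                        t = 1.25 * 86400 + c(3600, 7200))
  for (method in c("sk", "ok", "ked")) {
    got <- st_predict(obs, targets, m, method, camp$station, n_max = 20)
    for (i in 1:2) {
      tg <- list(x = targets$x[i], y = targets$y[i], t = targets$t[i])
      nb <- obs$obs[select_neighbors(obs, tg, 20, m$K), ]
      ref <- switch(method, sk = krige_sk(nb, camp$station, m, tg),
                    ok = krige_ok(nb, m, tg),
                    ked = krige_ked(nb, camp$station, m, tg))
      expect_equal(got$prediction[i], ref$prediction, tolerance = 1e-10)
      expect_equal(got$variance[i], ref$variance, tolerance = 1e-10)
    }
  }
  idw <- st_predict(obs, targets, method = "idw", idw_c = 50)
  expect_true(all(is.na(idw$variance)))
  # station-span guard for the station-backed methods
  late <- data.frame(x = 0, y = 0, t = max(camp$station$times) + 10)
  expect_error(st_predict(obs, late, m, "sk", camp$station),
               class = "stkrige_extrapolation")
})

test_that("a drift-degenerate KED neighbourhood falls back to OK only when allowed", {
  camp <- small_campaign()
  obs <- campaign_day(camp$truth, 1)
  m <- camp$field$model
  flat <- station_series(c(0, 3 * 86400), c(20, 20))   # constant reference
  targets <- data.frame(x = 0, y = 0, t = 86400 + 10 * 3600)
  expect_error(
    st_predict(obs, targets, m, "ked", flat, n_max = 10),
    class = "stkrige_drift_degenerate")
  got <- suppressMessages(
    st_predict(obs, targets, m, "ked", flat, n_max = 10, ked_fallback_ok = TRUE))
  expect_true(got$fallback)
  ref <- st_predict(obs, targets, m, "ok", n_max = 10)
  expect_equal(got$prediction, ref$prediction, tolerance = 1e-12)
})
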