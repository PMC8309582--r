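# Empirical variography, model evaluation, and metric-model fitting.

test_that("tiny cases: two observations, constant field", {
  o <- obs_set(c(0, 300), c(0, 0), c(0, 60), c(4, 8))
  emp <- empirical_variogram(o, n_spatial_bins = 1, n_temporal_bins = 1,
                             max_spatial_lag = 1000, max_temporal_lag = 600)
  expect_equal(emp$gamma[1, 1], 8)         # (4 - 8)^2 / 2
  expect_equal(emp$counts[1, 1], 1)
  expect_equal(emp$mean_h[1, 1], 300)
  expect_equal(emp$mean_u[1, 1], 60)

  const <- obs_set(1:20, (1:20)^1.3, stats::runif(20, 0, 500), rep(5, 20))
  empc <- empirical_variogram(const, max_spatial_lag = 100, max_temporal_lag = 600)
  expect_true(all(empc$gamma[empc$counts > 0] == 0))
  expect_error(
    empirical_variogram(obs_set(c(0, 1e6), c(0, 0), c(0, 1e6), c(1, 2)),
                        max_spatial_lag = 10, max_temporal_lag = 10),
    class = "stkrige_empty_variogram")
})

test_that("binned surface equals the O(n^2) brute-force oracle (n = 300)", {
  o <- random_obs(300, seed = 13)
  hmax <- 2500; umax <- 3000
  emp <- empirical_variogram(o, n_spatial_bins = 7, n_temporal_bins = 5,
                             max_spatial_lag = hmax, max_temporal_lag = umax)
  bf <- bf_variogram(o$obs, emp$s_edges, emp$u_edges, hmax, umax)
  expect_identical(emp$counts, bf$counts)
  expect_equal(emp$gamma[bf$counts > 0],
               (bf$sums / bf$counts)[bf$counts > 0], tolerance = 1e-12)
  # directional surfaces against the same oracle, and the 45-degree partition
  ns <- empirical_variogram(o, 7, 5, hmax, umax, direction = "ns")
  ew <- empirical_variogram(o, 7, 5, hmax, umax, direction = "ew")
  bf_ns <- bf_variogram(o$obs, emp$s_edges, emp$u_edges, hmax, umax, "ns")
  bf_ew <- bf_variogram(o$obs, emp$s_edges, emp$u_edges, hmax, umax, "ew")
  expect_identical(ns$counts, bf_ns$counts)
  expect_identical(ew$counts, bf_ew$counts)
  expect_identical(ns$counts + ew$counts, emp$counts)
})

test_that("auto spatial cutoff is half the maximum pairwise distance", {
  o <- obs_set(c(0, 100, 4000), c(0, 0, 3000), c(0, 10, 20), c(1, 2, 3))
  emp <- empirical_variogram(o, max_temporal_lag = 100)
  expect_equal(emp$max_spatial_lag, 2500)  # max distance 5000 (3-4-5 triangle)
})

test_that("model evaluation: origin, families, published-fit-scale parameters, symmetry", {
  models <- list(
    variogram_model("spherical", 82.30, 5.00, 30415.43, 105.16),
    variogram_model("exponential", 59.86, 2.00, 9872.405, 83.03),
    variogram_model("bounded_linear", 148.8, 5.00, 38073.4, 91.18)
  )
  for (m in models) {
    expect_identical(st_semivariance(m, 0, 0), 0)
    # at/beyond the range every bounded family reaches nugget + sill
    expect_equal(st_semivariance(m, m$range * 1.5, 0), m$nugget + m$sill,
                 tolerance = if (m$family == "exponential") 0.02 else 1e-12)
    # metric space-time exchange: h = K * u0 <-> u = u0
    u0 <- 120
    expect_equal(st_semivariance(m, m$K * u0, 0), st_semivariance(m, 0, u0))
    # nondecreasing in each lag
    g_h <- st_semivariance(m, seq(0, 2 * m$range, length.out = 80), 100)
    g_u <- st_semivariance(m, rep(500, 80),
                           seq(0, 2 * m$range / m$K, length.out = 80))
    expect_true(all(diff(g_h) > -1e-9))
    expect_true(all(diff(g_u) > -1e-9))
  }
  m <- models[[1]]
  expect_equal(st_semivariance(m, m$range, 0), 87.30, tolerance = 1e-10)
  expect_error(st_semivariance(m, -1, 0), class = "stkrige_invalid_input")
  expect_error(variogram_model("spherical", -1, 0, 10, 1),
               class = "stkrige_invalid_input")
})

test_that("covariance form is consistent with the variogram", {
  m <- variogram_model("exponential", 40, 5, 8000, 90)
  d <- c(0, 10, 500, 8000, 1e5)
  expect_equal(stkrige:::cov_metric(m, d)[1], 45)
  expect_equal(stkrige:::cov_metric(m, d) + stkrige:::gamma_metric(m, d),
               rep(45, 5))
})

test_that("fitting recovers a noiseless surface and respects bounds", {
  truth <- variogram_model("exponential", 50, 4, 9000, 110)
  s_edges <- seq(0, 3000, length.out = 11)
  u_edges <- seq(0, 600, length.out = 11)
  hc <- (s_edges[-1] + s_edges[-11]) / 2
  uc <- (u_edges[-1] + u_edges[-11]) / 2
  emp <- structure(list(
    s_edges = s_edges, u_edges = u_edges,
    gamma = outer(hc, uc, function(h, u) st_semivariance(truth, h, u)),
    counts = matrix(10, 10, 10),
    mean_h = matrix(hc, 10, 10), mean_u = matrix(uc, 10, 10, byrow = TRUE),
    max_spatial_lag = 3000, max_temporal_lag = 600,
    n_obs = 100, value_var = 100), class = "empirical_variogram")
  fit <- fit_variogram(emp, "exponential", seed = 2)
  expect_lt(abs(fit$model$sill - 50) / 50, 1e-3)
  expect_lt(abs(fit$model$range - 9000) / 9000, 1e-3)
  expect_lt(abs(fit$model$K - 110) / 110, 1e-3)
  expect_lt(abs(fit$model$nugget - 4) / 4, 0.02)
  expect_lt(fit$objective, 1e-6)

  # feasibility: parameters inside the default box, best over all starts
  b <- stkrige:::.fit_bounds(emp, NULL)
  cf <- coef(fit)
  for (p in names(b)) {
    expect_gte(cf[[p]], b[[p]][1]); expect_lte(cf[[p]], b[[p]][2])
  }
  expect_lte(fit$objective, min(fit$starts$objective, na.rm = TRUE) + 1e-12)
  # too few bins to identify four parameters
  emp2 <- emp; emp2$gamma[] <- NA; emp2$gamma[1, 1:3] <- 1
  expect_error(fit_variogram(emp2), class = "stkrige_insufficient_data")
})

test_that("directional variograms: geometry and isotropy echo", {
  # all pairs on a due-north transect: the east-west cone is empty
  o <- obs_set(rep(0, 10), seq(0, 900, by = 100), seq(0, 90, by = 10), 1:10)
  expect_error(
    empirical_variogram(o, 3, 3, 1000, 100, direction = "ew", tolerance = 30),
    class = "stkrige_empty_variogram")
  ns <- empirical_variogram(o, 3, 3, 1000, 100, direction = "ns", tolerance = 30)
  expect_gt(sum(ns$counts), 0)

  # isotropic field: the two 45-degree cones see statistically equal surfaces
  reldiff <- sapply(1:6, function(s) {
    set.seed(s)
    f <- field_spec(base = 0, amplitude = 0,
                    model = variogram_model("exponential", 30, 0, 1500, 50))
    pts <- data.frame(x = stats::runif(350, -2000, 2000),
                      y = stats::runif(350, -2000, 2000),
                      t = stats::runif(350, 0, 600))
    o <- obs_set(pts$x, pts$y, pts$t, simulate_field(pts, f, seed = s))
    dd <- directional_variograms(o, n_spatial_bins = 3, n_temporal_bins = 2,
                                 max_spatial_lag = 2000, max_temporal_lag = 600)
    both <- dd$ns$counts > 5 & dd$ew$counts > 5
    stats::median(abs(dd$ns$gamma[both] - dd$ew$gamma[both]) /
                    ((dd$ns$gamma[both] + dd$ew$gamma[both]) / 2))
  })
  expect_lt(stats::median(reldiff), 0.3)
})

test_that("residual and raw variograms agree in the near-zero temporal margin", {
  camp <- small_campaign()
  resid <- station_residuals(camp$truth, camp$station)
  e_raw <- empirical_variogram(camp$truth, n_spatial_bins = 6,
                               n_temporal_bins = 8, max_temporal_lag = 240)
  e_res <- empirical_variogram(resid, n_spatial_bins = 6,
                               n_temporal_bins = 8, max_temporal_lag = 240)
  first <- e_raw$counts[, 1] > 20 & e_res$counts[, 1] > 20
  expect_gt(sum(first), 1)
  rel <- abs(e_raw$gamma[first, 1] - e_res$gamma[first, 1]) /
    e_raw$gamma[first, 1]
  expect_lt(stats::median(rel), 0.25)
})

test_that("temporal cutoff helper finds the sill onset on synthetic data", {
  camp <- small_campaign()
  cut <- suppressWarnings(
    suggest_temporal_cutoff(station_residuals(camp$truth, camp$station),
                            step = 120, max_limit = 1800))
  expect_true(cut > 120 && cut <= 1800)
})

test_that("exact duplicate points are deduplicated defensively", {
  d <- data.frame(sensor_id = c("a", "b", "c"), x = c(0, 0, 100),
                  y = 0, t = c(10, 10, 20), value = c(5, 5, 9),
                  calibrated = TRUE)
  o <- observation_set(d)
  expect_message(
    emp <- empirical_variogram(o, 2, 2, 200, 60), class = "stkrige_log")
  expect_equal(sum(emp$counts), 1)   # only the (a|b)-c pair remains
})
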