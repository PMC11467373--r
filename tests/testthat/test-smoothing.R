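# Regular-grid construction, cubic smoothing splines and the local-level
# Kalman smoother.

test_that("regularisation assigns observations to nearest grid slots", {
  s <- gl_series(c(0, 2, 4), c(-90, -91, -92))
  r <- regularize_series(s, 2)
  expect_equal(r$times, c(0, 2, 4))
  expect_equal(r$values, s$values)

  s2 <- gl_series(c(0, 2, 7), c(-90, -91, -92))
  r2 <- regularize_series(s2, 2)
  expect_equal(r2$times, c(0, 2, 4, 6))
  expect_equal(r2$values, c(-90, -91, NA, -92))  # obs at 7 -> slot 6

  # collision keeps the strongest RSS
  s3 <- gl_series(c(0, 0.4), c(-90, -85))
  r3 <- regularize_series(s3, 2)
  expect_equal(r3$values[1], -85)
  # ... or the first value for coordinates
  r3f <- regularize_series(s3, 2, collision = "first")
  expect_equal(r3f$values[1], -90)

  r0 <- regularize_series(gl_series(numeric(0), numeric(0)), 2)
  expect_equal(length(r0$values), 0)
})

test_that("spline smoothing honours the 5-point fallback and fits exact lines", {
  const <- gl_series(0:4, rep(-90, 5))
  sm <- smooth_spline_series(const)
  expect_equal(sm$values, const$values, tolerance = 1e-6)

  short <- gl_series(0:3, c(-90, -88, -91, -89))
  out <- smooth_spline_series(short)
  expect_identical(out$values, short$values)
  expect_false(out$smoothed)

  line <- gl_series(seq(0, 18, by = 2), 2 * seq(0, 18, by = 2))
  sml <- smooth_spline_series(line)
  expect_lt(max(abs(sml$values - line$values)), 1e-3)
  expect_true(sml$smoothed)
})

test_that("local-level ML recovers the variance regime of simulated series", {
  set.seed(101)
  # white noise: constant level, obs sd 1 -> level variance ~ 0
  wn <- gl_series(0:199, rnorm(200, 0, 1), regular = TRUE, step = 1)
  f_wn <- fit_local_level_ml(wn)
  expect_true(f_wn$fitted)
  expect_lt(f_wn$sigma2_level / f_wn$sigma2_obs, 0.05)

  # pure random walk: obs noise ~ 0
  rw <- gl_series(0:199, cumsum(rnorm(200, 0, 1)), regular = TRUE, step = 1)
  f_rw <- fit_local_level_ml(rw)
  expect_lt(f_rw$sigma2_obs / f_rw$sigma2_level, 0.05)

  # two equal values: finite loglik, no crash
  f2 <- fit_local_level_ml(gl_series(0:1, c(-90, -90), TRUE, 1))
  expect_true(is.finite(f2$loglik))
})

test_that("local-level loglik agrees with StructTS on a clean series", {
  set.seed(7)
  y <- cumsum(rnorm(120, 0, 0.7)) + rnorm(120, 0, 1.3)
  s <- gl_series(seq_along(y) - 1, y, TRUE, 1)
  fit <- fit_local_level_ml(s)
  ref <- stats::StructTS(y, type = "level")
  # same model, same data: ML variances should agree closely
  expect_equal(fit$sigma2_level, unname(ref$coef["level"]), tolerance = 0.1)
  expect_equal(fit$sigma2_obs, unname(ref$coef["epsilon"]), tolerance = 0.1)
})

test_that("kalman smoothing is exact in the noiseless limit and helps under the model", {
  y <- c(-90, -85, -88, -92, -87)
  s <- gl_series(0:4, y, TRUE, 1)
  sm <- smooth_kalman_series(s, list(sigma2_level = 1, sigma2_obs = 1e-12,
                                     fitted = TRUE))
  expect_equal(sm$values, y, tolerance = 1e-4)

  const <- gl_series(0:9, rep(-90, 10), TRUE, 1)
  smc <- smooth_kalman_series(const, fit_local_level_ml(const))
  expect_equal(smc$values, const$values, tolerance = 1e-6)

  # simulated local-level series: smoother beats raw observations
  set.seed(202)
  level <- cumsum(rnorm(200, 0, 0.5))
  obs <- level + rnorm(200, 0, 2)
  so <- gl_series(0:199, obs, TRUE, 1)
  smo <- smooth_kalman_series(so, fit_local_level_ml(so))
  rmse_raw <- sqrt(mean((obs - level)^2))
  rmse_sm <- sqrt(mean((smo$values - level)^2))
  expect_lt(rmse_sm, rmse_raw)
})

test_that("kalman path fills missing slots and maps back to observation times", {
  set.seed(9)
  t_irr <- sort(sample(0:60, 25))
  y <- sin(t_irr / 10) * 5 - 90 + rnorm(25, 0, 0.5)
  s <- gl_series(t_irr, y)
  out <- smooth_series(s, "kalman", step = 2)
  expect_equal(out$times, s$times)
  expect_equal(length(out$values), length(y))
  expect_true(all(is.finite(out$values)))

  # below the 2-point threshold the series passes through bit-identical
  s1 <- gl_series(3, -95)
  expect_identical(smooth_series(s1, "kalman", step = 2)$values, s1$values)
})
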