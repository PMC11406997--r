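# Hill induction fits, steady-state windows, rolling regression,
# Gompertz growth fits and the derived performance metrics.

test_that("steady-state Fss averages the window correctly", {
  t <- seq(0, 24, by = 0.5)
  expect_equal(steady_state_fss(t, rep(100, length(t))), 100)
  # linear ramp v(t) = t on a symmetric grid over [6, 12] averages to 9
  expect_equal(steady_state_fss(t, t, c(6, 12)), 9)
  expect_error(steady_state_fss(t, t, c(30, 40)), "window")
})

test_that("noiseless Hill data are recovered to machine precision", {
  x <- rep(c(0, 2^(0:6)), each = 3)
  y <- hill_response(x, beta = 1000, K = 10, n = 2, C = 50)
  fit <- fit_hill(induction_curve("aTc", x, y))
  expect_true(fit$converged)
  expect_lt(abs(fit$beta / 1000 - 1), 1e-6)
  expect_lt(abs(fit$K / 10 - 1), 1e-6)
  expect_lt(abs(fit$n / 2 - 1), 1e-6)
  expect_equal(fit$C, 50)   # C is empirical, not fitted
  expect_equal(hill_response(0, 1000, 10, 2, 50), 50)
})

test_that("Hill fit is equivariant under fluorescence rescaling", {
  set.seed(43)
  x <- rep(c(0, 2^(0:6)), each = 4)
  y <- hill_response(x, 800, 4, 1.5, 60) * ln_noise(length(x), 0.03)
  f1 <- fit_hill(induction_curve("Ara", x, y))
  f2 <- fit_hill(induction_curve("Ara", x, 1000 * y))
  expect_equal(f2$K, f1$K, tolerance = 1e-6)
  expect_equal(f2$n, f1$n, tolerance = 1e-6)
  expect_equal(f2$beta, 1000 * f1$beta, tolerance = 1e-6)
  expect_equal(f2$C, 1000 * f1$C)
  expect_equal(f2$DR, f1$DR, tolerance = 1e-6)
})

test_that("noisy Hill fits recover K within the expected error band", {
  set.seed(47)
  x <- rep(c(0, 2^(0:6)), each = 8)
  kerr <- vapply(1:100, function(i) {
    y <- hill_response(x, 1000, 10, 2, 50) * ln_noise(length(x), 0.05)
    abs(fit_hill(induction_curve("aTc", x, y))$K / 10 - 1)
  }, numeric(1))
  expect_lte(median(kerr), 0.15)
})

test_that("dynamic range follows beta over empirical C", {
  expect_equal(dynamic_range(list(beta = 1375, C = 100)), 13.75)
  expect_equal(dynamic_range(list(beta = 100, C = 100)), 1)
  expect_equal(dynamic_range(list(beta = 0, C = 100)), 0)
  expect_warning(dr <- dynamic_range(list(beta = 10, C = 0)), "undefined")
  expect_true(is.na(dr))
})

test_that("rolling regression finds exponential and constant rates", {
  t <- seq(0, 10, by = 0.1)
  r <- rolling_max_rate(t, 0.05 * exp(0.6 * t))
  expect_lt(abs(r$mu - 0.6), 1e-9)
  expect_true(r$ok)
  rc <- rolling_max_rate(t, rep(5, length(t)))
  expect_equal(rc$mu, 0)
  expect_error(rolling_max_rate(t[1:3], rep(1, 3), h = 5), "fewer points")
})

test_that("rolling regression recovers mu from a log-Gompertz curve", {
  t <- seq(0, 24, by = 0.05)
  v <- exp(gompertz_response(t, A = 1, mu = 0.5, lambda = 2))
  r <- rolling_max_rate(t, v)
  expect_lt(abs(r$mu / 0.5 - 1), 0.05)
})

test_that("noiseless Gompertz curves are recovered to 1e-4 relative", {
  t <- seq(0, 24, by = 1 / 6)
  y <- gompertz_response(t, A = 1.2, mu = 0.4, lambda = 3, y0 = 0.05)
  fit <- fit_gompertz_lag(t, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$A / 1.2 - 1), 1e-4)
  expect_lt(abs(fit$mu / 0.4 - 1), 1e-4)
  expect_lt(abs(fit$lambda / 3 - 1), 1e-4)
})

test_that("a zero-lag curve fits lambda near the boundary", {
  t <- seq(0, 24, by = 1 / 6)
  set.seed(53)
  y <- gompertz_response(t, 1.2, 0.4, 0, 0.05) * ln_noise(length(t), 0.02)
  fit <- fit_gompertz_lag(t, y)
  expect_lt(abs(fit$lambda), 0.1)
})

test_that("noisy Gompertz fits recover mu within the error band", {
  t <- seq(0, 24, by = 1 / 6)
  set.seed(59)
  merr <- vapply(1:100, function(i) {
    y <- gompertz_response(t, 1.2, 0.4, 3, 0.05) * ln_noise(length(t), 0.02)
    abs(fit_gompertz_lag(t, y)$mu / 0.4 - 1)
  }, numeric(1))
  expect_lte(median(merr), 0.1)
})

test_that("rolling rate agrees with the fitted Gompertz mu", {
  # internal consistency on a curve whose log is the fitted model
  t <- seq(0, 24, by = 0.1)
  lcurve <- gompertz_response(t, A = 2.5, mu = 0.45, lambda = 2.5)
  fit <- fit_gompertz_lag(t, lcurve)
  roll <- rolling_max_rate(t, exp(lcurve))
  expect_lt(abs(roll$mu / fit$mu - 1), 0.05)
})

test_that("delta_mu implements the relative percentage change", {
  expect_equal(delta_mu(0.5, 0.5), 0)
  expect_equal(delta_mu(1, 0.5), 50)
  expect_equal(delta_mu(0.6, 0.75), -25)
  expect_error(delta_mu(0, 1), "positive")
})

test_that("specific dynamic range is a baseline-relative fold", {
  expect_equal(specific_dynamic_range(100, 100), 1)
  expect_equal(specific_dynamic_range(400, 100), 4)
  expect_lt(specific_dynamic_range(60, 100), 1)
  expect_warning(v <- specific_dynamic_range(10, 0), "undefined")
  expect_true(is.na(v))
})

test_that("toggle metrics carry DR_S of 1 for the NI state", {
  cfg <- small_config(seed = 61)
  cp <- plant_concordance(cfg)
  curves <- simulate_curves(cfg, cp$hill_params, cp$gompertz_params)
  tm <- toggle_metrics(curves$fluorescence)
  ni <- tm[tm$condition == "NI", ]
  expect_true(all(abs(ni$DR_S - 1) < 1e-12))
  # induced sfGFP under Ara exceeds its NI baseline
  ara <- tm[tm$condition == "Ara" & tm$channel == "sfGFP", ]
  expect_true(all(ara$DR_S > 1))
})

test_that("performance matrix panels expose the documented metrics", {
  cfg <- small_config(seed = 67)
  cp <- plant_concordance(cfg)
  curves <- simulate_curves(cfg, cp$hill_params, cp$gompertz_params)
  rep_panel <- performance_matrix(curves$induction, curves$growth)
  ord_panel <- performance_matrix(curves$induction, curves$growth,
                                  panel = "ordination")
  expect_true(all(c("logDR_Ara", "lambda_NI", "logmu_aTc") %in%
                    colnames(rep_panel)))
  expect_equal(colnames(ord_panel),
               c("logK_Ara", "logbeta_Ara", "logn_Ara", "logC_Ara",
                 "logK_aTc", "logbeta_aTc", "logn_aTc", "logC_aTc",
                 "logmu_NI", "logA_NI", "loglambda_NI"))
  expect_equal(rownames(ord_panel), paste0("G", 1:6))
})
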