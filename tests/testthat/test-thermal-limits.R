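test_that("internal-temperature closed form agrees with numerical ODE
           integration across the parameter grid", {
  for (r in c(0.05, 0.1, 0.2)) {
    for (k in c(0.01, 0.1, 1, 10)) {
      for (t_el in c(1, 30, 120, 300)) {
        start <- 20
        w <- start + r * t_el
        # closed form via the exported function (mass chosen so that
        # lag_k0 * mass^0 = k)
        tb <- internal_temp_at_loe(w, start, r, mass = 1,
                                   lag_k0 = k, lag_gamma = 0)
        ode <- deSolve::ode(
          y = c(Tb = start), times = seq(0, t_el, length.out = 201),
          func = function(t, y, p) list(p$k * (start + p$r * t - y)),
          parms = list(k = k, r = r), method = "ode45",
          atol = 1e-10, rtol = 1e-10)
        expect_lt(abs(tb - ode[nrow(ode), "Tb"]), 1e-6)
      }
    }
  }
})

test_that("no-lag limit, cooling symmetry and mass monotonicity", {
  w <- internal_temp_at_loe(39.5, 35.5, 0.1, mass = 1, lag_k0 = 1e8,
                            lag_gamma = 0)
  expect_lt(abs(w - 39.5), 1e-6)
  # steady-state overshoot r/k on a long heating ramp
  tb <- internal_temp_at_loe(32, 20, 0.1, mass = 1, lag_k0 = 0.2,
                             lag_gamma = 0)
  expect_equal(32 - tb, 0.5 * (1 - exp(-0.2 * 120)), tolerance = 1e-12)
  # cooling ramp: lag is added
  tbmin <- internal_temp_at_loe(10, 22, 0.1, mass = 1, lag_k0 = 0.2,
                                lag_gamma = 0)
  expect_gt(tbmin, 10)
  # heavier fish lag more when lag_gamma > 0
  lag1 <- 32 - internal_temp_at_loe(32, 20, 0.1, mass = 2, lag_k0 = 1.2,
                                    lag_gamma = 0.33)
  lag2 <- 32 - internal_temp_at_loe(32, 20, 0.1, mass = 4, lag_k0 = 1.2,
                                    lag_gamma = 0.33)
  expect_gt(lag2, lag1)
  expect_error(internal_temp_at_loe(32, 20, -0.1, 1), "positive")
})

test_that("env_extremes: constants, analytic sinusoid extremes and phase
           invariance", {
  const <- sinusoid_sst(mean = 27, amplitude = 0, years = 2)
  e <- env_extremes(const)
  expect_equal(e$mean_annual_max, 27)
  expect_equal(e$mean_annual_min, 27)

  s <- sinusoid_sst(mean = 27.25, amplitude = 9.25, years = 3)
  e2 <- env_extremes(s)
  expect_equal(e2$mean_annual_max, 36.5, tolerance = 1e-2)
  expect_equal(e2$mean_annual_min, 18.0, tolerance = 1e-2)

  # phase shift leaves noiseless extremes unchanged (seasonal windows
  # relaxed so the shifted peak still falls inside them)
  s2 <- sinusoid_sst(mean = 27.25, amplitude = 9.25, years = 3, phase = 100)
  e3 <- env_extremes(s2, summer_months = 1:12, winter_months = 1:12)
  expect_equal(e3$mean_annual_max, e2$mean_annual_max, tolerance = 1e-2)
  expect_equal(e3$mean_annual_min, e2$mean_annual_min, tolerance = 1e-2)

  expect_error(env_extremes(const, window = as.Date(c("2030-01-01",
                                                      "2030-02-01"))),
               "no observations")
})

test_that("partial trailing years contribute only the season they cover", {
  # truncated at end of October: summer covered, winter (Jan-Mar) covered
  s <- sinusoid_sst(years = 10, end_date = "2019-10-31")
  e <- env_extremes(s)
  expect_true(all(e$by_year$use_max))
  expect_true(all(e$by_year$use_min))
  # truncated mid-February: 2019 covers neither season fully
  s2 <- sinusoid_sst(years = 10, end_date = "2019-02-15")
  e2 <- env_extremes(s2)
  expect_false(e2$by_year$use_max[e2$by_year$year == 2019])
  expect_false(e2$by_year$use_min[e2$by_year$year == 2019])
})

test_that("annual_stats drops short years and reports medians/ranges", {
  s <- sinusoid_sst(mean = 27, amplitude = 5, years = 2)
  a <- annual_stats(s)
  expect_equal(a$range, rep(10, 2), tolerance = 1e-2)
  short <- sinusoid_sst(years = 2, end_date = "2011-03-01")
  expect_warning(a2 <- annual_stats(short), "dropped")
  expect_equal(a2$year, 2010)
})

test_that("hot and mild SST presets keep their configured range ordering", {
  cfg <- synthetic_config(sst = c(mean = 27, amplitude = 9.25,
                                  noise_sd = 0.3, years = 5))
  ag <- annual_stats(generate_sst(cfg, seed = 7, preset = "ag"))
  go <- annual_stats(generate_sst(cfg, seed = 7, preset = "go"))
  expect_true(all(ag$range > go$range))
  expect_equal(mean(ag$range), 18.5, tolerance = 0.15)
  expect_equal(mean(go$range), 11.0, tolerance = 0.15)
})

test_that("thermal safety margins: definition, fixtures and monotonicity", {
  expect_equal(thermal_safety_margin(36.5, 36.5, "summer"), 0,
               ignore_attr = TRUE)
  # winter margin from a printed winter limit and a back-computed extreme
  expect_equal(thermal_safety_margin(8.65, 19.23, "winter"), 10.58,
               ignore_attr = TRUE)
  # summer margin falls as the environmental maximum rises, rises with CTmax
  m1 <- thermal_safety_margin(39.5, 36.5, "summer")
  expect_lt(thermal_safety_margin(39.5, 37.0, "summer"), m1)
  expect_gt(thermal_safety_margin(40.0, 36.5, "summer"), m1)
  # winter mirror image
  w1 <- thermal_safety_margin(8.65, 19.23, "winter")
  expect_gt(thermal_safety_margin(8.65, 20.0, "winter"), w1)
  expect_lt(thermal_safety_margin(9.5, 19.23, "winter"), w1)
  expect_true(attr(thermal_safety_margin(36.0, 36.5, "summer"),
                   "flag_negative"))
  expect_error(thermal_safety_margin(36, 36, "spring"))
})

test_that("ct_limits annotates trials and records the lag coefficients", {
  trials <- data.frame(water_temp_at_loe = c(39.6, 8.2),
                       start_temp = c(35.5, 18), ramp_rate = 0.1,
                       mass = c(1.4, 1.4))
  out <- ct_limits(trials, lag_k0 = 1.2, lag_gamma = 0.33)
  expect_true(all(c("critical_limit", "internal_temp_at_loe") %in%
                    names(out)))
  expect_lt(out$critical_limit[1], 39.6)   # heating: body cooler
  expect_gt(out$critical_limit[2], 8.2)    # cooling: body warmer
  expect_equal(attr(out, "lag_coefficients")[["lag_k0"]], 1.2)
})

test_that("the seasonal polynomial is a faithful descriptive smooth", {
  s <- sinusoid_sst(mean = 27.25, amplitude = 9.25, years = 5)
  fit <- fit_seasonal_polynomial(s)
  expect_gt(fit$r2, 0.9)
  expect_equal(fit$predict(227), 36.5, tolerance = 0.5)
})
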