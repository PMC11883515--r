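test_that("segment_cycles honours labels, schedules and the minimum-size
           rule", {
  # 100 labelled 10-min cycles, 1 sample every 30 s
  t <- seq(0, 999.5, by = 0.5)
  phase <- ifelse(t %% 10 < 4, "measure", "flush")
  tr <- data.frame(time_min = t, o2_mg_per_l = 6.8, phase = phase)
  w <- segment_cycles(tr)
  expect_length(w, 100)
  expect_equal(attr(w[[2]], "cycle_start_time"), 10)

  # degenerate single-sample measure window is dropped with a warning
  tr2 <- tr
  tr2$phase[tr2$time_min >= 10 & tr2$time_min < 14][-1] <- "flush"
  expect_warning(w2 <- segment_cycles(tr2), "dropped")
  expect_length(w2, 99)

  # unlabelled trace + schedule: windows at [0,4), [10,14), ...
  tr3 <- data.frame(time_min = t, o2_mg_per_l = 6.8)
  w3 <- segment_cycles(tr3, schedule = c(total = 10, measure = 4))
  expect_length(w3, 100)
  expect_equal(vapply(w3[1:3], attr, numeric(1), "cycle_start_time"),
               c(0, 10, 20))
  expect_equal(max(w3[[1]]$time_min), 3.5)

  expect_error(segment_cycles(tr3), "schedule")
  tr4 <- data.frame(time_min = t, o2_mg_per_l = 6.8, phase = "flush")
  expect_error(segment_cycles(tr4), "no measurement windows")
})

test_that("fit_slope matches closed-form OLS and handles degenerate
           windows", {
  w <- data.frame(time_min = 0:10, o2_mg_per_l = 6.8 - 0.01 * (0:10))
  f <- fit_slope(w)
  expect_equal(f$slope, -0.01)
  expect_equal(f$r2, 1)

  wc <- data.frame(time_min = 0:10, o2_mg_per_l = rep(6.8, 11))
  fc <- fit_slope(wc)
  expect_equal(fc$slope, 0)
  expect_true(is.na(fc$r2))

  set.seed(3)
  wn <- data.frame(time_min = 0:20,
                   o2_mg_per_l = 6.8 - 0.01 * (0:20) + rnorm(21, 0, 0.005))
  fn <- fit_slope(wn)
  ols <- lm(o2_mg_per_l ~ time_min, data = wn)
  expect_equal(fn$slope, unname(coef(ols)[2]), tolerance = 1e-12)
  se <- summary(ols)$coefficients[2, 2]
  expect_lt(abs(fn$slope - (-0.01)), 2 * se)

  expect_error(fit_slope(w[1, ]), "2 samples")
})

test_that("compute_mo2 arithmetic, sign convention and volume guard", {
  expect_equal(compute_mo2(0, 1.2, 32.4), 0)
  expect_equal(compute_mo2(-0.01, 1.2, 32.4),
               0.01 * (1.2 - 0.0324) * 60 / 0.0324, tolerance = 1e-12)
  expect_equal(round(compute_mo2(-0.01, 1.2, 32.4), 3), 21.622)
  expect_lt(compute_mo2(0.01, 1.2, 32.4), 0)  # positive slope: negative mo2
  expect_error(compute_mo2(-0.01, 0.175, 200), "exceeds")
  expect_error(compute_mo2(-0.01, 1.2, -5), "positive")
})

test_that("estimate_mmr takes the first cycle, not the maximum", {
  expect_equal(estimate_mmr(make_series(c(500, 400, 300))), 500)
  expect_equal(estimate_mmr(make_series(c(400, 500, 300))), 400)
  expect_equal(estimate_mmr(make_series(c(400, 500, 300)), use_max = TRUE),
               500)
  expect_error(estimate_mmr(make_series(numeric(0))), "empty")
})

test_that("estimate_smr is the low quantile after the exclusion window", {
  expect_equal(estimate_smr(make_series(rep(100, 30))), 100)
  # 1..20 fixture: h = (20-1)*0.2 + 1 = 4.8 -> 4.8
  expect_equal(estimate_smr(make_series(1:20)), 4.8)
  expect_equal(estimate_smr(make_series(1:20), q = 0.5), 10.5)
  # mean-of-lowest-20% alternative
  expect_equal(estimate_smr(make_series(1:20), method = "mean_lowest"),
               mean(1:4))

  # trace only 4 h long: everything excluded
  short <- make_series(1:20, start_times = seq(0, by = 10, length.out = 20))
  expect_error(estimate_smr(short), "cycles remain")

  # half-open boundary: a cycle starting exactly at 300 min is included
  s <- make_series(c(999, 1:19),
                   start_times = c(300, seq(310, by = 10, length.out = 19)))
  incl <- estimate_smr(s)
  s2 <- make_series(c(999, 1:19),
                    start_times = c(299.9, seq(310, by = 10,
                                               length.out = 19)))
  excl <- estimate_smr(s2, min_cycles = 19)
  expect_false(isTRUE(all.equal(incl, excl)))
  expect_equal(excl, quantile_oracle(1:19, 0.2))
})

test_that("estimate_smr equals the sort-and-interpolate oracle and is
           monotone", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    x <- rlnorm(n, 5, 0.3)
    s <- make_series(x)
    expect_equal(estimate_smr(s), quantile_oracle(x, 0.2),
                 tolerance = 1e-12)
  }
  # adding a cycle above the current percentile never decreases SMR
  x <- rlnorm(30, 5, 0.3)
  base <- estimate_smr(make_series(x))
  expect_gte(estimate_smr(make_series(c(x, base + 10))), base)
  # raising q never decreases SMR
  expect_gte(estimate_smr(make_series(x), q = 0.4), base)
})

test_that("background correction and aerobic scope identities", {
  c0 <- correct_background(500, 100, 0, 0, 1.2, 32.4)
  expect_equal(c0$mmr_corrected, 500)
  expect_equal(c0$smr_corrected, 100)

  # post-trial background equivalent to 10 mass-specific units
  slope10 <- -10 * (32.4 / 1000) / (1.2 * 60)
  c1 <- correct_background(500, 110, 0, slope10, 1.2, 32.4)
  expect_equal(c1$smr_corrected, 100, tolerance = 1e-12)

  expect_equal(aerobic_scope(500, 100), 400, ignore_attr = TRUE)
  expect_equal(aerobic_scope(100, 100), 0, ignore_attr = TRUE)
  expect_true(attr(aerobic_scope(90, 100), "flag_negative"))
})

test_that("background correction reduces bias on drifting-background
           traces", {
  cfg <- synthetic_config(o2_noise_sd = 0, trait_cv = 0, epoc_tau = 30,
                          duration_h = 10)
  tr <- generate_o2_trace(cfg, fish_mass = 1.4, temp = 27)
  truth <- attr(tr, "truth")
  series <- extract_mo2_series(tr, cfg$chamber_volume, 1.4)
  smr_raw <- estimate_smr(series)
  mmr_raw <- estimate_mmr(series)
  corr <- correct_background(mmr_raw, smr_raw,
                             cfg$background_slope_pre,
                             cfg$background_slope_post,
                             cfg$chamber_volume, 1.4)
  expect_lt(abs(corr$smr_corrected - truth$smr_true),
            abs(smr_raw - truth$smr_true))
  expect_lt(abs(corr$mmr_corrected - truth$mmr_true),
            abs(mmr_raw - truth$mmr_true))
})

test_that("the aerobic scope identity holds exactly on extracted traits", {
  cfg <- noiseless_cfg(acclimation_temps = c(22, 31.5),
                       n_fish_per_cell = 2, duration_h = 8)
  co <- generate_cohort(cfg, seed = 9, traces = TRUE)
  tt <- extract_traits_cohort(co)
  expect_equal(tt$aerobic_scope, tt$mmr_corrected - tt$smr_corrected)
  expect_equal(tt$aerobic_scope, tt$as_true, tolerance = 1e-5)
})
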