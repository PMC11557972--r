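test_that("a pure cosine is recovered exactly on the grid", {
  t <- 0:119
  y <- 40 + 20 * cos(2 * pi * (t - 18) / 24)
  fit <- estimate_period(y, hours = t)
  expect_equal(fit$tau, 24.0)
  expect_equal(fit$phase, 18, tolerance = 1e-6)
  expect_equal(fit$amplitude, 20, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["mesor"]), 40, tolerance = 1e-6)
  expect_false(fit$arrhythmic)
  # model-object surface
  expect_equal(predict(fit, hours = 18), 60, tolerance = 1e-6)
  expect_equal(unname(residuals(fit)), rep(0, 120), tolerance = 1e-6)
})

test_that("a constant series is flagged arrhythmic, not an error", {
  fit <- estimate_period(rep(30, 120), hours = 0:119)
  expect_true(fit$arrhythmic)
  expect_equal(fit$amplitude, 0)
  expect_true(is.na(fit$tau))
  expect_equal(predict(fit, hours = 0:5), rep(30, 6))
})

test_that("short series and missing hours are rejected", {
  expect_error(estimate_period(rnorm(30), hours = 0:29), "two full cycles")
  expect_error(estimate_period(rnorm(120)), "hours")
})

test_that("time translation changes phase but never period or amplitude", {
  t <- 0:119
  y <- 35 + 15 * cos(2 * pi * (t - 6) / 23.5)
  f0 <- estimate_period(y, hours = t)
  f5 <- estimate_period(y, hours = t + 5)
  expect_equal(f5$tau, f0$tau)
  expect_equal(f5$amplitude, f0$amplitude, tolerance = 1e-8)
  expect_equal((f0$phase + 5) %% f0$tau, f5$phase, tolerance = 1e-6)
})

test_that("noisy 25.5 h rhythms are recovered within half an hour", {
  t <- 0:119
  errs_pkg <- errs_oracle <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    p <- 0.35 + 0.25 * cos(2 * pi * (t - 18) / 25.5)
    y <- 100 * rbinom(length(t), 23, p) / 23
    errs_pkg[s] <- estimate_period(y, hours = t)$tau - 25.5
    errs_oracle[s] <- oracle_period_scan(t, y) - 25.5
  }
  expect_lt(median(abs(errs_pkg)), 0.5)
  # the coarse-grid estimate agrees with the dense brute-force scan
  expect_lt(median(abs(errs_pkg - errs_oracle)), 0.1)
})

test_that("pair differences follow the control-minus-condition convention", {
  h <- 0:119
  a <- make_series(h, rep(40, 120), "LL", 1)
  b <- make_series(h, rep(40, 120), "LD", 1)
  expect_equal(pair_difference(a, b)$delta, rep(0, 120))

  b10 <- make_series(h, rep(50, 120), "LD", 1)
  expect_equal(pair_difference(a, b10)$delta, rep(10, 120))

  expect_error(pair_difference(a, make_series(h, rep(40, 120), "LD", 2)),
               "replicate")
  expect_error(pair_difference(a, make_series(h + 1, rep(40, 120), "LD", 1)),
               "grids")
})

test_that("window AUC matches closed forms and dominates the signed area", {
  h <- 0:119
  unit <- data.frame(hour = h, delta = rep(1, 120))
  expect_equal(window_auc(unit, c(72, 96)), 23.0)

  sine <- data.frame(hour = 0:24, delta = sin(2 * pi * (0:24) / 24))
  expect_equal(window_auc(sine, c(0, 24.5)), 0, tolerance = 1e-10)
  expect_gt(window_auc(sine, c(0, 24.5), absolute = TRUE), 10)

  set.seed(9)
  for (i in 1:10) {
    curve <- data.frame(hour = h, delta = rnorm(120, sd = 5))
    expect_gte(window_auc(curve, c(72, 96), absolute = TRUE) + 1e-12,
               abs(window_auc(curve, c(72, 96))))
  }
  expect_error(window_auc(unit, c(200, 210)), "fewer than 2")
})

test_that("midpoint peak finds symmetric pulses and flags flat windows", {
  h <- 0:119
  tri <- pmax(0, 8 - abs(h - 84))
  expect_equal(midpoint_peak(make_series(h, tri), c(72, 96)), 84)
  expect_true(is.na(midpoint_peak(make_series(h, rep(5, 120)), c(72, 96))))
})

test_that("peak distance is symmetric, zero at identity, exact under shifts", {
  h <- 0:119
  y <- 35 + 25 * cos(2 * pi * (h - 84) / 24)
  a <- make_series(h, y, "LL", 1)
  b <- make_series(h, 35 + 25 * cos(2 * pi * (h - 86) / 24), "LD", 1)
  expect_equal(peak_distance(a, a), 0)
  expect_equal(peak_distance(a, b), 2)
  expect_equal(peak_distance(a, b), peak_distance(b, a))
  flat <- make_series(h, rep(1, 120), "LD", 1)
  expect_warning(d <- peak_distance(a, flat), "undefined peak")
  expect_true(is.na(d))
})

test_that("day-4 peak divergence matches the closed-form phase bookkeeping", {
  # LL at tau = 25 h vs LD at 24 h, noiseless mean curves with acrophase 12:
  # day-4 peaks sit at 12 + 3*25 = 87 h vs 12 + 3*24 = 84 h, both with their
  # half-max runs fully inside the [72, 96) window.
  h <- 0:119
  ll <- 100 * oracle_prop_asleep(h, "DD", 0.35, 0.25, 0, 12, tau = 25)
  ld <- 100 * oracle_prop_asleep(h, "LD", 0.35, 0.25, 0, 12, tau = 24)
  d <- peak_distance(make_series(h, ll, "LL", 1), make_series(h, ld, "LD", 1))
  expect_lt(abs(d - 3), 1)
})

test_that("alignment table pairs every LL/DD cage with its LD control", {
  series <- to_sleep_series(simulate_experiment(sim_config(seed = 8)))
  al <- align_to_control(series)
  expect_equal(nrow(al), 6)
  expect_equal(sort(unique(al$condition)), c("DD", "LL"))
  expect_true(all(al$abs_auc_day4 >= abs(al$auc_day4) - 1e-9))
  expect_true(all(al$peak_distance <= 12, na.rm = TRUE))
})
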