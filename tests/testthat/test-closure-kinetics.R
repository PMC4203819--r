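test_that("crossing times interpolate linearly and flag unreachable levels", {
  tr <- make_closure_trace(0:9, c(10, 20, 30, 40, 48, 52, 60, 70, 80, 90))
  expect_equal(crossing_time(tr, 50), 4.5)          # between 48 and 52
  expect_equal(crossing_time(tr, 30), 2)            # exact sample
  plateau <- make_closure_trace(0:9, c(5, 10, 20, 30, 38, 40, 40, 40, 40, 40))
  expect_error(crossing_time(plateau, 50), "never reaches")
})

test_that("alignment shifts the midpoint to zero and is idempotent", {
  tr <- make_closure_trace(0:9, c(10, 20, 30, 40, 48, 52, 60, 70, 80, 90))
  al <- align_traces(list(tr))[[1]]
  expect_equal(al$time_min, tr$time_min - 4.5)
  expect_equal(crossing_time(al, 50), 0, tolerance = 1e-12)
  expect_identical(align_traces(align_traces(list(tr, tr))),
                   align_traces(list(tr, tr)))
})

test_that("speed series handles linear, constant and logistic closure", {
  lin <- make_closure_trace(seq(0, 10, 0.5), 10 * seq(0, 10, 0.5))
  for (w in c(1, 3, 5))
    expect_equal(speed_series(lin, w)$speed_pct_per_min,
                 rep(10, nrow(lin)), tolerance = 1e-10)

  flat <- make_closure_trace(0:9, rep(40, 10))
  expect_equal(speed_series(flat)$speed_pct_per_min, rep(0, 10))

  # logistic derivative peaks at 25 k %/min at the midpoint
  logi <- logistic_trace(k = 0.5, t0 = 10, dt = 0.5, span = c(2, 98))
  ss <- speed_series(logi, smooth_window = 1)
  i <- which.max(ss$speed_pct_per_min)
  expect_lt(abs(ss$time_min[i] - 10), 0.5 + 1e-9)
  expect_lt(abs(ss$speed_pct_per_min[i] - 12.5) / 12.5, 0.03)

  expect_error(speed_series(lin, smooth_window = 4), "odd")
  expect_error(speed_series(make_closure_trace(0:4, 1:5 * 10), 7), "exceeds")
})

test_that("20-80% average speed matches linear truth and the dense OLS oracle", {
  lin <- make_closure_trace(seq(0, 10, 0.5), 10 * seq(0, 10, 0.5))
  res <- average_speed_20_80(lin)
  expect_equal(res$speed, 10, tolerance = 1e-9)
  expect_equal(res$endpoint_speed, 10, tolerance = 1e-9)

  logi <- logistic_trace(k = 0.5, t0 = 10, dt = 0.05)
  oracle <- logistic_ols_slope_oracle(k = 0.5)
  expect_lt(abs(oracle - 11.45), 0.1)   # sanity on the oracle itself
  expect_lt(abs(average_speed_20_80(logi)$speed - oracle) / oracle, 0.02)
  # the OLS slope exceeds the endpoint average 30 k / log(4)
  expect_gt(average_speed_20_80(logi)$speed,
            average_speed_20_80(logi)$endpoint_speed)

  # doubling k doubles the slope
  s1 <- average_speed_20_80(logistic_trace(0.5, 10, 0.05))$speed
  s2 <- average_speed_20_80(logistic_trace(1.0, 10, 0.05))$speed
  expect_lt(abs(s2 / s1 - 2), 0.02 * 2)

  low <- make_closure_trace(0:9, seq(2, 15, length.out = 10))
  expect_error(average_speed_20_80(low), "never reaches")
})

test_that("peak speed finds the sigmoid maximum near 50% closure", {
  logi <- logistic_trace(k = 0.72, t0 = 5, dt = 0.01)
  pk <- peak_speed(logi, smooth_window = 3)
  expect_lt(abs(pk$speed - 18) / 18, 0.03)          # 25 k = 18 for k = 0.72
  expect_lt(abs(pk$closure_at_peak - 50), 5)

  # symmetric sigmoids of any rate peak at 50% closure
  for (k in c(0.3, 0.6, 1.2)) {
    pk <- peak_speed(logistic_trace(k, 8, 0.1), smooth_window = 3)
    expect_lt(abs(pk$closure_at_peak - 50), 100 * 0.1 * 25 * k / 100 + 1)
  }

  # exactly linear closure: tied maxima resolve to the middle frame
  lin <- make_closure_trace(seq(0, 10, 0.5), 10 * seq(0, 10, 0.5))
  pk <- peak_speed(lin)
  expect_equal(pk$speed, 10, tolerance = 1e-10)
  expect_equal(pk$closure_at_peak, 50, tolerance = 1e-9)
})

test_that("kinetics summary bundles the read-outs consistently", {
  lin <- make_closure_trace(seq(0, 10, 0.5), 10 * seq(0, 10, 0.5), id = "lin")
  sm <- kinetics_summary(lin)
  expect_equal(sm$t_mid_min, 5)
  expect_equal(sm$avg_speed_20_80, 10, tolerance = 1e-9)
  expect_equal(sm$peak_speed, 10, tolerance = 1e-10)
  expect_equal(sm$duration_10_90_min, 8)

  logi <- logistic_trace(k = 0.5, t0 = 10, dt = 0.5)
  expect_lt(abs(kinetics_summary(logi)$t_mid_min - 10), 0.5)

  # reversed closure: constructor rejects decreasing times, and a falling
  # closure series trips the monotonicity guard
  expect_error(ring_trace(rev(seq(0, 10, 0.5)), 10 * seq(0, 10, 0.5)),
               "strictly increasing")
  falling <- make_closure_trace(seq(0, 10, 0.5), rev(10 * seq(0, 10, 0.5)))
  expect_error(kinetics_summary(falling), "non-monotone")
})

test_that("average speed is translation invariant and scale equivariant in time", {
  logi <- logistic_trace(k = 0.5, t0 = 10, dt = 0.1)
  base <- average_speed_20_80(logi)$speed
  shifted <- make_closure_trace(logi$time_min + 7.3, logi$closure_pct)
  expect_equal(average_speed_20_80(shifted)$speed, base, tolerance = 1e-9)
  squeezed <- make_closure_trace(logi$time_min / 3, logi$closure_pct)
  expect_equal(average_speed_20_80(squeezed)$speed, 3 * base,
               tolerance = 1e-9)
})

test_that("the speed integral over the 20-80% window is 60 points", {
  logi <- logistic_trace(k = 0.5, t0 = 10, dt = 0.01)
  ss <- speed_series(logi, smooth_window = 1)
  t20 <- crossing_time(logi, 20)
  t80 <- crossing_time(logi, 80)
  sel <- ss$time_min >= t20 & ss$time_min <= t80
  tt <- ss$time_min[sel]; vv <- ss$speed_pct_per_min[sel]
  integral <- sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
  expect_lt(abs(integral - 60) / 60, 0.01)
})

test_that("sigmoid traces accelerate before the midpoint and decelerate after", {
  for (k in c(0.3, 0.72, 1.5)) {
    logi <- logistic_trace(k, 6, 0.25)
    ss <- speed_series(logi, smooth_window = 1)
    before <- ss$speed_pct_per_min[ss$time_min < 6 - 0.25]
    after <- ss$speed_pct_per_min[ss$time_min > 6 + 0.25]
    expect_true(all(diff(before) > 0))
    expect_true(all(diff(after) < 0))
  }
})

test_that("population averaging reports mean, SEM and trace counts", {
  tr <- make_closure_trace(0:9, c(10, 20, 30, 40, 48, 52, 60, 70, 80, 90))
  pc <- population_average(list(tr, tr, tr), "closure", grid_dt = 0.5)
  expect_true(all(pc$sem == 0))
  expect_true(all(pc$n == 3))
  on_grid <- pc[abs((pc$grid + 4.5) %% 1) < 1e-9, ]  # aligned sample times
  expect_equal(stats::approx(tr$time_min - 4.5, tr$closure_pct,
                             xout = on_grid$grid)$y,
               on_grid$mean)

  # two constant asymmetry traces at 40 and 60
  t1 <- make_closure_trace(0:9, seq(5, 95, 10), asymmetry = 40)
  t2 <- make_closure_trace(0:9, seq(5, 95, 10), asymmetry = 60)
  pa <- population_average(list(t1, t2), "asymmetry", grid_dc = 2)
  expect_true(all(abs(pa$mean - 50) < 1e-9))
  # sample sd of {40, 60} is sqrt(200); SEM = sd / sqrt(2) = 10
  expect_true(all(abs(pa$sem - 10) < 1e-9))
  expect_error(population_average(list(), "closure"), "at least one")
})

test_that("the population mean curve covers the generating logistic", {
  set.seed(5)
  sigma <- 2
  # pointwise, |mean - truth| <= 2 SEM holds with the t_49 probability
  # P(|t_49| <= 2) ~ 0.949; check that the empirical two-SEM coverage over
  # replicate populations is calibrated to that level
  coverage <- replicate(20, {
    # sample where the curve stays clear of the [0, 100] bounds, as
    # annotated traces do; clipping at the bounds would bias tail means
    traces <- lapply(1:50, function(i) {
      tt <- seq(4.5, 15.5, 0.5)
      cc <- pmin(pmax(logistic_closure(tt, 0.5, 10) +
                        rnorm(length(tt), 0, sigma), 0), 100)
      make_closure_trace(tt, cc, id = paste0("n", i))
    })
    # traces share one time base, so average without midpoint alignment
    # (alignment pins every trace to 50% at t = 0, deflating the SEM there)
    pc <- population_average(traces, "closure", grid_dt = 0.5,
                             align = FALSE)
    ok <- pc$n == 50
    truth <- logistic_closure(pc$grid, 0.5, 10)
    mean((abs(pc$mean - truth) <= 2 * pc$sem)[ok])
  })
  expect_gt(mean(coverage), 0.91)
  expect_lt(mean(coverage), 0.98)
})

test_that("asymmetry at a closure level interpolates the drift model", {
  conc <- make_closure_trace(0:9, seq(5, 95, 10), asymmetry = 0)
  expect_equal(asymmetry_at_closure(conc, 50), 0)

  drift <- quantify_trace(simulate_trace(
    closure_model(alpha = 0.6, jitter_sigma_um = 0)))
  expect_equal(asymmetry_at_closure(drift, 80), 48, tolerance = 1e-6)

  short <- make_closure_trace(0:9, seq(5, 68, length.out = 10))
  expect_error(asymmetry_at_closure(short, 80), "never reaches")
})

test_that("least-squares logistic fits recover k and t0 from noisy traces", {
  set.seed(9)
  ks <- t0s <- rep(NA_real_, 20)
  for (i in 1:20) {
    tt <- seq(2, 18, 0.5)
    cc <- pmin(pmax(logistic_closure(tt, 0.5, 10) + rnorm(length(tt), 0, 2),
                    0), 100)
    f <- fit_logistic(make_closure_trace(tt, cc))
    ks[i] <- f$k; t0s[i] <- f$t0
  }
  expect_lt(abs(mean(ks) - 0.5) / 0.5, 0.05)
  expect_lt(abs(mean(t0s) - 10) / 10, 0.05)
})
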