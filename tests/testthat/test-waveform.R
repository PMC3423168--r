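test_that("parameter validation reports the violated invariant", {
  ok <- issf_params(0.5, 1.5, 12, 24, 1, 0)
  expect_s3_class(validate_params(ok), "issf_params")
  expect_identical(validate_params(ok), ok)

  expect_error(issf_params(cycle_period = 0), "cycle_period")
  expect_error(issf_params(ramp_duration = -1), "ramp_duration")
  expect_error(issf_params(pulse_duration = 23, cycle_period = 24,
                           ramp_duration = 2), "cycle_period")
  expect_error(issf_params(pulse_duration = 1, ramp_duration = 2),
               "plateau")
  expect_error(issf_params(offset = NA), "finite")
})

test_that("hand-evaluated waveform values match on all regimes", {
  # constant light: amplitude 0 pins the output at the offset everywhere
  expect_equal(issf_value(trace_params$constant, c(-100, 0, 7.3, 1e4)),
               rep(9, 4))
  p0 <- issf_params(2, 0, 5, 30, 2, 11)
  expect_equal(issf_value(p0, seq(-40, 40, by = 0.7)),
               rep(2, length(seq(-40, 40, by = 0.7))))

  # slow-ramp trace: up-ramp, plateau, down-ramp, baseline
  expect_equal(issf_value(trace_params$slow_ramp, c(0, 0.5, 6, 12.5, 18)),
               c(0.5, 1.25, 2.0, 1.25, 0.5))

  # phase = -t0 places the up-ramp start at absolute time t0
  expect_equal(issf_value(trace_params$short_pulse, c(3, 4)), c(6.5, 8.0))
})

test_that("waveform agrees with an independent interpolation oracle", {
  set.seed(42)
  for (rep in 1:25) {
    p <- random_params()
    t <- sort(stats::runif(200, -3 * p$cycle_period, 3 * p$cycle_period))
    expect_equal(issf_value(p, t), oracle_issf(p, t), tolerance = 1e-12)
  }
})

test_that("ramp_duration = 0 gives a right-continuous square wave", {
  p <- issf_params(1, 2, 6, 24, 0, 0)
  eps <- 1e-9
  expect_equal(issf_value(p, c(0, 6 - eps, 6, 24 - eps, 24)),
               c(3, 3, 1, 1, 3))
})

test_that("periodicity is exact and phase acts as pure translation", {
  set.seed(7)
  for (rep in 1:20) {
    p <- random_params()
    t <- stats::runif(50, -100, 100)
    # mathematically exact; allow only floating-point roundoff of t + T_C
    expect_equal(issf_value(p, t + p$cycle_period), issf_value(p, t),
                 tolerance = 1e-10)
    # phi = -t0 translation property
    t0 <- stats::runif(1, -30, 30)
    p_shift <- p; p_shift$phase <- -t0
    p_zero <- p; p_zero$phase <- 0
    x <- stats::runif(30, 0, 2 * p$cycle_period)
    expect_equal(issf_value(p_shift, t0 + x), issf_value(p_zero, x),
                 tolerance = 1e-12)
  }
})

test_that("Lipschitz continuity holds for positive ramps", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_params()
    if (p$ramp_duration == 0) p$ramp_duration <- 0.3
    p <- validate_params(p)
    t <- stats::runif(300, -50, 50)
    delta <- stats::runif(300, 0, p$ramp_duration * 0.99)
    bound <- abs(p$amplitude) * delta / p$ramp_duration
    expect_true(all(abs(issf_value(p, t + delta) - issf_value(p, t))
                    <= bound + 1e-12))
  }
})

test_that("output range is exactly bounded by offset and offset+amplitude", {
  set.seed(13)
  for (rep in 1:10) {
    p <- random_params()
    v <- issf_value(p, seq(0, 3 * p$cycle_period, length.out = 4001))
    lo <- min(p$offset, p$offset + p$amplitude)
    hi <- max(p$offset, p$offset + p$amplitude)
    expect_true(all(v >= lo & v <= hi))
  }
})

test_that("period integral matches closed form and quadrature", {
  expect_equal(period_integral(trace_params$slow_ramp), 30)
  expect_equal(period_integral(issf_params(3, 0, 5, 20, 1, 2)), 60)
  # half duty cycle with zero offset integrates to T_C/2 whatever the ramp
  for (tr in c(0, 0.5, 2)) {
    expect_equal(period_integral(issf_params(0, 1, 12, 24, tr, 0)), 12)
  }
  # quadrature oracle: the waveform is piecewise linear, so a trapezoid
  # rule on a grid containing every kink point is exact
  quad_oracle <- function(p, t0) {
    kinks <- c(0, p$ramp_duration, p$pulse_duration,
               p$pulse_duration + p$ramp_duration)
    k <- seq(floor((t0 + p$phase) / p$cycle_period) - 1,
             ceiling((t0 + p$cycle_period + p$phase) / p$cycle_period) + 1)
    grid <- sort(unique(c(seq(t0, t0 + p$cycle_period, length.out = 2001),
                          outer(k * p$cycle_period - p$phase, kinks, `+`))))
    grid <- grid[grid >= t0 & grid <= t0 + p$cycle_period]
    y <- issf_value(p, grid)
    sum(diff(grid) * (y[-1] + y[-length(y)]) / 2)
  }
  set.seed(19)
  for (rep in 1:10) {
    p <- random_params()
    t0 <- stats::runif(1, -20, 20)
    expect_equal(quad_oracle(p, t0), period_integral(p), tolerance = 1e-9)
  }
})

test_that("schedules switch segments at half-open boundaries in absolute time", {
  ld <- issf_params(1.6, 0.4, 12, 24, 0.1, 0)
  dd <- issf_params(1.6, 0.0, 12, 24, 0.1, 0)
  sched <- issf_schedule(c(0, 240), list(ld, dd))
  expect_equal(issf_value(sched, c(6, 246)), c(2.0, 1.6))
  # at the boundary instant the later segment applies
  expect_equal(issf_value(sched, 240), issf_value(dd, 240))
  # single segment degenerates to plain evaluation
  one <- issf_schedule(0, list(ld))
  t <- seq(0, 100, by = 0.37)
  expect_identical(issf_value(one, t), issf_value(ld, t))
  # times before the first segment are an error
  expect_error(issf_value(sched, -1), "precedes")
  expect_error(issf_schedule(c(0, 0), list(ld, dd)), "increasing")
})

test_that("composites fold their combiner over the signal values", {
  dd <- issf_params(1.6, 0, 12, 24, 0.1, 0)
  pulse <- issf_params(0, 0.4, 12, 360, 0.1, -262)
  comp <- issf_composite(list(dd, pulse))
  expect_equal(issf_value(comp, 268), 2.0)   # 1.6 + 0.4 during the pulse
  expect_equal(issf_value(comp, 100), 1.6)   # outside the pulse
  # identity composition
  single <- issf_composite(list(dd))
  t <- seq(0, 48, by = 0.1)
  expect_equal(issf_value(single, t), issf_value(dd, t))
  # product and max combiners
  two <- issf_params(2, 0, 1, 10, 0, 0)
  three <- issf_params(3, 0, 1, 10, 0, 0)
  expect_equal(issf_value(issf_composite(list(two, three), "product"), 5), 6)
  expect_equal(issf_value(issf_composite(list(two, three), "max"), 5), 3)
  expect_error(issf_composite(list()), "at least one")
})

test_that("clamping floors the output at zero only when asked", {
  p <- issf_params(-1, 0.5, 6, 24, 0, 0)
  expect_equal(issf_value(p, 12), -1)
  expect_equal(issf_value(p, 12, clamp = TRUE), 0)
})

test_that("sampling returns a well-formed time series with exact extremes", {
  grid <- seq(0, 48, by = 0.01)
  ts <- issf_sample(trace_params$slow_ramp, grid, name = "light")
  expect_s3_class(ts, "issf_timeseries")
  expect_equal(names(ts), c("time", "light"))
  expect_equal(min(ts$light), 0.5)
  expect_equal(max(ts$light), 2.0)
  expect_error(issf_sample(trace_params$slow_ramp, numeric(0)), "empty")
  expect_error(issf_sample(trace_params$slow_ramp, c(1, 1)), "increasing")
})
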