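# Shared fixtures and independent oracles for the test suite.

# The five published characterization parameter sets (top to bottom traces):
# constant light, short pulse, long photoperiod, 12-h period, slow ramp.
trace_params <- list(
  constant = issf_params(offset = 9, amplitude = 0, pulse_duration = 12,
                         cycle_period = 24, ramp_duration = 0, phase = 0),
  short_pulse = issf_params(6.5, 1.5, 3, 24, 0.1, -3),
  long_photoperiod = issf_params(4.5, 1.5, 18, 24, 0.25, 3),
  twelve_hour = issf_params(2.5, 1.5, 6, 12, 0.5, 6),
  slow_ramp = issf_params(0.5, 1.5, 12, 24, 1, 0))

# Independent interpolation oracle: the waveform as a piecewise-linear
# interpolant over one cycle, built with approxfun (a different code path
# from the package's closed-form arithmetic).
oracle_issf <- function(p, t) {
  tc <- p$cycle_period; tr <- p$ramp_duration; tp <- p$pulse_duration
  u <- (t + p$phase) %% tc
  if (tr > 0) {
    knots_t <- c(0, tr, tp, tp + tr, tc)
    knots_y <- c(0, 1, 1, 0, 0)
    f <- stats::approxfun(knots_t, knots_y, method = "linear",
                          ties = "ordered")
    s <- f(u)
  } else {
    s <- as.numeric(u < tp)
  }
  p$offset + p$amplitude * s
}

# draw a random valid parameter set (callers set the seed)
random_params <- function() {
  tc <- stats::runif(1, 1, 60)
  tr <- stats::runif(1, 0, tc / 4)
  tp <- stats::runif(1, tr, tc - tr)
  issf_params(offset = stats::runif(1, -5, 10),
              amplitude = stats::runif(1, -5, 10),
              pulse_duration = tp, cycle_period = tc,
              ramp_duration = tr, phase = stats::runif(1, -50, 50))
}

# gentle 24-h light-dark entrainment regime for the Goodwin fixture,
# released into constant darkness at t = 240 h (10 cycles)
goodwin_ld_schedule <- function(amplitude = 0.02, release = 240) {
  ld <- issf_params(0, amplitude, 12, 24, 0.1, 0)
  dd <- issf_params(0, 0, 12, 24, 0.1, 0)
  issf_schedule(c(0, release), list(ld, dd))
}

cached_goodwin <- local({
  h <- NULL
  function() {
    if (is.null(h)) h <<- make_goodwin_oscillator(check = FALSE)
    h
  }
})
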