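#' Input signal step function parameters
#'
#' Constructs and validates the six-parameter description of a periodic
#' trapezoidal pulse waveform ("input signal step function", ISSF) used to
#' force a model parameter, e.g. light intensity driving a circadian clock.
#'
#' The waveform over one cycle of length `cycle_period` rises linearly from
#' `offset` to `offset + amplitude` during `ramp_duration` hours, holds the
#' plateau, descends back over `ramp_duration` hours, and stays at `offset`
#' for the remainder of the cycle. `pulse_duration` is measured between the
#' half-maximum crossings, so the integral over one cycle is exactly
#' `offset * cycle_period + amplitude * pulse_duration`, independent of the
#' ramp. `phase` translates the waveform in time: `phase = -t0` places the
#' start of the up-ramp at absolute time `t0`.
#'
#' @param offset Baseline signal level (theta_0), signal units.
#' @param amplitude Added level during the pulse (theta_1), signal units.
#'   `amplitude = 0` gives a constant signal equal to `offset`.
#' @param pulse_duration "On" duration per cycle in hours (T_P), measured
#'   between half-maximum crossings.
#' @param cycle_period Forcing period in hours (T_C); must be positive.
#' @param ramp_duration Linear off/on transition time in hours (T); 0 gives a
#'   right-continuous square wave.
#' @param phase Time translation in hours (phi).
#' @return An object of class `issf_params`.
#' @examples
#' p <- issf_params(offset = 0.5, amplitude = 1.5, pulse_duration = 12,
#'                  cycle_period = 24, ramp_duration = 1, phase = 0)
#' issf_value(p, c(0, 0.5, 6, 12.5, 18))
#' @export
issf_params <- function(offset = 0, amplitude = 1, pulse_duration = 12,
                        cycle_period = 24, ramp_duration = 0, phase = 0) {
  p <- structure(
    list(offset = as.numeric(offset), amplitude = as.numeric(amplitude),
         pulse_duration = as.numeric(pulse_duration),
         cycle_period = as.numeric(cycle_period),
         ramp_duration = as.numeric(ramp_duration),
         phase = as.numeric(phase)),
    class = "issf_params")
  validate_params(p)
}

#' Validate step-function parameters
#'
#' Checks the invariants of an [issf_params()] object and returns it
#' unchanged, or stops with a message naming the violated invariant and the
#' offending values.
#'
#' @param candidate An `issf_params` object (or a bare named list with the
#'   same fields).
#' @return The validated `issf_params` object.
#' @export
validate_params <- function(candidate) {
  fields <- c("offset", "amplitude", "pulse_duration", "cycle_period",
              "ramp_duration", "phase")
  if (!is.list(candidate) || !all(fields %in% names(candidate)))
    stop("issf_params requires fields: ", paste(fields, collapse = ", "))
  v <- vapply(candidate[fields], function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(v)))
    stop("issf_params fields must be finite numbers; got ",
         paste(fields[!is.finite(v)], collapse = ", "))
  if (v[["cycle_period"]] <= 0)
    stop("cycle_period must be > 0 (got ", v[["cycle_period"]], ")")
  if (v[["ramp_duration"]] < 0)
    stop("ramp_duration must be >= 0 (got ", v[["ramp_duration"]], ")")
  if (v[["pulse_duration"]] < v[["ramp_duration"]])
    stop("pulse_duration (", v[["pulse_duration"]],
         ") must be >= ramp_duration (", v[["ramp_duration"]],
         "): the plateau would be negative")
  if (v[["pulse_duration"]] + v[["ramp_duration"]] > v[["cycle_period"]])
    stop("pulse_duration + ramp_duration (", v[["pulse_duration"]], " + ",
         v[["ramp_duration"]], ") exceeds cycle_period (",
         v[["cycle_period"]], "): waveform cannot return to baseline")
  if (!inherits(candidate, "issf_params"))
    candidate <- structure(as.list(v), class = "issf_params")
  candidate
}

#' @export
print.issf_params <- function(x, ...) {
  cat(sprintf(
    "<issf_params> offset=%g amplitude=%g pulse=%gh cycle=%gh ramp=%gh phase=%gh\n",
    x$offset, x$amplitude, x$pulse_duration, x$cycle_period,
    x$ramp_duration, x$phase))
  invisible(x)
}

# normalized shape s(u) in [0,1]; u already wrapped into [0, T_C)
.issf_shape <- function(u, tP, tR) {
  if (tR > 0) {
    ifelse(u < tR, u / tR,
      ifelse(u < tP, 1,
        ifelse(u < tP + tR, 1 - (u - tP) / tR, 0)))
  } else {
    # square wave, right-continuous at both transitions
    ifelse(u >= 0 & u < tP, 1, 0)
  }
}

#' Evaluate a signal at given times
#'
#' Generic evaluation of a step-function signal, a multi-segment schedule or
#' a composite of several signals at arbitrary absolute times (hours).
#'
#' @param signal An [issf_params()], [issf_schedule()] or [issf_composite()]
#'   object.
#' @param t Numeric vector of times in hours.
#' @param clamp If `TRUE`, negative output values are clamped to zero
#'   (off by default: the waveform is generic, not light-specific).
#' @return Numeric vector of signal values, same length as `t`.
#' @export
issf_value <- function(signal, t, clamp = FALSE) {
  UseMethod("issf_value")
}

#' @export
issf_value.issf_params <- function(signal, t, clamp = FALSE) {
  p <- validate_params(signal)
  t <- as.numeric(t)
  x <- t + p$phase
  u <- x - p$cycle_period * floor(x / p$cycle_period)
  out <- p$offset + p$amplitude * .issf_shape(u, p$pulse_duration,
                                              p$ramp_duration)
  if (clamp) out <- pmax(out, 0)
  out
}

#' @export
issf_value.default <- function(signal, t, clamp = FALSE) {
  stop("cannot evaluate object of class ", paste(class(signal), collapse = "/"),
       " as a signal")
}

#' Multi-segment signal schedule
#'
#' An ordered list of time segments, each with its own [issf_params()], so a
#' single signal can switch regime over the course of an experiment (e.g.
#' ten light-dark cycles followed by constant darkness). Segments are
#' half-open `[start, next_start)`: at a boundary instant the later segment
#' applies. Time stays absolute across segments (no per-segment clock
#' reset), so a release into constant conditions remains phase-aligned with
#' the preceding entrainment cycles.
#'
#' @param starts Numeric vector of segment start times (hours), strictly
#'   increasing. `-Inf` is allowed for an always-active first segment.
#' @param params A list of `issf_params`, one per start time (a single
#'   `issf_params` is recycled only when there is one start).
#' @return An object of class `issf_schedule`.
#' @examples
#' ld <- issf_params(1.6, 0.4, 12, 24, 0.1, 0)
#' dd <- issf_params(1.6, 0.0, 12, 24, 0.1, 0)
#' sched <- issf_schedule(c(0, 240), list(ld, dd))
#' issf_value(sched, c(6, 246))  # 2.0 in LD plateau, 1.6 after release
#' @export
issf_schedule <- function(starts, params) {
  if (inherits(params, "issf_params")) params <- list(params)
  starts <- as.numeric(starts)
  if (length(starts) == 0) stop("schedule needs at least one segment")
  if (length(starts) != length(params))
    stop("starts and params must have equal length")
  if (any(diff(starts) <= 0))
    stop("segment start times must be strictly increasing")
  params <- lapply(params, validate_params)
  structure(list(starts = starts, params = params), class = "issf_schedule")
}

#' @export
print.issf_schedule <- function(x, ...) {
  cat(sprintf("<issf_schedule> %d segment(s), starts: %s\n",
              length(x$starts), paste(signif(x$starts, 6), collapse = ", ")))
  invisible(x)
}

#' @export
issf_value.issf_schedule <- function(signal, t, clamp = FALSE) {
  t <- as.numeric(t)
  if (any(t < signal$starts[1]))
    stop("time ", min(t), " precedes first segment start (",
         signal$starts[1], ")")
  idx <- findInterval(t, signal$starts)  # half-open: later segment wins
  out <- numeric(length(t))
  for (i in unique(idx)) {
    sel <- idx == i
    out[sel] <- issf_value(signal$params[[i]], t[sel])
  }
  if (clamp) out <- pmax(out, 0)
  out
}

#' Composite of several signals
#'
#' Combines several signals (step functions and/or schedules) into one by
#' folding a combiner over their per-time values. The default combiner is
#' `sum`, which reproduces the standard construction of an entrainment
#' regime plus a superimposed test pulse for phase-response protocols.
#'
#' @param signals A list of `issf_params` and/or `issf_schedule` objects
#'   (a bare `issf_params` is promoted to a one-segment, always-active
#'   schedule).
#' @param combiner One of `"sum"`, `"product"`, `"max"`.
#' @return An object of class `issf_composite`.
#' @export
issf_composite <- function(signals, combiner = c("sum", "product", "max")) {
  combiner <- match.arg(combiner)
  if (inherits(signals, c("issf_params", "issf_schedule")))
    signals <- list(signals)
  if (length(signals) == 0) stop("composite needs at least one signal")
  signals <- lapply(signals, function(s) {
    if (inherits(s, "issf_params")) s <- issf_schedule(-Inf, list(s))
    if (!inherits(s, "issf_schedule"))
      stop("composite signals must be issf_params or issf_schedule objects")
    s
  })
  structure(list(signals = signals, combiner = combiner),
            class = "issf_composite")
}

#' @export
print.issf_composite <- function(x, ...) {
  cat(sprintf("<issf_composite> %d signal(s), combiner: %s\n",
              length(x$signals), x$combiner))
  invisible(x)
}

#' @export
issf_value.issf_composite <- function(signal, t, clamp = FALSE) {
  vals <- lapply(signal$signals, issf_value, t = t)
  out <- switch(signal$combiner,
    sum     = Reduce(`+`, vals),
    product = Reduce(`*`, vals),
    max     = do.call(pmax, vals))
  if (clamp) out <- pmax(out, 0)
  out
}

#' Exact integral of the waveform over one cycle
#'
#' Closed form `offset * cycle_period + amplitude * pulse_duration`. The two
#' trapezoid ramps each contribute half their width, exactly cancelling the
#' plateau shortfall, so the value is independent of `ramp_duration`.
#'
#' @param params An [issf_params()] object.
#' @return The integral of the signal over any window of one cycle period,
#'   in signal units times hours.
#' @export
period_integral <- function(params) {
  p <- validate_params(params)
  p$offset * p$cycle_period + p$amplitude * p$pulse_duration
}

#' Sample a signal on a time grid
#'
#' @param signal An `issf_params`, `issf_schedule` or `issf_composite`.
#' @param times Strictly increasing numeric vector of times (hours).
#' @param name Column name for the signal values.
#' @param clamp Passed to [issf_value()].
#' @return An `issf_timeseries` (a data frame with a `time` column followed
#'   by one column per series).
#' @export
issf_sample <- function(signal, times, name = "signal", clamp = FALSE) {
  times <- as.numeric(times)
  if (length(times) == 0) stop("empty time grid")
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  df <- data.frame(time = times)
  df[[name]] <- issf_value(signal, times, clamp = clamp)
  as_timeseries(df)
}
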