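# Protocol drivers: peak/phase statistics, photoperiod experiments and
# phase-response-curve sweeps on any loaded SBML model with a controllable
# light parameter.

#' Detect peaks in a simulated trajectory
#'
#' Local maxima after a transient cutoff, each refined by quadratic
#' interpolation through the three samples around the discrete argmax.
#' Shallow wiggles are discarded by a prominence threshold: a candidate's
#' prominence is its height above the higher of the two minima separating
#' it from taller neighbours (or the series boundary).
#'
#' @param series An `issf_timeseries`.
#' @param column Name of the column to scan.
#' @param after Transient cutoff: samples at `time < after` are ignored.
#' @param min_prominence Minimum prominence; default 5% of the post-cutoff
#'   range of the column.
#' @return Numeric vector of refined peak times (hours).
#' @export
detect_peaks <- function(series, column, after = 0, min_prominence = NULL) {
  if (!column %in% names(series))
    stop("no column '", column, "' in the series")
  keep <- series$time >= after
  tt <- series$time[keep]
  yy <- series[[column]][keep]
  if (length(tt) < 3) stop("series too short after transient cutoff")
  rng <- diff(range(yy))
  if (is.null(min_prominence)) min_prominence <- 0.05 * rng
  n <- length(yy)
  cand <- which(yy[2:(n - 1)] > yy[1:(n - 2)] &
                yy[2:(n - 1)] >= yy[3:n]) + 1L
  if (length(cand) == 0 || rng == 0)
    stop("no peaks found in column '", column, "'")

  prom <- vapply(cand, function(i) {
    j <- i
    lmin <- yy[i]
    while (j > 1 && yy[j] <= yy[i]) { lmin <- min(lmin, yy[j]); j <- j - 1 }
    if (j == 1 && yy[1] <= yy[i]) lmin <- min(lmin, yy[1])
    k <- i
    rmin <- yy[i]
    while (k < n && yy[k] <= yy[i]) { rmin <- min(rmin, yy[k]); k <- k + 1 }
    if (k == n && yy[n] <= yy[i]) rmin <- min(rmin, yy[n])
    yy[i] - max(lmin, rmin)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) stop("no peaks above the prominence threshold")

  vapply(cand, function(i) {
    t3 <- tt[(i - 1):(i + 1)]
    y3 <- yy[(i - 1):(i + 1)]
    # vertex of the parabola through the three points
    d <- (t3[1] - t3[2]) * (t3[1] - t3[3]) * (t3[2] - t3[3])
    a <- (t3[3] * (y3[2] - y3[1]) + t3[2] * (y3[1] - y3[3]) +
          t3[1] * (y3[3] - y3[2])) / d
    b <- (t3[3]^2 * (y3[1] - y3[2]) + t3[2]^2 * (y3[3] - y3[1]) +
          t3[1]^2 * (y3[2] - y3[3])) / d
    if (a >= 0) t3[2] else -b / (2 * a)
  }, numeric(1))
}

#' Estimate the oscillation period from peak times
#'
#' Median inter-peak interval; robust to a single missed or spurious peak.
#'
#' @param peaks Numeric vector of at least 3 peak times.
#' @return Period estimate in hours.
#' @export
estimate_period <- function(peaks) {
  if (length(peaks) < 3)
    stop("need at least 3 peaks to estimate a period (got ",
         length(peaks), ")")
  stats::median(diff(sort(peaks)))
}

# circular mean of phases on [0, period)
.circ_mean <- function(phases, period) {
  ang <- 2 * pi * phases / period
  m <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  m %% period
}

# circular distance between two phases
.circ_dist <- function(a, b, period) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# reduce a shift to within half a cycle of zero; a shift of exactly half a
# cycle is ambiguous and is reported as a delay (-period/2), keeping the
# classification consistent with the sign
.reduce_shift <- function(shift, period) {
  m <- shift - period * round(shift / period)
  if (m == period / 2) m <- -period / 2
  m
}

#' Run a photoperiod experiment
#'
#' For each requested photoperiod, the base signal's pulse duration is set
#' to that value, injected onto the light parameter, and the model is
#' simulated through the transient; the marker's steady-state peak phase is
#' reported in hours after dawn (the start of the up-ramp).
#'
#' @param model An `sbml_model` handle (uninjected).
#' @param light_parameter Target parameter identifier.
#' @param photoperiods Numeric vector of pulse durations (hours).
#' @param base_signal An [issf_params()] providing the non-photoperiod
#'   fields (offset, amplitude, cycle period, ramp, phase).
#' @param marker Model variable whose peaks are scored.
#' @param n_cycles Total forcing cycles simulated (default 16).
#' @param transient_cycles Forcing cycles discarded before scoring
#'   (default 5).
#' @param output_step Sampling interval (default 0.05 h).
#' @param convergence_tol Maximum spread of the last 3 cycles' peak phases
#'   for the run to count as entrained (default 0.1 h).
#' @return A data frame with columns `photoperiod` and `peak_phase`
#'   (hours after dawn, circular mean of the last 3 cycles).
#' @export
run_photoperiod_experiment <- function(model, light_parameter, photoperiods,
                                       base_signal, marker,
                                       n_cycles = 16, transient_cycles = 5,
                                       output_step = 0.05,
                                       convergence_tol = 0.1) {
  base_signal <- validate_params(base_signal)
  out <- data.frame(photoperiod = as.numeric(photoperiods),
                    peak_phase = NA_real_)
  for (i in seq_along(photoperiods)) {
    p <- base_signal
    p$pulse_duration <- as.numeric(photoperiods[i])
    p <- validate_params(p)
    tc <- p$cycle_period
    injected <- inject_issf(model, signal_assignment(light_parameter, p))
    ts <- simulate_model(injected, t_end = n_cycles * tc,
                         output_step = output_step)
    peaks <- detect_peaks(ts, marker, after = transient_cycles * tc)
    if (length(peaks) < 3)
      stop("photoperiod ", photoperiods[i],
           ": fewer than 3 post-transient peaks")
    dawn_phase <- (-p$phase) %% tc   # up-ramp start within the cycle
    phases <- (peaks - dawn_phase) %% tc
    last3 <- utils::tail(phases, 3)
    ref <- .circ_mean(last3, tc)
    if (max(.circ_dist(last3, ref, tc)) > convergence_tol)
      stop("photoperiod ", photoperiods[i], ": peak phases not converged ",
           "(spread ", format(max(.circ_dist(last3, ref, tc)), digits = 3),
           " h over the last 3 cycles)")
    out$peak_phase[i] <- ref
  }
  out
}

#' Run a phase-response-curve sweep
#'
#' Reproduces the classic PRC protocol: entrain with light-dark cycles,
#' release into constant conditions, deliver a single light pulse at a
#' series of phases (swept through the pulse signal's phase parameter,
#' with the pulse cycle period at least the simulation span so the pulse
#' fires once), and measure the steady-state phase shift of a marker
#' relative to an unpulsed control.
#'
#' The shift is `control peak time - treated peak time`, averaged over the
#' first post-pulse peak at least one free-running cycle after the pulse
#' plus the next 3 peaks, reduced to within half a free-running period `P`
#' of zero. Advances are positive, delays negative; a shift of exactly half
#' a cycle is ambiguous and is reported as a delay (`-P/2`).
#'
#' @param model An `sbml_model` handle (uninjected).
#' @param light_parameter Target parameter identifier.
#' @param entrain_schedule An [issf_schedule()]: entrainment cycles followed
#'   by release into constant conditions (amplitude 0 segment).
#' @param pulse_template An [issf_params()] for the pulse; its `phase` field
#'   is overwritten by each swept value.
#' @param pulse_phases Numeric vector of phase values to sweep (each pulse
#'   starts at `-phase` in absolute time).
#' @param marker Model variable whose peaks are scored.
#' @param shift_threshold Classification threshold in hours (default 0.25):
#'   `advance` above `+threshold`, `delay` below `-threshold`, else `none`.
#' @param t_end Simulation end; default: latest pulse start plus 6
#'   entrainment cycle periods.
#' @param output_step Sampling interval (default 0.05 h).
#' @return An object of class `prc_result`: a data frame with columns
#'   `pulse_phase`, `pulse_start_time`, `phase_shift`, `classification`,
#'   plus attributes `free_running_period` and `control_peaks`.
#' @export
run_prc <- function(model, light_parameter, entrain_schedule, pulse_template,
                    pulse_phases, marker, shift_threshold = 0.25,
                    t_end = NULL, output_step = 0.05) {
  stopifnot(inherits(entrain_schedule, "issf_schedule"))
  pulse_template <- validate_params(pulse_template)
  pulse_phases <- as.numeric(pulse_phases)
  pulse_starts <- -pulse_phases
  tc <- entrain_schedule$params[[1]]$cycle_period
  release <- entrain_schedule$starts[length(entrain_schedule$starts)]
  if (is.null(t_end)) t_end <- max(pulse_starts) + 6 * tc
  if (pulse_template$cycle_period < t_end)
    stop("pulse_template cycle_period (", pulse_template$cycle_period,
         ") must be >= the simulation span (", t_end,
         ") so the pulse fires exactly once")
  if (any(pulse_starts < release))
    warning("some pulses start before release into constant conditions")

  # control: entrainment schedule only
  control_model <- inject_issf(model,
    signal_assignment(light_parameter, entrain_schedule))
  control_ts <- simulate_model(control_model, t_end = t_end,
                               output_step = output_step)
  control_peaks <- tryCatch(
    detect_peaks(control_ts, marker, after = release),
    error = function(e) stop("control not rhythmic after release: ",
                             conditionMessage(e)))
  if (length(control_peaks) < 5)
    stop("control not rhythmic after release (", length(control_peaks),
         " peaks)")
  P <- estimate_period(control_peaks)

  res <- data.frame(pulse_phase = pulse_phases,
                    pulse_start_time = pulse_starts,
                    phase_shift = NA_real_,
                    classification = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pulse_phases)) {
    pulse <- pulse_template
    pulse$phase <- pulse_phases[i]
    pulse <- validate_params(pulse)
    comp <- issf_composite(list(entrain_schedule, pulse), combiner = "sum")
    treated_model <- inject_issf(model,
      signal_assignment(light_parameter, comp))
    treated_ts <- simulate_model(treated_model, t_end = t_end,
                                 output_step = output_step)
    treated_peaks <- detect_peaks(treated_ts, marker, after = release)

    ref <- pulse_starts[i] + P   # >= one full free-running cycle post-pulse
    ck <- control_peaks[control_peaks >= ref]
    if (length(ck) < 4)
      stop("phase ", pulse_phases[i],
           ": fewer than 4 control peaks in the measurement window; ",
           "increase t_end")
    ck <- ck[1:4]
    shifts <- vapply(ck, function(cp) {
      tp <- treated_peaks[which.min(abs(treated_peaks - cp))]
      .reduce_shift(cp - tp, P)
    }, numeric(1))
    sh <- mean(shifts)
    res$phase_shift[i] <- sh
    res$classification[i] <-
      if (sh > shift_threshold) "advance"
      else if (sh < -shift_threshold) "delay"
      else "none"
  }
  structure(res, class = c("prc_result", "data.frame"),
            free_running_period = P, control_peaks = control_peaks)
}

#' @export
print.prc_result <- function(x, ...) {
  cat(sprintf("<prc_result> %d pulse phase(s), free-running period %.3f h\n",
              nrow(x), attr(x, "free_running_period")))
  print(as.data.frame(x), ...)
  invisible(x)
}
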