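# issf — periodic step-function forcing for SBML circadian models

Computational models of the circadian clock need a time-dependent light
input to be entrained, yet published SBML models encode light in ad-hoc,
mutually incompatible ways (events, fixed constants, or no input at all).
`issf` implements a single, numerically continuous waveform — a periodic
trapezoidal pulse — that can force **any** scalar parameter of **any** SBML
ODE model, plus the machinery to wire it in and run the classic
chronobiology protocols with a general-purpose simulator. It is aimed at
modellers who want reproducible light/dark (or drug, or temperature)
regimes without hand-editing MathML.

## The waveform

The input signal step function is configured by six parameters. With
offset Θ₀, amplitude Θ₁, pulse duration T_P, cycle period T_C, ramp
duration T and phase φ, and u = (t + φ) mod T_C:

    Θ(t) = Θ₀ + Θ₁ · s(u)

    s(u) = u/T                 0 ≤ u < T        (up-ramp)
           1                   T ≤ u < T_P      (plateau)
           1 − (u − T_P)/T     T_P ≤ u < T_P+T  (down-ramp)
           0                   otherwise        (baseline)

T_P is measured between half-maximum crossings, so the integral over one
cycle is exactly Θ₀·T_C + Θ₁·T_P regardless of the ramp. Θ₁ = 0 gives
constant light; T = 0 a right-continuous square wave; setting T_C to the
whole simulation span and φ = −t₀ gives a single pulse starting at t₀.
Signals can be chained into multi-segment schedules (e.g. 10 light-dark
cycles, then constant darkness) and combined (sum/product/max) onto one
parameter.

Injection adds a `FunctionDefinition` (annotated `SBO:0000475`) and one
`AssignmentRule` per target parameter — no events, so any rule-capable
simulator can run the result.

## Worked example

```r
library(issf)

# the classic LD12:12 trace with 1 h ramps
p <- issf_params(offset = 0.5, amplitude = 1.5, pulse_duration = 12,
                 cycle_period = 24, ramp_duration = 1, phase = 0)
issf_value(p, c(0, 0.5, 6, 12.5, 18))
#> [1] 0.50 1.25 2.00 1.25 0.50
period_integral(p)
#> [1] 30

# inject into the analytic accumulator fixture (dx/dt = L): the simulated
# state is the running integral of the signal
acc <- inject_issf(make_accumulator_model(), signal_assignment("L", p))
ts <- simulate_model(acc, t_end = 24, output_step = 0.5)
tail(ts$x, 1)
#> [1] 30          # matches the closed form to < 1e-6

# a phase-response curve on the built-in Goodwin oscillator (~22 h
# free-running period): 10 LD cycles, release into darkness at t = 240 h,
# then a single 3 h pulse swept across one cycle
gw    <- make_goodwin_oscillator()
ld    <- issf_params(0, 0.02, 12, 24, 0.1, 0)
dd    <- issf_params(0, 0,    12, 24, 0.1, 0)
sched <- issf_schedule(c(0, 240), list(ld, dd))
pulse <- issf_params(0, 0.2, 3, 500, 0.1, 0)   # cycle >= span: fires once
prc <- run_prc(gw, "L", sched, pulse, pulse_phases = -seq(250, 272, by = 2),
               marker = "X")
head(as.data.frame(prc), 4)
#>   pulse_phase pulse_start_time phase_shift classification
#> 1        -250              250  -1.8743391          delay
#> 2        -252              252   0.0999124           none
#> 3        -254              254   1.7364183        advance
#> 4        -256              256   2.6623945        advance
```

Positive shifts are phase advances (the pulsed oscillator peaks earlier
than the unpulsed control), negative are delays; pulses delivered on the
rising phase of the clock advance it, pulses near the peak delay it — the
type-1 response expected of a limit-cycle oscillator.

A photoperiod comparison (`run_photoperiod_experiment(gw, "L", c(8, 16),
ld, "X")`) reports steady-state marker peak phases of 6.21 h and 9.60 h
after dawn for 8 h and 16 h days respectively: the peak tracks dusk.

## Command line

```sh
# validate / run a YAML experiment description
Rscript exec/issf validate --config experiment.yaml
Rscript exec/issf run --config experiment.yaml --out results/
```

Protocols: `evaluate` (sample signals to CSV), `simulate` (inject + write
SBML and trajectory), `photoperiod`, `prc`. Every run writes its
normalized config and a run log, and is reproducible from them alone.

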