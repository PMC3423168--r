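---
title: "Methods: step-function forcing of SBML oscillator models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-function forcing of SBML oscillator models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(issf)
```

# The waveform and its assumptions

The package's core is a six-parameter periodic trapezoidal pulse used to
force a scalar model parameter, typically light intensity driving a
circadian oscillator. Writing u = (t + φ) − T_C·⌊(t + φ)/T_C⌋ for the
wrapped cycle coordinate,

Θ(t) = Θ₀ + Θ₁·s(u), with s rising linearly from 0 to 1 on [0, T),
holding 1 on [T, T_P), descending on [T_P, T_P + T) and 0 elsewhere.

Three conventions deserve explanation because they were genuinely open
design choices:

* **Pulse duration at half-maximum.** T_P is the spacing between the
  half-maximum crossings, not the plateau length or the full footprint.
  This makes the per-cycle integral exactly Θ₀·T_C + Θ₁·T_P for *every*
  ramp duration — the two trapezoid ramps contribute T/2 each, cancelling
  the plateau shortfall — which gives the package a closed-form dosing
  oracle and makes "LD12:12 with gentle ramps" mean the same photon dose
  as "LD12:12 square". The validity constraints follow: T ≤ T_P (the
  plateau cannot be negative) and T_P + T ≤ T_C (the signal must return
  to baseline within the cycle).
* **Phase sign.** φ = −t₀ places the up-ramp start at absolute time t₀.
  Sweeping φ over negative values is therefore the natural way to place a
  single pulse late in a long run, which is exactly how the
  phase-response protocol uses it.
* **Zero ramps.** T = 0 collapses to a right-continuous square wave: at a
  transition instant the post-transition value applies. Right-continuity
  is arbitrary but deterministic, and it is encoded identically in the
  R evaluator and the generated MathML (strict `<lt/>` against the upper
  edge, `<geq/>` against the lower).

Wrapping uses floor-based modulo rather than a `mod` operator because the
SBML MathML subset has `<floor/>` but no modulo; the same algebra is used
in R so both routes agree to machine precision for negative t + φ too.

Outputs are deliberately *not* clamped at zero by default: the waveform is
a generic forcing function (drug dose, temperature, transgene induction),
and a negative offset or amplitude can be meaningful. A `clamp` flag
exists for light-like uses.

Schedules (ordered segments, each a full parameter set) keep absolute
time: a release into constant darkness stays phase-aligned with the
preceding entrainment cycles, as the protocol requires. Segment
boundaries are half-open; the later segment wins at the instant itself.
Composites fold sum (default), product or max over their member signals;
sum is the default because superposition of an entrainment regime and a
test pulse is the construction every PRC protocol uses.

# SBML encoding

Injection adds one reusable `FunctionDefinition`
(`issf(t, theta0, theta1, tP, tC, tR, phi)`) whose body is a piecewise
with mutually exclusive conditions, annotated `sboTerm="SBO:0000475"`, and
one `AssignmentRule` per target parameter. Because SBML forbids the time
csymbol inside function bodies, time is always passed as the first
argument from the rule. Multi-segment schedules become nested piecewise
over the time csymbol — not events — so simulators without event support
can still run the models. The ramp pieces guard their divisions by
conditions with empty support when tR = 0, and the package's own MathML
interpreter compiles piecewise to lazy nested `if`, so no 0/0 is ever
evaluated; simulators that evaluate piecewise strictly would need tR > 0.

The central correctness property is *simulator equivalence*: the
trajectory of the rule-assigned parameter reported by the ODE simulator
must match direct R evaluation of the same composite signal to ≤ 1e-6
max absolute error. This is a genuine dual-route check — the MathML is
parsed back by an independent code path (XML → expression → evaluation)
rather than by the code that generated it.

Re-injection onto an already-governed parameter errors unless an explicit
`replace = TRUE` is given; rules never stack silently. Reaction-local
parameters must be explicitly promoted to global scope first
(`promote_local_parameter()`), mirroring the SBML restriction that rules
only target global symbols.

# The built-in fixtures: what they emulate and what they do not

No published clock model ships with the package (their equation sets are
external), so protocols are exercised on two synthetic stand-ins:

* **Accumulator** — `dx/dt = L(t)`, `x(0) = 0`. After injection, `x(T_C)`
  equals the closed-form period integral, so the entire
  inject→MathML→compile→integrate pipeline is checked against an exact
  number (30.0 for the standard LD12:12 trace with Θ₀ = 0.5, Θ₁ = 1.5).
* **Goodwin oscillator** — the three-variable negative feedback loop
  X → Y → Z ⊣ X with Hill repression (n = 4) and saturable Michaelis-type
  degradation, the canonical minimal circadian oscillator. Light enters
  additively in X production by default (a degradation coupling is also
  available); additive production coupling is the simplest mechanism that
  yields a type-1-like phase response. Rate constants were calibrated
  once — all first-order rates scaled uniformly, which rescales time
  exactly — to a free-running period of 22.0 h, and frozen as
  `GOODWIN_DEFAULT_RATES` (v = 0.752443, v/2 = 0.3762215, all K = 1).
  A 22 h intrinsic period is typical of real clock mutants and, more
  importantly, is far enough from 24 h that locking to a 24 h forcing
  cycle demonstrates genuine entrainment rather than coincidence.

The stated experimental world for fixture protocols, chosen once:

* Entrainment amplitude Θ₁ = 0.02 (≈3% of maximal production). The
  fixture entrains 1:1 at this drive (inter-peak interval 24.000 ±
  0.001 h) yet releases into darkness with only a mild amplitude
  transient. Stronger forcing (Θ₁ = 0.1) also locks but overdrives the
  loop so severely that the post-release rhythm needs ~80 h to recover —
  unusable for a PRC control. Intermediate drive (0.05) sits in a
  period-doubled entrainment regime, a real feature of forced Goodwin
  dynamics worth knowing about.
* PRC pulse: 3 h duration, amplitude 0.2, 0.1 h ramps, delivered in
  constant darkness after 10 LD cycles (release at t = 240 h), swept in
  2 h steps across one free-running cycle. Brief-but-strong against
  gentle entrainment mirrors the laboratory convention of saturating
  test pulses on a dim background.

What a green fixture test does **not** establish: quantitative agreement
with any published clock model. The fixtures have one light input, no
transcription/translation delay, and no photoadaptation; real models
(e.g. multi-loop plant clocks) have several light entry points and much
stiffer kinetics. The protocols accept any loaded SBML model, so
bring-your-own-model reproduction of published photoperiod and PRC
figures is supported but deliberately not part of the test contract.

# Protocol conventions

* **Peaks** are discrete local maxima after a transient cutoff, refined
  by the vertex of the parabola through the three samples around the
  argmax, with a prominence filter (default 5% of the post-cutoff range)
  to reject sampling wiggles. **Period** is the median inter-peak
  interval, robust to one missed or spurious peak.
* **Photoperiod experiment**: 16 forcing cycles, first 5 discarded
  (conservative for stiff clock models), peak phase reported as the
  circular mean over the last 3 cycles of (peak time − dawn) mod T_C,
  where dawn is the up-ramp start. Runs must converge — phases stable to
  0.1 h over the last 3 cycles — or the driver errors rather than
  reporting a drifting number.
* **PRC**: one control (entrainment schedule only) and one run per pulse
  phase (schedule + pulse, sum combiner). The shift is control peak time
  minus treated peak time — advances positive, the chronobiology
  convention — measured from the first control peak at least one
  free-running period after the pulse start and averaged over 4 peaks
  (treated peaks paired by nearest time), then reduced to within half a
  period of zero. A shift of exactly half a cycle is genuinely ambiguous;
  it is reported as a delay (−P/2), keeping the sign and the
  classification consistent. Classification uses a ±0.25 h threshold:
  above peak-interpolation noise (≤0.02 h), below any meaningful shift.

# Numerical choices

* The ODE integrator is an adaptive Dormand–Prince 5(4) with FSAL,
  absolute tolerance 1e-9 and relative 1e-7, stepping exactly onto the
  output grid. The environment provides no solver library, so the
  integrator is part of the package; the fixture models are non-stiff,
  and an explicit method with these tolerances reproduces the analytic
  accumulator to <1e-8.
* The internal step is capped at half the shortest ramp of any injected
  signal (detected by walking the compiled rule expressions), so a 0.1 h
  ramp can never be stepped over; square-wave discontinuities are handled
  by step rejection.
* Everything is deterministic — fixed tolerances, no randomness — so
  repeated runs produce bit-identical CSV output; the CSV writer pins
  17-significant-digit formatting to make that reproducibility visible on
  disk.
* Exact mathematical identities (periodicity, range bounds) are tested at
  1e-10, conceding only the floating-point roundoff of forming t + T_C.

# Known limitations

* Irregular, recorded light traces cannot be represented — the waveform
  is inherently periodic/piecewise — and smooth sinusoidal forcing is out
  of scope.
* The SBML reader covers the subset needed here (parameters, species,
  compartments, reactions, assignment/rate rules, function definitions,
  the arithmetic/relational/piecewise MathML core). Algebraic rules,
  events, delays and hierarchical composition are rejected or ignored
  with an error, not silently mishandled.
* The integrator is explicit; genuinely stiff models would need smaller
  steps than a production implicit solver.
* Phase statistics assume a clearly rhythmic marker; the drivers error on
  non-converged or arrhythmic runs instead of guessing.
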