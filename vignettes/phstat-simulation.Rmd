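---
title: "Simulating a pH-stat autotitrator: models, parameters and design choices"
author: "phstatsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a pH-stat autotitrator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phstatsim)
```

# The problem

A pH-stat measures an acid-producing reaction by *not letting it change the
pH*: a feedback loop doses strong base whenever the measured pH drops below
a setpoint, and the dosed volume over time becomes the measurement. The
canonical application here is in vitro intestinal lipolysis: pancreatic
lipase hydrolyzes emulsified triglycerides, each yielding up to two free
fatty acids (FFA), and the NaOH needed to keep the vessel at pH 7 counts
the acid released.

This package simulates that instrument end to end — chemistry, sensor
chain, pump, firmware loop, log file, analysis — so each stage can be
validated in isolation and in closed loop at desk scale. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the physical device leaves them open.

# Ground-truth chemistry

## Speciation and the pH solver

The vessel is represented by conserved totals (moles), never by
concentrations, so titrant addition dilutes exactly. For a trial pH, each
$n$-protic acid contributes its mean number of dissociated protons
$\bar n(\mathrm{pH})$ computed from the stepwise constants; electroneutrality

$$ [\mathrm{H^+}] - [\mathrm{OH^-}]
   + \frac{n_\text{base} - n_\text{acid} + n_\text{fixed}}{V}
   - \sum_i C_i \,\bar n_i(\mathrm{pH}) = 0 $$

defines the pH as the unique root (the residual is strictly decreasing in
pH). `solve_ph()` brackets it on $[0, 14]$ and solves by Brent iteration,
polishing until the residual is below $10^{-12}$ mol/L; a missing sign
change signals an inconsistent state (e.g. an impossible negative fixed
charge) rather than returning a clamped value. Bracketed iteration was
chosen over Newton steps deliberately: at a few hundred evaluations per
millisecond the robustness costs nothing at this scale.

Constants are thermodynamic 25 °C values, all configurable: phosphate
pKa 2.15 / 7.21 / 12.35, pKw 14.00. The buffers simulated are ~1 mM, so
activity corrections are ignored; at mM ionic strength the error is of
order 0.05 pH, far below the controller's 0.1 pH deadband. Temperature
dependence, CO₂ absorption and Ca–phosphate/soap complexation are out of
scope; the NaCl and CaCl₂ of simulated intestinal fluid enter only as
(net-zero) spectator charge.

## Lipolysis kinetics

The physical device never prescribes a rate law, so the simulator adopts
the simplest one consistent with the saturating release curves such
assays produce: first-order decay of the remaining hydrolyzable pool,

$$ n_\text{rel}(t) = n_0\,(1 - e^{-kt}), \qquad n_0 = \frac{2\,W}{M}, $$

with $W$ the oil mass and $M$ the mean triglyceride molar mass (default
885 g/mol, triolein — representative of olive oil and configurable, since
oils vary). Released FFAs are pooled into a single effective monoprotic
acid. Its pKa matters: long-chain fatty acids at an emulsion interface
titrate one to two units above their aqueous monomer value, so the default
`ffa_pKa_eff = 7.5`. A consequence worth understanding: at a pH 7 setpoint
only $1/(1+10^{7.5-7.0}) \approx 24\%$ of released FFA is ionized and
hence titrated, so the %FFA plateau computed from dosed NaOH
underestimates total hydrolysis — a real, known property of pH-stat
lipolysis that the simulation reproduces rather than hides.

# The instrument chain

The measurement path is deliberately modelled stage by stage because its
artefacts (bias, attenuation, quantization) are exactly what one wants to
study in an instrument of this class.

* **Calibration** (`pH_at_0V`, `pH_1V_range`): the meter's recorder output
  is $(pH - pH_{0V})/\text{range}$ volts, clamped to ±2 V. Practice puts
  the 0 V point one unit below the target with a 1 pH/V range, which keeps
  the working region well inside the clamp.
* **Bias divider**: two equal resistors between the 3.3 V rail and the
  meter output put the sampled node at $(3.3 + V)/2$ — a +1.65 V offset
  *and* a gain of ½. The attenuating model (rather than pure offset) is
  the physically correct reading of that circuit; `divider_ratio` is
  configurable so a unity-gain bias stage can be emulated for comparison.
* **ADC**: 10 bits over 0–5 V, floor quantization (successive-approximation
  behaviour), optional Gaussian noise at the node. Read-back inverts at
  the bin centre, giving a worst-case round-trip error of
  $\text{range} \cdot V_\text{ref} / (\text{ratio} \cdot 2^\text{bits})
  \approx 0.0098$ pH with the defaults — asserted exhaustively over all
  1024 codes in the test suite. No multi-sample averaging is modelled:
  each displayed pH is a single conversion.
* **Pump**: an 8 mm/rev lead screw, 200 steps/rev motor and 1/16
  microstepping make the dispensable volumes an integer grid of
  `volume_per_microstep`; requests round to the nearest grid point, ties
  upward. The syringe's endstop is a state, not an error — an empty
  syringe terminates a run with its own stop reason.

# The controller

Each sampling tick (default 1 s) the loop advances the chemistry, reads
the pH through the full chain, and doses one aliquot iff the *reading* is
strictly below `target − dosing_threshold` (default deadband 0.1 pH; a
reading exactly at the boundary does not dose). During the dispense time
(`aliquot/flowrate`) and an inter-aliquot wait, sampling and logging
continue but dosing is gated — the wait is what prevents runaway dosing
before an aliquot has mixed. Mixing and re-equilibration are treated as
instantaneous, which gentle stirring justifies qualitatively at these
volumes.

Stop conditions, each with its own recorded reason: user abort, syringe
endstop, a hard `max_duration_s` (default 7200 s — assays of this kind run
30–120 min), and *stability*: the device-side analogue of "the operator
sees the pH is stable", quantified as max−min recorded pH ≤ 0.02 over a
600 s window containing no dose. The 0.02 band is an invented, configurable
quantification (it must exceed the 0.0098 pH quantization step, or a
noiseless run could never look stable). Faults (missing storage card,
broken sensor cable) suspend records and dosing until cleared, while the
chemistry — external reality — keeps evolving.

Base-dosing (upward titration) is the validated path; acid dosing is a
sign mirror available through `add_titrant(kind = "acid")` but not
exercised by the packaged scenarios.

# The log dialect

The storage format mirrors an embedded logger: append-only text, one
`New Titration` marker per run, `key=value` header (including the
*quantized* aliquot volume, which the analysis needs), tab-separated
per-tick records (`t_s pH aliquots cum_volume_uL`, pH at 3 decimals,
volume at 2), and a trailing `stop_reason` key — written last because it
is only known last. Every line is flushed on write, so a power failure
leaves a parseable prefix. The parser is correspondingly defensive: a
malformed *final* line is discarded with a warning (truncation damage), a
malformed interior line is an error with its line number, and header keys
are order-insensitive. Timestamps are experiment-relative integers; the
device has no real-time clock.

# Analysis

`%FFA = 100\,V_\text{NaOH} N_\text{NaOH} M / (2W)` is applied pointwise to
the cumulative volume column (units fixed at this boundary: litres, grams,
g/mol). The `%FFA` is computed from the analysed log only — the
neutralization phase is run and logged separately, so its baseline volume
never enters the lipolysis calculation. Values above 100% are flagged, not
clipped: they indicate inconsistent assay constants.

The endpoint is found *post hoc*, as on the real instrument: the earliest
time $t$ with no dose in $(t, t+600\,\mathrm{s}]$ and recorded pH spread
≤ 0.02 (defaults shared with the controller's stability stop). The window
is half-open on the left so that the final dose itself can mark the
endpoint. Rate recovery fits $A(1-e^{-kt})$ by Levenberg–Marquardt with
self-starting values (plateau from the curve maximum, rate from the
half-rise time); a flat curve signals a typed no-fit error instead of
returning nonsense.

# Packaged scenarios and what they show

`scenario_buffer_titration()` is the known-endpoint validation: 38.98 mg
NaH₂PO₄·H₂O in 0.25 L (1.13 mM), titrated to pH 7 with 0.1 N NaOH in
10 µL aliquots. Stoichiometry says ~1 mL; the closed loop dispenses
~0.93 mL because it stops dosing at the deadband edge (pH 6.9) — the same
behaviour the physical experiment shows when it doses slightly less than
the hand value.

`scenario_olive_oil_lipolysis()` holds an emulsion aliquot in simulated
intestinal fluid at pH 7 while FFAs are released. Two quantities the
experiment does not print had to be fixed as package defaults: the total
reaction volume (40 mL: a 4 mL emulsion aliquot plus 36 mL of fluid, a
typical bench scale for such assays) and the emulsion's oil fraction
(20% w/w, hence `W_lipid = 0.8` g) — both configurable and documented as
assumptions, not measurements. Emulsifier, bile salts and pancreatin enter
only through the kinetics parameters, and the default
`rate_constant = 1e-3` s⁻¹ puts the release time scale in the observed
30–120 min assay range.

## Problem sizes and the recovery study

The reproducibility study behind `recover_rate_constant()` runs 20
closed-loop simulations with $k$ log-spaced over $[10^{-4}, 10^{-2}]$ s⁻¹,
each with a 0.4 g substrate load and no inter-aliquot wait so that pump
capacity exceeds peak base demand even at the fastest rate, a horizon of
$4/k$, and a sampling interval coarsened for slow kinetics so every run
stays at a few thousand ticks. The median relative error of the recovered
$k$ is ~3%, comfortably under the 10% the package asserts.

# Known limitations

* The last few percent of the hydrolyzable pool are titrimetrically
  invisible: once the remaining release can no longer push the pH below
  the 0.1 deadband (the accumulated FFA buffers it), dosing stops at about
  95% release under the default parameters. Endpoint detection therefore
  certifies "release no longer measurable", not "release complete".
* The synthetic loop omits electrode drift and response time, motor
  acceleration, CO₂ uptake, activity corrections and droplet-scale
  colloid physics. Passing tests show the *logic* of the instrument is
  right under an idealized but quantization- and noise-faithful chain;
  they do not calibrate any real emulsion's kinetics.
* Simulation time is virtual: one tick per sampling interval, however fast
  the host runs it. Real-time pacing, serial I/O and the device's UI are
  out of scope.
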