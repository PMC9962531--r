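---
title: "Models and methods behind pneumotex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pneumotex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotex)
```

`pneumotex` simulates a complete textile respiration-sensing chain —
mechanical stimulus, piezoresistive sensor, microcontroller acquisition,
breath counting — so that the signal-processing design can be studied and
regression-tested without hardware. This vignette explains each model, its
assumptions, the tunable parameters and the numerical choices, and what the
simulations can and cannot say about real garments.

## The stimulus models

### Testing-machine stretch cycles

A tensile testing machine cycling between 0 and a stretch distance at
constant crosshead (beam) speed is the standard bench stand-in for a
breathing chest. Because the speed is constant, the elongation wave is
**triangular**, not sinusoidal: `instron_waveform()` ramps
0 → `stretch_distance_mm` → 0 at `|d(elongation)/dt| = beam_speed`, giving a
cycle frequency of `beam_speed / (2 × stretch_distance)` cycles per minute.
With a 10 mm stretch, beam speeds of 160, 240, 400 and 480 mm/min simulate
8, 12, 20 and 24 breaths per minute; these four protocols ship as
`scenario_presets()`.

The sampling interval defaults to `dt = 0.05` s (20 Hz). Embedded firmware
loop periods vary between prototypes, so the rate is configurable; 20 Hz
over-samples the fastest packaged scenario (24 cycles/min, 2.5 s period) by
a factor of 50, so detection results are insensitive to modest changes in
`dt`. `dt` larger than a half-cycle is rejected outright (the triangle would
alias).

### Human breathing

`breathing_waveform()` models chest expansion as consecutive
**raised-cosine pulses** of height `depth_mm`, one per breath, paced by a
piecewise-constant rate schedule. No standard chest-motion waveform exists
for this class of sensor, so the pulse shape is a documented modelling
choice: a raised cosine is smooth, has a single apex, and returns to
baseline between breaths, which is what matters for a slope-threshold
detector. `inspiration_fraction` (default 0.4) sets the asymmetry between
the inspiratory rise and the slower expiratory fall. Only breaths whose full
period fits inside the trace are emitted, so an integer rate r over 60 s
yields exactly r pulses; a zero rate produces a flat apnoeic segment.

On top of the pulses the generator can add, all seeded and reproducible:

* Gaussian elongation noise (`noise_sd_mm`),
* a linear baseline drift (`drift_slope_mm_min`), emulating slow posture
  change or garment settling,
* Poisson-timed raised-cosine **artifact bumps** (`artifact_rate_per_min`,
  `artifact_amplitude_mm`, width 0.5 s by default), emulating arm or torso
  movements that produce "false breaths".

The generator emulates the features a slope-threshold detector actually
responds to — pulse amplitude, pacing, baseline wander, transient bumps. It
does **not** emulate cardiac cross-talk, sensor fatigue or creep,
temperature/humidity response, or garment-fit variability, so a passing
simulation grid shows algorithmic correctness, not clinical performance.

## The sensor model

### Calibration

The gauge is characterised by its **sensory coefficient**
$R_\mathrm{rel}(s) = (R - R_0)/R_0 \times 100\,\%$ at stretch $s$.
`fit_gauge_response()` builds a monotone curve through the origin and the
calibration points; the packaged table for the cotton + MWCNT + PPy print is

```{r}
gauge_calibration_points()
```

The default interpolant is the Fritsch–Carlson monotone shape-preserving
cubic (`stats::splinefun(method = "monoH.FC")`): it reproduces every
calibration point exactly and cannot overshoot between points, which keeps
the stretch→resistance map physically monotone. Measured sensory
coefficients grow roughly linearly with stretch, and a least-squares linear
mode (`mode = "linear"`, through the origin) is provided for that reading —
but a straight line cannot pass through all four points at once, so exact
interpolation is the default. Beyond the last calibration point the curve
continues as a power law matched to the last two points (exponent ≈ 1.46
for the packaged table), avoiding both flat and runaway extrapolation.
Non-monotone calibration sets are rejected with a diagnostic naming the
offending pair.

The baseline resistance defaults to `R0_kohm = 150`. The choice is driven by
the detector: its susceptibility threshold is 80 kΩ, and with the packaged
~62 % rise at a 10 mm stretch, R₀ = 150 kΩ produces ~93 kΩ breath-scale
swings — comfortably supra-threshold. Fabric-level sheet-resistance
measurements of such prints are orders of magnitude smaller (kΩ-scale), and
the effective sensing-path resistance of a full garment loop is generally
not published; R₀ is therefore an explicit, configurable parameter rather
than a derived one.

### Hysteresis

Knitted piezoresistive sensors show load–unload hysteresis, but published
loop figures rarely carry axis calibrations usable for fitting. The model is
therefore deliberately qualitative: a two-branch construction in which
unloading changes resistance with gain `hysteresis_ratio` ≤ 1 of the loading
gain, the retained excess decaying exponentially with time constant
`relaxation_tau_s`. This reproduces the properties that matter — the loop
area is zero iff `hysteresis_ratio = 1`, grows as the ratio drops, the
unloading branch sits above the loading branch, and a full cycle followed by
a rest of a few time constants returns to R₀. Only these qualitative
properties are asserted in tests; no numeric loop reproduction is claimed.

### Noise

Measurement noise is additive Gaussian on resistance (`noise_spec()`),
seeded, and clipped so resistance stays positive. Analog-electronics noise
beyond this (and beyond ADC quantization, which lives in the acquisition
module) is out of scope.

## The acquisition model

The sensor `R2` and a known resistor `R1` form a series divider across the
supply `U`; the midpoint voltage $U_1 = U R_1/(R_1 + R_2)$ is quantized by
the ADC and the firmware inverts $R_2 = R_1 U/U_1 - R_1$. Defaults mirror a
typical Arduino prototype: R1 = 10 kΩ, U = 5 V, 10-bit ADC referenced to
the supply.

Numerical conventions, since microcontroller families differ:

* quantization is `round(u1 × (2^bits − 1)/Uref)` with **round half away
  from zero**, clipped to `[0, 2^bits − 1]`;
* a sample quantizing to zero counts would invert to infinite resistance
  (open circuit); `acquire()` flags it (`open_circuit = TRUE`, `NA`
  resistance) instead of propagating a non-finite value, and the detector
  refuses flagged samples rather than guessing;
* the divider/estimator pair is an exact algebraic inverse without
  quantization, and with quantization the round-trip error is bounded by
  `|dR2/dU1|` at the operating point times half an LSB — both are enforced
  as property tests.

At the simulation operating point (R₂ between 150 and 243 kΩ with the
default divider) the midpoint voltage is small (0.2–0.3 V), so the 10-bit
reconstruction error is a few kΩ — visible in the traces, but an order of
magnitude below the 80 kΩ detection threshold, which is why the counting
chain is robust to it.

## The breath detector

The detector mirrors firmware that tracks the sign of
`delta = previous − current` resistance: `delta ≤ 0` is a rising slope
(inhalation; flat samples count as rising), `delta > 0` falling
(exhalation). A rising run accumulates the total rise since the last trough;
at the first falling sample the run ends and a peak is marked **iff the
accumulated rise reached the susceptibility threshold** (default 80 kΩ),
after which the accumulator resets.

Applying the threshold to the *accumulated* rise is an interpretation:
prose descriptions of such firmware are ambiguous between per-sample delta
magnitude and cumulative rise, but at any realistic sampling rate a single
inter-sample delta can never reach 80 kΩ (at 20 Hz a 93 kΩ swing spread
over a 2 s inspiration gives ~2 kΩ per sample), so the cumulative reading
is the one under which the documented threshold is meaningful. A strict
`mode = "per_sample"` is provided for fidelity experiments.

Other conventions: no pre-filtering by default (an optional moving-average
`smooth_n` exists but is off, matching minimal firmware); counting windows
are tumbling half-open intervals `[k·window, (k+1)·window)` so a boundary
peak belongs to the window containing its sample time; `breaths_per_minute()`
reports the last complete window, offers a rolling trailing window, and for
traces shorter than one window either errors or — explicitly opted in —
scales the count by `60/duration`.

Consequences worth knowing: the detector is invariant to constant
resistance offsets (only rises matter), peak counts are non-increasing in
susceptibility, and a sub-threshold artifact landing **on an inspiratory
upslope** can split the rising run and suppress that breath — the false
negative mirror of the supra-threshold "false breath" failure mode. The
test suite pins down both behaviours.

### Classification

Clinical reference labels leave gaps (adult bradypnea is quoted as 8–10,
normal as 12–16, hyperpnea "about 20", tachypnea above 24, apnea "about two
breaths per minute"). The default table closes them conservatively with
half-open bands: apnea < 3, bradypnea 3–11, normal 12–16, hyperpnea 17–24,
tachypnea ≥ 25, and pediatric groups built the same way around their
age-specific normal ranges (newborn/infant 30–60, toddler 24–40,
preschooler 22–34, school age 18–30, adolescent as adult). This closure is
an interpretation, not a clinical claim, and the table is fully
user-overridable via the `table` argument of `classify_rate()`.

## Textile characterisation formulas

`surface_mass()` (m/(La·Sa), g/m²), `air_permeability()`
((q̄v/A)·167, mm/s), `thermal_resistance()` ((Tm−Ta)·A/(H−ΔHc) − Rct0,
m²K/W) and `summarize_replicates()` implement the standard fabric-lab
report quantities. The standard deviation uses the n−1 sample convention;
the packaged calibration table's coefficient-of-variation column is
consistent with sd/mean under 2-decimal rounding, which the suite checks
row by row. The heating-power correction ΔHc is treated as watts subtracted
from H. Kawabata hand-value transforms and garment-pressure calculations
are out of scope (instrument-proprietary or lacking published inputs).

## Evaluation

`run_scenario()` executes stimulus → sensor → acquisition → detection →
classification, returns every intermediate trace, and optionally writes
them as CSVs; reruns with identical configurations and seeds are
byte-identical. `agreement()` computes the mean absolute error and mean
bias of device-versus-reference paired counts; the packaged pairs
(`respiratory_agreement_pairs()`) are human-subject measurements carried as
a fixture for the arithmetic — the simulation chain makes no attempt to
reproduce them.

## Problem sizes and determinism

The packaged scenarios use 60 s at 20 Hz (1201 samples); the property
suites run grids of a few hundred cases with fixed seeds; calibration math
operates on 4-point tables. All randomness flows through explicit integer
seeds, and generators restore the caller's RNG state, so whole-chain runs
are reproducible to the byte.

## Known limitations

* The sensor model is phenomenological: no percolation physics, no
  temperature/humidity/washing response, no creep.
* The breathing generator's pulse shape and artifact shape are modelling
  choices; real chest-band signals have richer morphology.
* The hysteresis model is qualitative by design.
* Classification tables encode range conventions, not diagnostic criteria.
* Exact line-level fidelity to any particular firmware cannot be verified
  beyond the documented semantics; the per-sample mode exists to bracket
  the plausible readings.
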