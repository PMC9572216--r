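---
title: "From ADC counts to gait cycles and plantar maps: the models behind insolemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ADC counts to gait cycles and plantar maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolemetry)
```

## The system being modelled

insolemetry implements the software side of a pressure- and
temperature-sensing shoe insole. The instrument is simple and cheap by
design: 16 force-sensitive resistors (FSRs) and 8 NTC thermistors per
insole, each read through a pull-up voltage divider into a 12-bit ADC at
40 Hz, multiplexed into a 24-channel frame and streamed as delimited text.
Clinically, the interesting outputs are the per-stride vertical ground
reaction force (vGRF) curve, the spatial distribution of plantar pressure
through the phases of the gait cycle, and the standing plantar temperature
map — the quantities monitored for early signs of diabetic foot
complications, where pressure and temperature asymmetries precede
ulceration.

The package has no radio or microcontroller dependency: a synthetic trial
generator stands in for the hardware, producing the same frame streams the
logger would record, so that every downstream stage is testable end to end.

## Sensor physics and calibration

**Voltage divider.** Every channel is a pull-up divider:
$V_{out} = V_{cc} R_{ext} / (R_{ext} + R)$, inverted as
$R = R_{ext}(V_{cc} - V_{out})/V_{out}$. `divider_config()` holds
$V_{cc}$ (default 5 V), $R_{ext}$ (default 10 kΩ) and the ADC width
(default 12 bits, counts 0–4095 mapped linearly onto 0–$V_{cc}$). The
defaults match the reference electronics, but nothing is hard-coded to
them: the one-step count-to-resistance form
$R = R_{ext}(A_{max} - A)/A$ is derived for any configuration and is
algebraically identical to the two-step path (a property the test suite
checks across the whole count range, to $10^{-9}$ °C after the thermistor
conversion). A count of 0 is an open circuit (unloaded FSR, broken wire)
and is signalled as a typed condition rather than returned as infinity.

**Thermistor.** The NTC bead is modelled as $R(T) = a e^{bT}$ with
defaults $a = 24{,}710$ Ω, $b = -0.036$ /°C, which places 10 kΩ at room
temperature (25 °C). The inverse is $T = (\ln R - \ln a)/b$; $\ln a$ is
always computed from `a`, never stored as a rounded constant, so the
forward and inverse paths are exact inverses. The calibration's working
range is 20–50 °C; conversions outside it are returned with a warning
(extrapolation), not rejected, because transient readings just outside the
band are common and harmless. `fit_exponential_calibration()` recovers
$(a, b)$ by ordinary least squares on $\ln R$ versus $T$ and reports $R^2$
on that log scale; with 2% multiplicative resistance noise over a 31-point
20–50 °C sweep the fitted rate stays within 5% of truth (the bound was
fixed from a 200-seed Monte-Carlo at that noise level before being frozen
into the tests).

**FSR.** Vendor curves for FSR-type sensors are published as log–log
plots, so `fsr_force_model()` is an anchor table of (resistance, force)
pairs with log–log linear interpolation: exact at every anchor, monotone,
and zero above the largest-resistance anchor — the sensor's dead band
below its lightest characterised load (49 mN in the default table). The
default table passes exactly through the published 10 kΩ at 100 g
(0.981 N) operating point and spans 10 g–10 kg with a roughly inverse
force–resistance shape. It is a documented default, not a measured
characterisation; users with a calibrated sensor supply their own anchors.

The auxiliary conversions are deliberately plain arithmetic: a circular
active area $\pi r^2$ (126.68 mm² at the 6.35 mm radius),
force = pressure × area (so the 80–600 kPa adult plantar pressure range
loads one sensor with 10–76 N), mass = force / 9.81, and the battery
budget energy (Wh) = capacity × voltage, runtime = energy / draw, days =
runtime / daily wear (4.81 Wh, ≈12 h, ≈24 days at the 1300 mAh / 0.4 Wh/h /
0.5 h/day defaults).

## The synthetic trial generator

The generator emulates the reference acquisition protocol: a cohort of 12
adults (ages 20–59, 52–125 kg, 153–185 cm, BMI 18–36.5), each walking a
10 m walkway 6 times at self-selected speed, sampled at 40 Hz; plus
standing-still captures for temperature mapping. Where the protocol fixes
a number, the generator's default is that number; where it does not, a
value typical for adult gait was chosen once and documented here:

* **Stance template.** Total vGRF during stance is the sum of two
  Gaussian peaks (σ = 0.13 of stance time) at 25% and 75% of stance, the
  push-off peak 1.25× the loading peak and scaled to 1.15 body weight,
  with a linear taper over the last 12% of stance so force reaches zero
  at toe-off. Swing force is exactly zero. The taper width was set so
  that threshold-based stance measurement on the resampled curves centres
  on the configured duty cycle (see below).
* **Timing.** Stance occupies 60% of each cycle. Cycle durations are
  drawn per stride as mean 1.05 s with 5% coefficient of variation, so
  stride time drifts through a trial. Self-selected speed is drawn
  uniformly from 1.0–1.4 m/s per trial.
* **Spatial sharing.** Each sensor site is classified by its normalised
  heel-to-toe coordinate (heel < 0.30, midfoot 0.30–0.55, metatarsal
  0.55–0.82, toe > 0.82). Heel weight decays as $(1-s)^2$ in stance
  progress $s$, midfoot carries a $(4s(1-s))^2$ foot-flat bump,
  metatarsals ramp as $s$, toes engage linearly over the final 20% of
  stance. This reproduces the qualitative heel-strike → toe-off load
  progression; real per-sensor force sharing is subject-specific and was
  never published, so this scheme is a stand-in, not biomechanics.
* **Sensing chain.** Per-site force → FSR resistance (inverse anchor
  table) → first-order hysteresis lag (default relaxation time 0.02 s,
  the slow polymer recovery of resistive sensors) → divider voltage →
  additive Gaussian voltage noise (default 2 LSB) → integer quantization
  clamped to the ADC range. Temperatures are per-site baselines (drawn
  from 29–33 °C unless supplied) plus a slow linear drift (0.005 °C/s)
  through the same divider chain.

All randomness flows through one seeded generator; the same seed
reproduces a trial bit for bit, and the caller's RNG state is left
untouched. Every simulated trial carries a ground-truth sidecar (template
vGRF, post-hysteresis "sensed" vGRF, stance flags, true site temperatures,
true heel-strike frames) so tests compare pipeline output against what was
actually generated rather than against the pipeline itself.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: soft-tissue and footwear dynamics, shear forces,
inter-subject waveform variability beyond amplitude/timing jitter,
sensor-to-sensor calibration spread, drift and creep of the FSR polymer
beyond the first-order lag, and real skin-temperature dynamics. Results on
simulated cohorts validate the *software chain*, not the instrument.

## Gait analysis

`total_vgrf()` pushes all 16 pressure channels through the calibration
chain and sums per frame. `segment_cycles()` defines a heel strike as an
upward crossing of 5% of the trial's maximum force after at least one
below-threshold sample; a cycle runs heel strike to next heel strike,
leading/trailing partials are discarded. The threshold is relative, so
segmentation is invariant to uniform force rescaling; the 5% default and
the rule itself are this package's choice (no detection rule was published)
and both are configurable. Cycles are stored as 1-based half-open
`[start, end)` frame index pairs — the native indexing convention of R.

Each cycle is linearly resampled to 512 points and summarised as a
pointwise ensemble mean with a population standard-deviation band.
Population rather than sample SD is used because the band is descriptive;
at the cycle counts involved (dozens) the difference is immaterial. Forces
are reported in raw newtons; `ensemble_stats()` callers can normalise by
body weight beforehand if cross-subject shape comparison is the goal.

`stance_fraction()` measures the loaded share of a resampled cycle as the
fraction of points above 5% of the cycle maximum. Two discretisation
effects bias this measure upward slightly: the resampled curve
interpolates across the toe-off drop, and heel strikes are detected on
40 Hz frame boundaries. With the 12%-of-stance toe-off taper the residual
bias is a few tenths of a percentage point; simulated cohorts at the 60%
duty cycle measure 60.6–60.9%.

## Plantar maps

`build_template()` rasterises a parametric foot outline — circular heel
arc, tapering midfoot, quarter-ellipse toe cap, symmetric about the long
axis — onto a regular grid (default 1 mm, row 1 at the heel). The outline
is a display/masking device, not an anthropometric model.

`interpolate_map()` spreads one scalar per sensor over the template by
piecewise-linear interpolation on a Delaunay triangulation of the sites,
chosen for two properties worth guaranteeing: exactness at every sensor
node and boundedness by the input range. Mask cells outside the sites'
convex hull take the nearest site's value. No attached numerical library
provides planar scattered interpolation, so a compact Bowyer–Watson
triangulation is implemented in the package; at ≤16 sites per map it is
exact and fast. Cells containing a sensor are stamped with that sensor's
exact value, and equidistant-cell ties resolve toward the foot axis so a
mirrored layout produces an exactly mirrored grid. A thin-plate-spline
variant (`method = "rbf"`) gives smoother pictures but no boundedness
guarantee.

Pressure maps are produced at chosen fractions of a gait cycle (default
set: heel strike 0, foot-flat 0.15, midstance 0.30, heel-off 0.45, toe-off
0.60, mid-swing 0.80) from the nearest frame; temperature maps time-average
each channel over a window (default 10 s) of a standing capture. The
shipped sensor layout is a synthetic reconstruction of typical plantar
placements on a 260 mm foot — the physical insole's coordinates were never
published — and all map code is driven by the layout file, so real
coordinates drop in without code changes.

## Numerical and interface choices

* ADC counts are accepted as reals in calibration (analytic operating
  points like $A = 2047.5$ are expressible); integer quantization is the
  simulator's job.
* Degenerate inputs fail loudly and specifically: open circuits are a
  typed condition, malformed frames name the offending field, sensors
  outside the foot outline are rejected by id, collinear site sets are
  rejected before triangulation.
* The frame wire format is comma-delimited text (timestamp to 3 decimals,
  foot tag, 16 + 8 integer counts), with stream-level metadata in
  `#`-prefixed header lines; integer counts make write→read round trips
  exact. The original wire layout was never published; this one is chosen
  for losslessness and greppability.
* Problem sizes in the test suite and acceptance script (single trials
  for unit checks, 20-trial cohorts for the stance-duty recovery) keep
  full runs in seconds while leaving the stochastic checks comfortably
  inside their tolerances.

## Worked example

```{r example, eval = FALSE}
subject <- subject_profile(age = 30, weight = 70, height = 170)
trial <- simulate_walk(subject, seed = 42)
force <- total_vgrf(trial)
cycles <- extract_cycles(force)
ensemble_stats(cycles)
mean(apply(cycles, 1, stance_fraction))

maps <- phase_pressure_maps(trial, attr(cycles, "cycles")[1, ])
plot(maps[["midstance"]])

standing <- simulate_standing(subject, seed = 7, duration_s = 30)
plot(standing_temperature_map(standing, window_s = 10))
```

## Known limitations

The generator's load-sharing scheme and foot outline are plausible
stand-ins, not measured anatomy; the FSR anchor table beyond the one
published operating point is a data-sheet-shaped default; hysteresis is a
single first-order lag, while real polymer recovery is multi-timescale;
and the polynomial thermistor calibration variant that the reference
deployment preferred is not implemented because its coefficients were
never published — the exponential form, whose algebra was published in
full, is used throughout.
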