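---
title: "From electrode voltages to ion fluxes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From electrode voltages to ion fluxes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iseflux)
```

## The measurement

A self-referencing ion-selective microelectrode is moved periodically
between two positions near a tissue surface — position 0 close to the
cells and position 1 a scan distance further out (50 µm by default). Any
transmembrane ion flux sets up a concentration gradient in the unstirred
solution layer next to the tissue, and the Nernstian electrode converts
the concentration at each position into a voltage. Because a single
electrode visits both positions, its notorious slow drift appears
identically in both signals and cancels in the position-to-position
voltage difference dV — that cancellation is the whole point of the
self-referencing design.

The default timing reproduces standard practice: samples every 10 ms,
1000 samples per 10 s "position loop", the electrode stationary at
position 0 during the first loop and then alternating. The electrode's
exponential response means the first seconds after each move are
transients; only samples after the `start_fit` settling time (default
5 s) enter any estimate. `start_fit` is an analysis parameter, not an
acquisition parameter: it can be changed at re-analysis without touching
the stored data.

## Drift-corrected dV

`dv_triple()` implements the paired-regression procedure. For three
consecutive loops (positions p, q, p), one ordinary least-squares line in
absolute time is fitted through the pooled settled samples of the two
flanking loops, and a second line *constrained to the same slope* is
placed through the settled samples of the middle loop. The vertical
offset between the parallel lines is dV, signed as
dV = V(position 0) − V(position 1). A shared linear trend ℓ(t) added to
every sample shifts both lines by the same amount and leaves the offset
unchanged; the package tests this to 10⁻⁹ mV at drift rates up to
10 mV/min.

Two details the procedure leaves open were fixed as follows. The flanking
loops are pooled into *one* joint fit (not averaged per-loop fits), and
every sliding window of three loops is refitted from scratch. The fitted
voltages V0 and V1 are both lines evaluated at the middle loop's midpoint
time; under linear drift the choice of evaluation time cancels in every
downstream quantity. The least-squares sums are computed on centered
times, which keeps the estimates at full double precision even late in a
long recording.

## Two flux formalisms

With dx the (corrected) distance between the positions, the package
offers:

* **Chemical potential**: J = −C · u · ((58/|z|)/slope_cal) · (dV/dx),
  with C the average bath concentration (mol m⁻³), u the ionic mobility
  (m² V⁻¹ s⁻¹) and slope_cal the *signed* fitted calibration slope
  (mV/decade). Only the slope of the calibration enters, so electrode
  drift — which shifts the intercept, not the slope — barely affects this
  estimate.
* **Diffusion gradient**: the fitted V0 and V1 are converted to
  concentrations through the calibration curve and Fick's law is applied,
  J = −D (c0 − c1)/dx. This uses the intercept too, so it inherits any
  drift in the absolute concentration scale, but it makes no assumption
  about the bath concentration.

Signs follow one convention everywhere: J > 0 is influx into the tissue,
J < 0 efflux. A cation efflux raises c0 above c1, hence dV > 0 with a
non-inverting electrode, hence the leading minus sign. The ideal-slope
factor is written 58/|z| rather than 58/z: for an anion the calibration
slope is itself negative, and using |z| is exactly what makes the
chemical-potential estimate agree with Fick's law for anions as well. A
common amplifier gain (e.g. the customary inverting −33× low-pass stage)
multiplies dV and slope_cal alike and cancels; the package tests this
invariance at g = −33.

The two formalisms are linked by the Einstein relation. The package
derives every diffusion coefficient from the mobility table as
D = u · (S/ln 10)/|z| with S = 0.058 V — the same 58 mV that defines the
ideal electrode slope. With that single constant the two estimates
coincide identically as the gradient vanishes; at a finite relative
gradient ε = (c0 − c1)/c1 the chemical-potential estimate referenced to
the position-1 concentration is low by ε/2 + O(ε²) (the logarithmic vs
arithmetic mean of the two concentrations). At ε = 10⁻³ the methods agree
to 0.05%; at ε = 10⁻² to 0.5%. The 58 mV constant corresponds to roughly
18–19 °C; it is retained verbatim, temperature is deliberately not a
parameter, and no activity-coefficient correction is attempted.

When a strong flux elevates the local concentration well above the bath —
the situation the simulated "barley root" acceptance scenario reproduces,
with ~1.5 mM at the electrode against a 0.5 mM bath — the bulk-referenced
chemical-potential estimate is low by the concentration ratio (3-fold
there), while Fick's law is unaffected. Setting `use_position1_conc`
replaces the bath concentration by the measured position-1 concentration
and restores agreement to within 5% even at that 3-fold elevation.

## Geometry correction

For cylindrical or spherical tissues the steady-state field is not linear
in the electrode travel d = scan_distance · cos(scan_angle), so d is
replaced by a corrected distance that references the flux to the tissue
surface: with tissue radius a, r0 = a + gap0 and r1 = r0 + d,

* cylinder: dx = a · ln(r1/r0)
* sphere: dx = a² (r1 − r0)/(r0 · r1)

Both converge to d as a → ∞ (flat limit), and both are the exact
integrating factors of the simulator's cylindrical and spherical fields,
so parameter recovery on simulated curved geometries is exact rather than
approximate. Referencing to the surface (rather than to position 0) was
an open choice; it changes curved-geometry magnitudes only and is what
the corrected-distance forms above imply.

## Buffer correction for H⁺ fluxes

In a buffered solution part of a proton flux travels as protonated buffer
HA rather than free H⁺. Two corrections are provided, matching the two
flux formalisms. For the chemical-potential method the total flux is
J_total = (r + 1) · J_H with

r = (u_HA/u_H⁺) · C · 10⁻³ · 10^pK · (10^pH/(10^pK + 10^pH))²,

where C is the total buffer concentration in mM (the 10⁻³ converts to
molar — the formula is dimensional in concentration, so the unit
convention matters and is pinned by tests). For the Fick method the
protonated fraction [HA] = C/(10^(pH−pK) + 1) is evaluated at both
positions, its Fick flux −D_HA([HA]₀ − [HA]₁)/dx is added to the free-H⁺
flux, and the pH at each position comes from the measured H⁺
concentration of the same triple (pH = −log₁₀ of the molar
concentration). Consequently buffer correction is only accepted for H⁺
analyses; the chemical-potential ratio r uses the nominal solution pH
from the configuration, consistent with that method's use of the nominal
bath concentration. Polyprotic organic-acid buffers are modelled with a
single pK and therefore refused when the solution pH is more than 0.25
units from it.

## The simulator: what it emulates, and what it does not

`simulate_recording()` produces the analyser's entire input chain with a
known answer. The tissue emits a piecewise-constant source flux J(t)
(positive = efflux) into an unstirred layer of thickness L (default
500 µm) with a perfectly mixed bath beyond; the steady-state profiles are
the closed forms quoted under `concentration_field()`. The electrode
reports intercept + slope·log₁₀(c) through a first-order lag (default
τ = 0.5 s; after the 5 s settling window a step has decayed by e⁻¹⁰), a
linear drift term, and i.i.d. Gaussian noise (default 0.03 mV, the noise
floor of a good A/D chain). Noise is generated from the scenario seed
with the caller's RNG state preserved, so seeded runs are
bit-reproducible.

Deliberate idealisations, which bound what passing recovery tests can
show about real data:

* the field is quasi-static — it tracks flux changes instantly, with no
  transient diffusion PDE;
* L and the mixed-bath boundary are modelling conveniences chosen for
  closed-form ground truth, not measured properties;
* convection episodes (e.g. after adding solution to the bath) are not
  simulated — inject an event mark instead and exclude the interval;
* electrode lag is a single exponential; real electrodes can show
  multi-exponential or history-dependent responses;
* no electromigration: bath electric fields acting on all ions at once
  are outside both the simulator and the flux formalisms' validity
  discussion here.

A scenario whose source flux would drive the field concentration to zero
is rejected outright rather than clipped.

## Numerical and interface choices

* Concentrations cross module boundaries in mol m⁻³ (numerically equal
  to mM, which is what users enter); voltages in mV; distances in metres;
  fluxes in mol m⁻² s⁻¹ internally and nmol m⁻² s⁻¹ in the output table.
* The mobility table ships as an editable TSV (limiting ionic mobilities
  from standard electrochemistry references, u = Λ/(|z|F) at 25 °C);
  the numerical flux scale inherits whatever mobility values are used.
* Segmentation is driven by the recorded position channel, tolerating
  ±10% of the scan distance around each level; transition samples join
  the following segment; more than 2% unclassifiable samples, or
  position runs shorter than half a loop, abort with an error. A final
  short loop is flagged truncated and excluded from dV analysis (an
  explicit choice — the window simply never covers it).
* The recording file format is a fixed-precision, tab-separated text
  dialect (4 decimals for time/position, 6 for voltages ≈ 1 nV, far
  below any electrode noise floor) so written files are diffable and
  write∘read∘write is byte-stable.
* Calibration fits use ordinary least squares on log₁₀(concentration);
  electrodes with |slope| < 1 mV/decade are rejected as degenerate, and
  the `calibrate` command warns at 20% deviation from 58/|z| (a
  housekeeping threshold, not a scientific rule).

## Problem sizes used in the tests

The shipped tests and the acceptance script run 3–6 loops of 1000 samples
(30–60 s of synthetic recording, a few thousand samples per scenario) —
enough for four sliding-window dV estimates per run, which is where every
recovery statement above is measured. Real experiments are one to two
orders of magnitude longer; nothing in the pipeline depends on run
length beyond memory for the sample table.

## Known limitations

Fick-method concentrations (and hence fluxes) inherit electrode drift
through the calibration intercept: a 1 mV/min drift inflates the
concentration scale by ~1.7% per 25 s of recording at 58 mV/decade. This
is a property of the method, visible in the simulator, and the reason the
chemical-potential method is preferred for small fluxes. Robust or
weighted regression, outlier rejection, multi-position surface scanning,
interference (Nikolsky–Eisenman) calibration and voltage-clamp
electromigration analysis are all out of scope.
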