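---
title: "Modelling oxygen and nutrient zonation in a two-layer PDMS chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen and nutrient zonation in a two-layer PDMS chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxyzone)
```

## The system

Liver lobules are oxygen-zonated: hepatocytes near the periportal inlet see
high oxygen and nutrient levels, cells near the central vein see low ones,
and their function (albumin synthesis among much else) follows that
gradient. `oxyzone` models a microfluidic device that recreates this
zonation in vitro: a lower PDMS layer carries two serpentine gas channels —
one fed with incubator air (19% O2), one with nitrogen — and a cell-culture
chamber sits in the upper layer, separated from the gas network by a PDMS
membrane. Oxygen permeates the membrane and sets up three oxygenation zones
along the chamber (zone 1 high, zone 3 low) while the perfused medium forms
a parallel glucose gradient. Circular sensor films on the chamber floor
report local oxygen through ratiometric (red/green) luminescence imaging.

The package provides four connected layers of functionality:

1. a finite-volume transport model of oxygen (whole device) and glucose
   (chamber only) on a 2-D vertical cross-section,
2. the closed-form chamber hydrodynamics (plane Poiseuille, wall shear),
3. the two-site Stern–Volmer sensing pipeline (calibration, ROI ratio
   extraction, inversion, QC, response time), and
4. zone-wise biological quantification (object counts, viability, albumin
   RFU, one-way ANOVA), with a synthetic-data generator producing sensor
   stacks and staining images with known ground truth.

## Transport model

Both species obey the convection–diffusion equation
$\partial C/\partial t + \nabla\cdot(uC) = D\nabla^2 C$. Oxygen is solved
over the whole device — gas-channel band, PDMS bulk, medium — and glucose
only in the medium, where the flow is confined.

**Dimensional reduction.** The solver works on an $x$–$z$ cross-section
(flow direction × height), treating the width as homogeneous. Every
quantity the model is asked to reproduce — outlet glucose, zone-wise
oxygen, shear — varies chiefly along $x$ and $z$; giving up the third
dimension turns a cluster-scale FEM problem into a desk-scale sparse solve
(5 000 unknowns at the default 100 × 50 grid).

**Partition interface.** Oxygen is about ten times more soluble in PDMS
than in culture medium; at the interface the concentration jumps,
$C_\mathrm{PDMS} = K\,C_\mathrm{medium}$ with $K = 10$, while flux is
continuous. The solver works in the partition-scaled variable $\psi$
(equal to $C$ in medium and $C/K$ in PDMS), which is continuous across the
interface; fluxes use the effective diffusivity $D\,S$ (solubility $S = K$
in PDMS, $1$ in medium) with harmonic-mean face averaging, and the storage
term in transient runs uses $S$ as well. The interface condition is then
exact by construction, which the tests verify by one-sided extrapolation of
both profiles to the interface (ratio $K$ within 1%) and by face-flux
comparison. The convention $C_\mathrm{PDMS} = 10\,C_\mathrm{medium}$ is
consistent with a PDMS saturation of 1.8 mol/m³ against ~0.18 mol/m³ for
air-saturated medium.

**Boundary conditions.** The gas channels are Dirichlet patches at the
bottom of the grid: air level under zone 1, nitrogen under zone 3, and the
interleaved serpentine under zone 2 rendered as the cell-averaged air
fraction of an alternating stripe pattern (default pitch 1 mm; a uniform
mid-level is available as `zone2_mode = "mid"`). Cell averaging — rather
than snapping whole cells to one stripe — makes the zone-2 boundary
resolution-independent. Since the channels are only 0.1 mm high, they are
snapped to the bottom grid row(s); the PDMS membrane above them must be
resolved by at least three cells (a hard precondition). The device is not
sealed, so PDMS faces exposed to the atmosphere (top and sides) take the
19% saturation value. The side faces of the medium layer are no-flux when
oxygen advection is off — the default for gas-switch scenarios, where
medium advection at 0.5 µL/min is second order — and become
inlet/outlet faces when advection is enabled.

**Cellular consumption.** The cell monolayer on the chamber floor consumes
oxygen at the Michaelis–Menten areal rate
$\mathrm{OCR} = (q N_t/A_t)\,C/(K_m + C)$ with $q = 3.5\times10^{-16}$
mol/s per cell and $K_m = 6.3\times10^{-3}$ mol/m³, gated by a Heaviside
necrosis cutoff at $10^{-4}$ mol/m³ (cells below it are dead and consume
nothing; an optional smoothed step of configurable half-width, default
$0.1\,C_\mathrm{nec}$ when enabled, aids convergence near the cutoff). The
nonlinear sink is resolved by semi-implicit Picard iteration — the sink is
linearised as $k(C_\mathrm{prev})\,C$, keeping the system an M-matrix and
the iterate positive — to a true-residual tolerance of $10^{-10}$.

**Glucose.** Uptake is zero-order (a constant areal flux from the printed
2.4 nmol/min per 10⁶ cells), not Michaelis–Menten, with a smooth cutoff as
concentrations approach zero so that uptake ceases where glucose is
exhausted. Advection uses first-order upwinding, robust at the chamber's
cell Péclet numbers (≈0.5 at the default grid). The inlet is a Danckwerts
(closed) condition: the total inlet flux equals $u\,C_\mathrm{in}$ through
the upwind advective term, with no separate diffusive Dirichlet face term.
At 0.2 µL/min axial diffusion through an open Dirichlet inlet would carry
as much glucose as the flow itself and break the chamber-wide mass balance
by ~8%; the closed inlet keeps the balance exact by construction, which is
also the correct description of a syringe-fed port. The discrete
Poiseuille profile is renormalised so its depth-integrated flux equals $Q$
exactly for the same reason. The outlet is reported flow-averaged.

**Time integration.** Transient runs use backward Euler (unconditionally
stable) with a 10 s default step and snapshots every 600 s, matching the
10-minute imaging cadence; the system matrix is factorised once (sparse
Cholesky) when no cells are present.

## Reconstructed geometry

The published device dimensions cover the layers (2 mm gas, 3 mm upper),
the gas channels (0.2 × 0.1 mm), the 1 mm PMMA chamber mould and the
1.5 mm sensor punches — but not the chamber footprint. The defaults are
therefore reconstructions from two printed constraints, and both are plain
arguments that a config file can override:

* `chamber_width` = 13.7 mm from the parallel-plate shear closed form
  $\tau = 6\mu Q/(w h^2) = 3.4\times10^{-6}$ Pa at 0.5 µL/min with
  $h = 1$ mm and $\mu = 0.93$ mPa·s;
* `chamber_length` = 49.4 mm from the glucose balance: a 5.5 → 4.2 mM drop
  at 0.5 µL/min implies $N = \Delta C\,Q/r \approx 2.71\times10^{5}$
  cells, and at 400k cells/mL seeding over a 1 mm-deep chamber of width
  13.7 mm that cell count needs 49.4 mm of length. (Carrying the
  constraint through exactly, rather than rounding the length to the
  nearest millimetre, is what keeps the low-flow outlet concentration
  inside its tolerance band — the balance is sensitive to $N/Q$.)

With this footprint the model reproduces, with no further adjustment:
outlet glucose 5.37 / 4.20 / 2.25 mM at 5.0 / 0.5 / 0.2 µL/min (printed:
5.3 / 4.2 / 2), a 24% inlet→outlet drop at 0.5 µL/min, and zone oxygen
with cells of ~18.0 / 9.8 / 3.0% (measured bands: 19, 10–11, 3–5.5).

The printed shear values themselves are not mutually linear in $Q$
(2 × 10⁻⁵ at 5.0 vs 3.4 × 10⁻⁶ at 0.5 µL/min), which no closed form linear
in $Q$ can reproduce simultaneously; the package reports the closed form
and documents a ±50% comparison band (relative to the computed value) for
the 5.0 and 0.2 µL/min figures. At these Reynolds numbers (≪1) a numerical
Stokes solve would add nothing to the exact plane-Poiseuille profile, so
none is included.

## Sensing model

The two-site Stern–Volmer model relates the red/green emission ratio to
oxygen:
$$\frac{R}{R_0} = \frac{f_1}{1 + K_{sv}[\mathrm{O_2}]} + f_2, \qquad
  f_2 = 1 - f_1,$$
with $f_1$ the quenchable dye fraction and $K_{sv}$ the quenching constant
(per %O2 here). Inversion is closed-form on the physical band
$f_2 < R/R_0 \le 1$; ratios above 1 are clamped to 0% and flagged, ratios
at or below $f_2$ have no physical preimage (the signature of a bleached
flake) and are flagged `out_of_range`. ROIs reading above 21% O2 for three
or more consecutive frames are excluded wholesale.

A practical identifiability point: the bench protocol calibrates each ROI
at 19% and 0% only, and two points cannot determine both $f_1$ and
$K_{sv}$. The package therefore offers a `two_point` mode that fixes $f_1$
(default 0.8) and solves $K_{sv}$ exactly from the 19% level, and a
`multi_point` least-squares mode (with $f_2 = 1 - f_1$ constrained)
whenever three or more levels are available. Ratios are computed as
mean(red)/mean(green) over each ROI disk — means before the ratio — with
no background subtraction by default.

**Response time.** The sensor-on-gas-layer calibration scenario is
modelled as 1-D transient diffusion through the 2 mm PDMS layer after the
channel side steps 19% → 0%. The sensor film backing (polystyrene) passes
oxygen poorly, so the outer face is treated as no-flux and the readout
plane is that outer face; an `ambient` outer-face option exists for films
open to air. The response metric is t90 — time to complete 90% of the
plateau-to-plateau excursion, linearly interpolated between frames; the
source experiment states the number but not its criterion, so the 90%
definition is this package's choice. The model gives t90 ≈ 21 min against
the reported 18 min, consistent given that the real membrane above the
channels is nearer 1.9 mm and the film adds its own lag. (An
all-Dirichlet slab with a plane evaluated next to the stepped face — a
literal reading of "sensor adjacent to the channel" — responds in under a
minute and cannot reproduce the measurement; that reading was discarded.)

**Stabilisation.** Zone formation after the gas switch is summarised by
the earliest time from which every ROI changes by less than 1% of full
scale over each subsequent 10-minute window. On the default no-cell
simulation this gives 40 min, the same tens-of-minutes scale as the
reported ~30 min (the criterion here is strict and quantitative; the
reported figure reads a plateau off a curve).

## Quantification

Counting applies a threshold (Otsu by default — the protocol says only
"appropriate threshold" — with a numeric override, since counts are
threshold-sensitive), labels 8-connected components and drops those below
a minimum area. Viability is
$(\mathrm{total} - \mathrm{dead})/\mathrm{total} \times 100$. Albumin
expression per imaging site is the RFU ratio mean(red)/mean(blue) after
linear 8-bit conversion, invariant to common exposure scaling. Zone
comparisons use per-zone mean ± sample SD ($n-1$; the source is silent on
the denominator) and one-way equal-variance ANOVA at $p < 0.05$.

## Synthetic data

The generator emulates the acquisition, not the optics: multiplicative
Gaussian noise per channel (photon-like, default 1%; no noise
characterisation is published), ideal disks for sensors and nuclei, no
PSF, no photobleaching kinetics (only the QC signature of a bleached
flake, on request), no illumination-field structure. Sensor stacks render
green as a constant gain and red as
$\mathrm{gain}\cdot R_0\cdot(R/R_0)(\mathrm{O_2})$ inside 1.5 mm disks,
quantised to the camera bit depth (default 16-bit at 100 µm/px; the
sensing runs used a 2.5× objective, staining a 20× one, and both pixel
scales are configurable). Staining sites draw non-overlapping nuclei
(minimum separation two radii plus two pixels, so that 8-connected
counting can recover the exact cell number), a Bernoulli live/dead split,
and per-cell albumin intensity equal to the zone gain times a lognormal
factor (σ = 0.3). Phantom zone targets default to 19 / 13 / 7 %O2 with a
450 s relaxation constant, inside the measured no-cell bands. Every
stochastic output takes a mandatory seed and is bit-reproducible; ground
truth travels alongside the data as a JSON sidecar.

Passing the round-trip tests on these phantoms demonstrates that the
pipeline is self-consistent (rendering inverted exactly at zero noise,
unbiased calibration recovery at 1% noise, RFU ordering following the
generator's gains). It does not demonstrate robustness to the things the
generator omits — spatial illumination structure, focus drift, dye
loading heterogeneity, cell clumping — which real data have.

## Numerical choices and degenerate inputs

* Grid: uniform rectilinear, default 100 × 50 (≈0.5 mm × 0.1 mm cells);
  mesh doubling moves outlet glucose by <10⁻⁷ and zone oxygen means by
  ≤1.5%. Preconditions: nx ≥ 20, nz ≥ 10, ≥3 cells across the membrane.
* ROI means use exact per-column disk-slice areas and wall-extrapolated
  sensor-plane values (cell centres sit dz/2 above the floor; with
  consumption the difference is visible).
* Zone boundary ties go to the lower-numbered zone, with a 10⁻¹² relative
  epsilon so exact-fraction positions survive floating-point division.
* Picard iterations stop on a true nonlinear residual < 10⁻¹⁰ (relative);
  non-convergence raises an error carrying the residual, and a fully
  necrotic culture surface warns rather than errors.
* Glucose exhaustion uses a smooth cutoff $C/(C+\varepsilon)$ with
  $\varepsilon = 10^{-3}$ mol/m³ — small enough not to perturb uptake at
  physiological concentrations, large enough to keep the iteration stable.
* Degenerate inputs error early and specifically: zero-area chambers,
  non-increasing zone boundaries, ROIs off the footprint, missing velocity
  fields, calibrations without a zero-oxygen point, thresholds that are
  not finite, dead counts exceeding totals.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run steady solves at 100 × 50
(doubled to 200 × 100 for the convergence check), a 2-hour transient at
10 s steps, a 200-cell slab at 5 s steps, 50-replicate calibration
Monte-Carlo, and 36 synthetic staining sites per zone at 128 px — all
chosen as the smallest sizes at which the discretisation errors above are
demonstrably below the tolerances being asserted.

## Known limitations

* The 2-D reduction cannot represent the serpentine channel geometry or
  lateral wall effects; zone-2 oxygen depends on the (unpublished)
  serpentine pitch through the stripe model.
* The chamber footprint is reconstructed, not measured; all downstream
  absolute numbers inherit that uncertainty (the acceptance bands reflect
  it).
* Shear is reported from the parallel-plate closed form; the printed 3-D
  values are not linear in flow and are matched only within the
  documented band.
* No CO2/pH coupling, no protein-fouling kinetics, no ELISA model; albumin
  is quantified as relative fluorescence only.
* The sensing model omits optics (PSF, flat-field) and dye photophysics
  beyond the two-site model; lifetime-based sensing is out of scope.

## A worked example

```{r example, eval = FALSE}
geometry <- device_geometry()
params <- transport_params(geometry)
grid <- build_grid(geometry)
cells <- cell_field(params, grid)

# glucose outlet at the bench flow rate, with its analytic cross-check
v <- poiseuille_profile(flow_spec(0.5), geometry, grid)
steady_glucose(grid, params, v, cells)$extra$outlet   # 4.20 mM
glucose_mass_balance(flow_spec(0.5)$Q, params)        # 4.20 mM

# steady zonation with cells
ox <- steady_oxygen(grid, params, cells, gas_bc = list(air = 19, n2 = 0))
roi <- extract_roi_series(ox)
tapply(roi$O2_percent, roi$zone, mean)                # ~18.0 / 9.8 / 3.0

# sensor response of the 2-mm gas layer
slab <- slab_step_response()
response_time(slab$time_s, slab$O2_percent)           # ~21 min
```
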