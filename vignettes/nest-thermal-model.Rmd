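---
title: "An energy-balance model of sea turtle nest incubation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-balance model of sea turtle nest incubation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestherm)
```

## The problem

Sea turtle clutches incubate 40–80 cm underground, and the temperature each
embryo experiences decides its fate three times over: development rate (hence
incubation duration), sex (temperature-dependent sex determination during the
middle third of development), and survival to hatching. Sand temperature
measured beside a nest is the common proxy for incubation temperature, but it
misses the heat the embryos themselves produce — by late incubation a clutch
of 50+ eggs runs several degrees warmer than the adjacent sand. `nestherm`
simulates the nest as a physical object: transient three-dimensional heat
conduction through beach sand, the looser sand a female repacks around her
clutch, and the eggs, with a metabolic heat source in every egg that grows
with embryonic maturity and temperature. Per-egg temperature histories then
drive per-embryo predictions of duration, sex and hatching success.

## Model structure

The governing equation on all subdomains is the heat equation

$$\rho C_\rho \frac{\partial T}{\partial t} = \nabla\!\cdot(k \nabla T) + r,$$

with conduction fluxes given by Fourier's law and a source $r$ that is nonzero
only inside eggs. Three subdomains carry distinct material properties:

* **Beach sand** — a cylinder 2 m across and 1.5 m deep of undisturbed sand.
* **Nest-chamber sand** — the flask-shaped egg chamber and the refilled neck
  shaft, packed at a lower bulk density than the surrounding beach.
* **Eggs** — spheres of 46.7 mm diameter, thermally treated as water (they
  are ~80% water by mass and within a few percent of water density).

### Effective material properties

Sand is a three-phase mixture of quartzite grains, pore water and pore air.
From a dry bulk density and gravimetric moisture the package computes phase
volume fractions, then the effective conductivity by Mori–Tanaka
homogenisation (grains as matrix, water and air as spherical inclusions) and
the heat capacity by a mass-weighted rule of mixtures. Two conventions need
stating:

* Heat capacity is expressed **per unit dry mass** (`c_solid + m c_water`),
  which pairs with the dry bulk density so their product is the volumetric
  heat capacity of the solid + water mixture; pore air carries negligible
  mass either way.
* The canonical nest-chamber value excludes the pore-water term. The
  published effective values for the two sands (829.9 and
  661.3 J kg⁻¹ °C⁻¹ at equal 4.0% moisture) are mutually consistent *only*
  under that reading — at equal moisture the two sands differ in air
  fraction alone, which cannot move a mass-weighted heat capacity — so
  `reference_materials()` adopts it for the repacked chamber sand and
  records the physically complete form (`include_pore_water = TRUE`) as the
  default for user-supplied sands.

Constituent constants default to handbook-style values (quartzite
ρ = 2650 kg m⁻³, k = 5.6 W m⁻¹ °C⁻¹, c = 661.3 J kg⁻¹ °C⁻¹; water at
0 °C; air at 1.2 kg m⁻³) and are overridable per call. With the reference
field measurements (beach 1282.2 kg m⁻³, nest 1026.6 kg m⁻³, 4.0% moisture)
they reproduce the published effective pairs 2.2/1.7 W m⁻¹ °C⁻¹ and
829.9/661.3 J kg⁻¹ °C⁻¹:

```{r materials}
reference_materials()
```

### Geometry and clutch packing

The chamber is an axisymmetric flask — a cylindrical throat over an
ellipsoidal bulb — of fixed height 0.31 m, the constant offset between nest
depth and neck length observed across field nests; `build_nest_geometry()`
therefore gives the neck unit slope in depth. Bulb dimensions (radius
0.12 m, height 0.22 m, throat radius 0.09 m) follow published averages for
flatback egg chambers and are configuration values.

Eggs are packed by random sequential deposition with downhill settling: each
egg is dropped at random horizontal positions, rests at its deepest feasible
contact (chamber wall/floor or previously placed eggs), rolls greedily into
local hollows, and the deepest candidate is kept. Only the *outcome* — a
gravity-settled random arrangement with no overlaps — matters to heat
transfer, so this replaces a rigid-body dynamics simulation. Packing is
bit-reproducible under its seed, respects a 10⁻⁴ m overlap tolerance, and
fits the largest observed clutch (61 eggs) below random-close-packing
density.

### The finite-volume solver

The heat equation is discretised on a rectilinear finite-volume grid, 2 cm
cells near the clutch grading geometrically to ~12 cm at the domain edges,
with harmonic-mean interface conductivities and backward-Euler time stepping
(1 h outer steps, optional substeps). An unstructured mesh would track the
flask boundary more smoothly, but the rectilinear discretisation solves the
same continuum model, is directly testable against closed-form solutions,
and keeps the whole stack dependency-free; at 2 cm the egg-scale features
are resolved (each egg captures ≥ 6 cells and its centre cell carries its
source).

Boundary conditions mirror the two series a field campaign measures:

* a **Dirichlet plane 10 cm below the surface** above the nest, driven by
  the above-nest series (this plane absorbs radiation, rain and surface
  exchange, which are therefore never modelled explicitly);
* a **Dirichlet lateral wall** at 1 m radius driven by the adjacent-sand
  series, translated to each wall depth by the damped-diel profile
  $A(z) = A_0 e^{-\Delta z/D}$, with phase delay $\Delta z/D$ radians and
  $D = \sqrt{2\alpha/\omega} \approx 0.24$ m for this sand;
* zero flux at the 1.5 m base.

The initial field is the stationary solve at the first boundary values. The
matrix is factorised once (sparse Cholesky) and reused for every step, and a
per-step energy ledger closes storage = boundary influx + sources to
rounding level (~10⁻¹⁰ of turnover), a property the test suite asserts at
10⁻⁶. Backward Euler is unconditionally stable; its first-order damping
costs under 2% of diel amplitude at 10-minute substeps, which the analytic
column test pins down.

### Metabolic heat

Per-egg sources follow the field-standard three-step chain, on an hourly
step: (1) integrate a development-rate curve $r(T)$ over the proxy
temperature to get maturity $m(t) \in [0, 100]\%$; (2) evaluate reference
heat production at 29.5 °C, $h(m) = h_{max}(e^{bm/100}-1)/(e^b-1)$ mW per
embryo; (3) rescale to the current temperature with a Q10 factor
$Q_{10}^{(T-29.5)/10}$. In the coupled simulation the proxy is the
simulated centre-egg temperature of the *previous* hour — a one-step lag
that avoids implicit coupling while preserving the feedback between clutch
warmth and metabolism. A supplied measured series can replace it
(validation mode), and a temperature-dependent Q10 derived from the rate
curve (`q10_from_rate()`) is available in place of the scalar.

Mortality gating follows excavation categories: hatched/pipped and
full-term-dead eggs heat for their whole incubation, pre-term-dead eggs
stop at two-thirds of development, undeveloped eggs never heat; positions
are assigned randomly under a seed. Gating can only remove energy relative
to the all-viable ("unadjusted") model.

**Default parameters and why.** The development curve is an asymmetric
Gaussian with peak 2.2%/day at 33.5 °C (widths 9 °C below, 3.5 °C above).
The peak temperature sits in the 33–34 °C band reported for flatback
embryos; the asymmetry encodes the observed decline of development rate at
supra-optimal nest temperatures, which is what makes hot nests hatch
*later* than slightly cooler ones. The amplitude gives incubation durations
of ~48–53 days at typical nest temperatures and completes development
within 80 days anywhere in the viable 25–36 °C range. The heat-curve
amplitude $h_{max} = 70$ mW and shape $b = 3.5$ were calibrated once on the
reference nest so that a 51-egg clutch shows centre-minus-adjacent warming
of ≈ 0.0 / 0.6 / 3.3 °C over the three trimesters — the qualitative pattern
and magnitude reported for real flatback nests (no detectable first-trimester
warming, ~3 °C late warming) — and then frozen. Q10 defaults to 2.0, a
mid-range value for reptilian embryonic metabolism. All of these are
configuration entries, not constants.

### Developmental outcomes

Each egg's own hourly centre temperature drives three predictions:

* **Duration**: first hour at 100% maturity, in days.
* **Sex**: the Hill reaction norm places the logit of the male proportion
  linear in log temperature, pivotal at $P$; with $P = 30.3$ °C and
  $S = -0.01$ its 5%/95% transitional range is 29.4–31.2 °C. The
  log-temperature placement was verified by checking that it reproduces the
  published transitional range from these parameters, where a linear-scale
  variant does not. The default input is the mean temperature over the
  thermosensitive period (maturity 33.3–66.7%); an hourly-averaged variant
  (`sex_aggregation = "hourly"`) is provided because published per-nest sex
  ratios are not always reproducible from window means alone, and neither
  mode is asserted to reproduce them.
* **Hatching success**: a logistic in mean incubation temperature with its
  inflection at 32.7 °C, the temperature above which hatchling mortality
  rises sharply in multispecies compilations. The published slope is not
  available, so the default β = 0.8 °C⁻¹ was chosen to give a transition a
  few degrees wide, consistent with the graded hatching-success declines
  those compilations show; β is a configuration value.

`predict_outcomes()` also reports the single "sand proxy" prediction from
the adjacent series plus the conventional +0.5/+1.0/+1.5 °C corrected
variants, so the per-egg model can be compared with correction-factor
practice.

## The synthetic boundary generator

No field series ship with the package; `boundary_scenario()` +
`generate_boundaries()` produce hourly series with the minimal structure
the analysis assumes: a seasonal warming trend, a depth-damped and
depth-delayed diel cycle, and stationary AR(1) noise,

$$T(z,t) = T_0 + \beta t + A_0 e^{-\Delta z/D} \sin(\omega t + \phi - \Delta z/D) + \varepsilon_t.$$

Defaults (55 days, 30 °C base, +0.07 °C/day, 2.5 °C diel amplitude at
10 cm, noise sd 0.15 °C with AR(1) 0.8) put clutch-depth temperatures in
the low-to-mid 30s rising a few degrees over the season — an early-season
nest at a hot summer beach. `simulate_observed()` closes the loop by
running the forward model and re-emitting what the loggers would have
recorded (base/centre/top of clutch plus the two boundary loggers), with
Gaussian logger noise of 0.2 °C (large logger) and 1.0 °C (small loggers).

What the generator deliberately does *not* emulate: rainfall events, tidal
pulses, sand accretion or erosion above the nest, and moisture transients
(field moisture was stable through the season). Tests passing on synthetic
data therefore demonstrate that the pipeline recovers what the model
imposes under the stated statistical structure — not that the model matches
any particular beach.

## Problem sizes and numerical choices

The reference simulation (51 eggs, 60 cm, 55 days) runs on a
35 × 35 × 33-cell graded grid (~40k cells, 2 cm at the clutch) with 1-hour
backward-Euler steps: about half a minute on one core. Halving the cell
size moves the centre-egg temperature by less than 0.05 °C on the reduced
convergence scenario the test suite runs (an 8-egg nest over one day). The
analytic checks use a 150-cell 1-D column (diel damping, 10-minute
substeps) and a 31³ uniform block (steady point source against the
$P/4\pi k r$ far field with the analytic profile imposed on the boundary).
Ties in probe selection and logger placement go to the lowest egg id;
degenerate inputs (over-saturated sand, infeasible packings, grids too
coarse to see an egg, all-Neumann boundaries) are rejected with errors
rather than repaired.

## Known limitations

* Conduction only: no moisture-coupled heat transport, evaporation or
  convection in pore air; boundary series are assumed to absorb surface
  physics.
* One proxy drives the metabolic schedule for the whole clutch (as in the
  field-standard calculation); per-egg heat fluxes would differ across the
  clutch's internal gradient.
* Dead embryos stop heating instantly at their category cutoff; residual
  metabolism and microbial decomposition heat are not modelled.
* The development, heat and hatching-success curves are pluggable defaults
  calibrated to published qualitative anchors, not fitted physiological
  models for any one population — replace them with fitted parameters
  before drawing biological conclusions for a specific rookery.

## A worked run

```{r run, eval = FALSE}
cfg <- make_reference_nest(seed = 42)
sim <- simulate_nest(cfg)
sim$outcomes$summary
write_artifacts(sim, "run1")
```

The summary reports per-clutch means of duration, female probability and
hatch probability; `sim$outcomes$eggs` holds the per-embryo table, and
`write_artifacts()` persists the configuration (with hash), per-egg
temperatures, flux schedule and predictions so the run is reconstructable
byte-for-byte.
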