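---
title: "Models and methods behind magnetocapture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magnetocapture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnetocapture)
```

This vignette documents the physical models, the statistical conventions,
and the deliberate design choices in `magnetocapture`. The package chains
four layers: a magnetostatic field model, a single-cell magnetics model, a
Monte-Carlo capture simulator, and a summary-statistics toolkit with
matching synthetic-data generators.

## The field model

The magnet is an axially magnetized NdFeB cylinder, radius `R` (default
4 mm), length `L`, remanence `Br`. For a uniformly magnetized cylinder the
external field is exactly that of two uniformly charged disks on the pole
faces (the equivalent-surface-charge model). We evaluate it in closed form
with Bulirsch's generalized complete elliptic integral `cel`, which is
fast, mesh-free, and exact to machine precision — the test suite checks 50
random exterior points against an independent brute-force quadrature of the
two disks and sees relative errors at the 1e-15 level, and verifies
`div B = 0` at sampled points. A finite-element solution of the same
geometry would add discretization error and a mesh dependency for no gain
at this geometry, which is why the analytic route was chosen.

Choices worth knowing about:

* **Magnet length.** Only the 8-mm diameter and the 600-mT surface field of
  the bench magnet are specified; the length is not. We default to
  `L = 8 mm` (1:1 aspect, the common stock shape for such cylinders) and
  expose it. All derived numbers in the documentation state this `L`.
* **Calibration.** "600 mT at the surface" is ambiguous because the ideal
  uniformly magnetized cylinder diverges logarithmically at the pole-face
  edge, where the real maximum sits. `magnet_spec()` therefore calibrates
  `Br` so the *face-center* field equals the target (the default,
  `Br = 2 B_0 sqrt(L^2+R^2)/L = 1.3416 T` for 600 mT), with a `"flank"`
  alternative that pins the field just outside the edge instead. The edge
  singularity is handled by a 0.1-mm exclusion margin: evaluations inside
  it are clamped to the margin and flagged.
* **Gradient.** Central differences with step `h = 1e-6 m` on the exact
  field; the on-axis analytic derivative agrees to well under 0.5%. The
  stencil must stay outside the magnet body, which is enforced.

## Cell magnetics

A labeled cell (diameter 6–36 µm, mean 19.3 µm; elemental iron
21.77 ± 3.62 pg per cell) is modelled as a rigid sphere with a point dipole
at its center. The iron mass converts to magnetite by the molar-mass factor
231.53 / (3 × 55.845) = 1.382, to volume by the magnetite density
5180 kg/m³, and to a saturated moment by the saturation magnetization
4.8e5 A/m: the mean cell carries about 2.79e-12 A·m². Intracellular SPIO is
actually distributed as a shell of ~500-nm vesicles; collapsing it to a
point dipole errs by order (cell radius / working distance)² ≈ 1e-4 here,
which we ignore.

The force is the standard saturated point-dipole form
`F = m(|B|) grad|B|`, with the moment aligned to the local field. In the
0.1–0.6 T working range the 62-nm SPIO particles are essentially saturated
(the Langevin factor exceeds 0.999), so the `"saturated"` model is the
default; the `"langevin"` model is available when low-field behavior
matters. Overdamped Stokes drag closes the force balance:
`v_drift = F / (3 pi eta d)`. The mean cell in a 100 T/m magnitude gradient
drifts at about 1.5 mm/s in water-like medium (`eta` = 1.0 mPa·s, density
1000 kg/m³, cells treated as density-matched so gravity and buoyancy drop
out). Particle inertia is negligible (Stokes number « 1 at every velocity
considered), which justifies first-order kinematics.

## The capture simulator

The bench experiment perfuses a 2.3-mm-ID, 20-mm quartz tube at mean
velocities of 4, 20, 100 and 500 mm/s with the magnet pressed against the
outer wall (1.0-mm wall, so the pole face sits 1 mm from the lumen — the
"working height" at which the field is ~0.45 T). The simulator realizes
exactly that geometry: tube axis along x, magnet below at the midsegment,
axis perpendicular to the tube. The magnet's orientation is not otherwise
specified by the bench description; perpendicular-with-tangent-pole-face is
the only arrangement consistent with the 1-mm working distance.

Per cell, the kinematics `dx/dt = v_flow + v_drift` are integrated with an
adaptive Cash–Karp Runge–Kutta 4(5) pair (relative tolerance 1e-6, absolute
1e-9 m), with steps additionally capped at 0.25 mm of displacement so wall
events cannot be skipped. Events are located on the step chord by
bisection, and an outlet crossing that precedes a wall contact within the
same step takes priority. The flow is undisturbed Poiseuille
(`v = 2 vbar (1 - (rho/R_t)^2)`); at 5e4 cells/ml the suspension is dilute
enough that cell–cell interactions and flow perturbation are neglected.

Capture semantics: a cell is captured at its first wall contact whose
contact point lies within the magnet footprint (lateral distance from the
magnet axis up to one magnet radius beyond the pole face, i.e. `2R`) on the
magnet-facing side; it is then absorbed. Contacts elsewhere do not stick —
the cell slides along the wall with the tangentially projected velocity
(midpoint rule, re-clamped to the wall curvature) until it is released,
enters the footprint, or exits. This avoids modelling adhesion, for which
no parameters exist. Inlet positions are flux-weighted over the inlet disc;
diameters and iron loads come from the population laws; all randomness is
drawn on the R side under the user's seed, so a fixed seed reproduces the
result bit for bit.

The closed-form check: with a uniform force and plug flow the capture
fraction over uniformly distributed inlet heights is
`min(1, u L / (v H))` for drift `u`, tube length `L`, gap `H`. The
simulator run in that configuration (midplane, uniform-gradient stub
source) matches this slab formula to well under 1%, and the fate boundary
height matches the analytic threshold.

What the simulator deliberately does **not** model: the bench experiment
recirculated 20 ml of suspension through the tube with a syringe pump,
whereas the simulator is single-pass; adhesion strength, re-entrainment,
and cluster formation are excluded; there is no in-vivo hemodynamics or
vessel-network geometry. Simulated CE values are therefore comparable to
bench values in trend and order of magnitude — a monotone decline with
velocity, high capture at 4 mm/s collapsing more than tenfold by 500 mm/s —
not digit-for-digit. The test suite asserts exactly that qualitative
contract (strict monotone decline, >10-fold drop, 2000 cells per velocity)
and nothing stronger.

## Statistics on summary tables

Experiments of this kind print every measurement as mean ± SD with n, so
the toolkit operates on those summaries directly; the raw-replicate path
gives identical answers whenever replicates realize the same moments (an
algebraic identity, tested as such).

* **Student t** is the pooled-variance form (`df = n1 + n2 - 2`). Whether
  the original SPSS analysis pooled or used Welch cannot be determined from
  a summary table; pooled is the textbook default and Welch is available
  behind `welch = TRUE`. All p values are two-sided.
* **ANOVA + LSD.** One-way ANOVA on the group summaries; Fisher LSD
  pairwise t on the pooled within-group mean square, uncorrected for
  multiplicity. The lack of correction mirrors LSD usage and is a known
  limitation, not an endorsement.
* **Pearson on the CE–velocity data** uses all 12 replicate points
  (4 velocities × triplicate). That is the only reading under which the
  printed significance is attainable — correlating the 4 means alone gives
  p ≈ 0.23. On the 12 summary-mean points `r = -0.772`, p = 0.0033.
  A caution established while validating: with this x design
  ({4, 20, 100, 500}, extreme leverage, tied triplicates) a permutation
  test of r gives a p an order of magnitude smaller than the t-based one;
  the two agree closely only for near-normal designs (where the suite
  checks the agreement across seeds). The t-based p is what summary-table
  reconstruction can support, and is what the package reports.

## Synthetic data

The generators invert mean ± SD reporting: `sample_group_replicates()`
draws per-group normal replicates (truncated at zero for count-like
measures), and `sample_cell_population()` draws cell diameters from a
truncated normal on [6, 36] µm around 19.3 µm and iron loads from a
truncated normal above zero around 21.77 ± 3.62 pg. The diameter SD is not
reported anywhere; 5 µm is adopted as a realistic spread for cultured MSCs
in suspension and is configurable — no claim is made of matching the true,
unreported shape. Truncation shifts the diameter mean by ~0.04 µm, far
below the sampling error at the sizes used.

`generate_retention_experiment()` emulates the sex-mismatched qPCR
retention assay: per-animal detected-cell counts with lognormal noise
(counts are positive and right-skewed; CV 0.3 by default) around a base
retention and `fold` times it, with 1e6 cells infused per animal. The base
retention is not printed as a number; 10% of the infused dose at 24 h is
adopted as the typical early-retention scale for intravascular delivery.
Because the estimator is a ratio of group means, its expectation carries a
small positive bias of order CV²/n (~1.5% at the defaults), well inside the
5% recovery tolerance the suite verifies over 1000 seeded experiments.

Null designs give a calibrated 5% type-I error for the pooled t (checked
over 10,000 draws), so power statements made with these generators are
trustworthy at the effect sizes involved.

What passing these tests shows — and does not show — about real data: the
generators reproduce the *reported moments* and the stated bounds, not the
unpublished raw distributions; agreement of reconstructed statistics with
printed ones validates the arithmetic chain, not the original measurement.

## Problem sizes and runtime

Defaults were chosen so the full suite runs comfortably on a laptop core:
2000 cells per velocity for the capture sweep (Monte-Carlo SE on CE under
1.2 percentage points), 1000 seeded experiments for the retention
recovery, 10,000 draws for the type-I calibration. The compiled trajectory
core integrates the full 4-velocity sweep in a few seconds.

## Known limitations

* Single-pass flow versus the recirculating bench loop (above): simulated
  CE is a trend-level, not a point-level, reproduction.
* The ideal-magnet edge singularity is clamped rather than resolved; field
  values within 0.1 mm of the pole-face edge are approximate by
  construction and flagged.
* The point-dipole cell ignores the SPIO shell geometry and any
  intracellular redistribution or label dilution over divisions.
* LSD post hoc is uncorrected; treat borderline pairwise calls accordingly.
* The capture criterion (absorb on first in-footprint wall contact) brackets
  adhesion physics it does not model; re-entrainment at high shear would
  lower high-velocity CE further.
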