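# magnetocapture

Magnetic targeting of stem-cell therapy delivers superparamagnetic iron
oxide (SPIO) labeled mesenchymal stem cells ("MagMSCs") to an injury site by
holding a permanent magnet next to the vessel the cells flow through.
Whether that works hinges on a quantitative chain: the field of the magnet,
the moment it induces in a labeled cell, the resulting attraction force
against viscous drag, and the fraction of flowing cells that reaches the
wall before being swept past. `magnetocapture` implements that chain for the
canonical bench configuration — an 8-mm NdFeB cylinder (600 mT at the pole
face) pressed against a 2.3-mm-ID tube perfused at 4–500 mm/s with cells
carrying ~21.8 pg iron each — together with the statistical toolkit used to
analyze such experiments from summary tables.

## What it computes

**Field model.** An axially magnetized cylinder of radius $R$, length $L$
and remanence $B_r$, solved exactly by the equivalent-surface-charge model
(two oppositely charged disks) via Bulirsch generalized complete elliptic
integrals. On the axis, at height $z$ above the pole face,

$$B_z(z) = \frac{B_r}{2}\left[\frac{z+L}{\sqrt{(z+L)^2+R^2}} -
\frac{z}{\sqrt{z^2+R^2}}\right],$$

which also calibrates $B_r$ from a measured surface field.

**Cell magnetics.** An SPIO-labeled cell is a point dipole whose magnetite
load derives from its elemental-iron mass
($m_{\mathrm{Fe_3O_4}} = 1.382\, m_\mathrm{Fe}$, density 5180 kg/m³,
saturation magnetization $4.8\times10^5$ A/m), giving the saturated moment
$m_{sat}$ (optionally a Langevin field dependence). The force is
$\mathbf{F} = m(|B|)\,\nabla|B|$ and the overdamped drift velocity
$\mathbf{v} = \mathbf{F}/(3\pi\eta d)$ (Stokes drag).

**Capture simulation.** A Monte-Carlo simulator releases cells at the tube
inlet (flux-weighted positions, diameters and iron loads drawn from the
population laws), integrates $\dot{\mathbf{x}} = \mathbf{v}_{flow} +
\mathbf{v}_{drift}$ with an adaptive Runge–Kutta scheme through the 3-D
field of the laterally placed magnet, and scores each cell captured ($Q_1$,
first wall contact within the magnet footprint) or escaped ($Q_2$),
yielding the capture efficiency $CE = 100\,Q_1/(Q_1+Q_2)$.

**Statistics.** Pearson correlation, pooled-variance Student t, one-way
ANOVA with Fisher LSD post hoc — all operable directly on mean ± SD / n
summaries as printed in Results tables — plus the derived metrics
(fold ratio, relative MRI signal intensity, retention rate, capillary
density) and seeded synthetic-data generators that invert mean ± SD
reporting back into replicates.

## Worked example

```r
library(magnetocapture)

mag <- magnet_spec()        # 8 mm x 8 mm cylinder calibrated to 600 mT
round(on_axis_field(c(0, 1e-3, 2e-3), mag), 4)
#> [1] 0.6000 0.4503 0.3228      # tesla at the face, 1 mm, 2 mm

simulate_capture(2000, flow_spec(4e-3), seed = 1)      # slow venous-like flow
#> Capture simulation: n = 2000, Q1 = 1991 captured, Q2 = 9 escaped
#>   CE = 99.5% (MC SE 0.15%)
simulate_capture(2000, flow_spec(500e-3), seed = 1)    # fast arterial-like flow
#> Capture simulation: n = 2000, Q1 = 44 captured, Q2 = 1956 escaped
#>   CE = 2.2% (MC SE 0.33%)

# inference straight from printed summaries (photon counts, n = 6 each)
two_sample_t(group_summary("Mag", 26222, 5102, 6),
             group_summary("NonMag", 9620, 1930, 6))
#> Pooled two-sample t: t = 7.455, df = 10, p = 2.172e-05

# capture efficiency vs velocity, 4 velocities x triplicate
pearson_test(rep(c(4, 20, 100, 500), each = 3),
             rep(c(85, 68.7, 11.3, 1.6), each = 3))
#> Pearson correlation: r = -0.7721, df = 10, p = 0.003253
```

At 4 mm/s nearly every cell drifts to the wall within its residence time
(drift near the wall is a few mm/s, comparable to the flow), while at
500 mm/s only the near-wall sliver is caught — a >10-fold CE decline across
the velocity sweep. `reproduce()` re-runs all the summary-table checks in
one call and reports a pass/fail table.

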