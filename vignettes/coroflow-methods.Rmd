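---
title: "Quantifying coronary hemodynamics: WSS descriptors, helical flow and morphometry"
author: "coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying coronary hemodynamics: WSS descriptors, helical flow and morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroflow)
```

## Scope and model

Disturbed near-wall shear and the organization of intravascular helical
flow are established mechanistic correlates of atherosclerosis
localization in coronary arteries. `coroflow` post-processes
time-resolved CFD results — a wall shear stress (WSS) vector series on a
triangulated lumen surface and a velocity series on a tetrahedral lumen
volume, both covering one cardiac cycle of period $T$ — into the
standard scalar descriptors used to compare vessels and populations
(e.g. human vs swine cohorts, grouped by RCA/LAD/LCX vessel type), and
provides the nonparametric group comparison itself.

The four near-wall descriptors are defined per surface node from the WSS
vector $\mathbf{w}(t)$ and outward unit normal $\mathbf{n}$:

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\mathbf{w}|\,dt, \qquad
\mathrm{OSI} = \frac{1}{2}\left[1 -
  \frac{|\int_0^T \mathbf{w}\,dt|}{\int_0^T |\mathbf{w}|\,dt}\right],$$

$$\mathrm{RRT} = \left[\frac{1}{T}\left|\int_0^T \mathbf{w}\,dt\right|\right]^{-1}
 = \frac{1}{\mathrm{TAWSS}\,(1 - 2\,\mathrm{OSI})}, \qquad
\mathrm{transWSS} = \frac{1}{T}\int_0^T
  \left|\mathbf{w}\cdot\left(\mathbf{n}\times\hat{u}_{\mathrm{mean}}\right)\right| dt,$$

with $\hat{u}_{\mathrm{mean}}$ the unit cycle-mean WSS vector. OSI lies
in $[0, 0.5]$ (0 for a fixed direction, 0.5 for a vanishing temporal
mean); RRT is computed through the mean-vector form, which is
algebraically identical to the first form wherever both are defined.

Intravascular helical flow is quantified by the helicity density
$\mathbf{v}\cdot\boldsymbol{\omega}$ of velocity and vorticity. Local
normalized helicity $\mathrm{LNH} = \cos\gamma$ (the cosine of the angle
between $\mathbf{v}$ and $\boldsymbol{\omega}$) separates right- and
left-handed patterns; the four bulk descriptors are space-time averages
over the lumen volume $V$:

$$h_1 = \frac{1}{TV}\int_T\!\!\int_V \mathbf{v}\cdot\boldsymbol{\omega}\;dV\,dt,
\quad h_2 = \frac{1}{TV}\int_T\!\!\int_V |\mathbf{v}\cdot\boldsymbol{\omega}|\;dV\,dt,
\quad h_3 = \frac{h_1}{h_2}, \quad h_4 = \frac{|h_1|}{h_2}.$$

$h_2 \ge |h_1|$ always; $h_3 \in [-1, 1]$ and $h_4 = |h_3|$ measure the
signed and unsigned balance of counter-rotating helical structures.

Morphometry derives from a smooth analytic centerline $\mathbf{C}$:
curvature $\kappa = |\mathbf{C}'\times\mathbf{C}''|/|\mathbf{C}'|^3$,
torsion $\tau = [(\mathbf{C}'\times\mathbf{C}'')\cdot\mathbf{C}''']
/|\mathbf{C}'\times\mathbf{C}''|^2$, the distance metric (tortuosity)
$DM = L/l \ge 1$ (curve length over endpoint chord), and the
cross-section shape index $SI = d/D \in (0,1]$ (minimum over maximum
section diameter; 1 = circular). Both formulas are invariant to the
curve parametrization, so they are evaluated directly in the fit
parameter with no arc-length reparametrization; arc length is used only
to place evaluation stations.

## Numerical choices

**Time quadrature.** All cycle integrals use the trapezoidal rule on the
(possibly non-uniform) sample grid with *periodic closure*: when the
samples stop short of $T$, the interval back to the $t = 0$ sample is
appended. This is second order for smooth signals (doubling the
resolution reduces the error $\approx 4\times$, verified in the tests)
and requires no assumption beyond periodicity.

**Node-based maps, lumped area weights.** Descriptor maps live on mesh
nodes (the common CFD export convention). Per-vessel reduction weights
each node by one third of its incident triangle areas; both the
area-weighted mean (default) and the sort-and-accumulate weighted median
are available, since the spatial reduction behind per-vessel published
values is generally unstated.

**Masking, not fabrication.** OSI is masked where
$\int|\mathbf{w}|dt < 10^{-12}\times$ the mesh maximum; RRT and transWSS
where the cycle-mean WSS vector is similarly degenerate (RRT diverges
and the mean direction is undefined there). LNH is set to 0 and masked
where $|\mathbf{v}||\boldsymbol{\omega}| < 10^{-12}\,
\max|\mathbf{v}|\max|\boldsymbol{\omega}|$ — stagnation is genuine in
pulsatile flow. $h_3, h_4$ are reported as `NA` when $h_2 = 0$ (the
ratios are 0/0); a purely axisymmetric parallel flow such as Poiseuille
flow is the canonical case.

**Vorticity reconstruction.** Velocity gradients are computed per
tetrahedron from the P1 (linear) shape functions, curled, and averaged
to nodes with cell-volume weights. This is exact for fields linear in
space (rigid rotation, uniform shear) and first-order convergent at
interior nodes otherwise; boundary nodes average one-sided cells and are
flagged lower-accuracy (`interiorNodes()`). The volume integral of
helicity density uses the cell-centroid midpoint rule, exact for P1
integrands — consistent with the element order.

**Centerline fitting.** Raw centerline points (from any extraction tool)
are fitted per coordinate by cubic least-squares B-splines on a shared
chord-length parameter. The interior knot count (0..`maxInteriorKnots`,
default 10) is selected by corrected AIC over uniform knot layouts; the
selected layout's knot positions are then refined by bounded Nelder-Mead
from the uniform start. Optimizing positions only for the selected count
keeps the sweep cheap without changing the selection in practice. A
length-1024 parameter-to-arc-length table supports station placement;
curve length for $DM$ uses adaptive quadrature of $|\mathbf{C}'|$
(relative tolerance $10^{-12}$). Torsion is masked where
$|\mathbf{C}'\times\mathbf{C}''| < 10^{-8}|\mathbf{C}'|^3$ (its formula
divides by that quantity); a straight vessel reports mean torsion 0 with
an explicit `torsionUndefined` flag. Note one structural limit: a curve
that is polynomial in *its own* parameter is generally not polynomial in
chord length, so exact cubic reproduction holds only when the two
parametrizations are affinely related (e.g. collinear points); for
generic smooth curves the fit converges with knot count, and a full
helix turn needs on the order of 20 interior knots for sub-percent
curvature profiles.

**Cross-section slicing.** At stations uniform in arc length — excluding
a 5% end margin by default, where any regression spline is least
reliable — the surface is cut by the plane normal to the tangent; the
connected intersection loop nearest the centerline point is kept. $d$ is
the minimum caliper width of the loop's convex hull and $D$ the maximum
vertex-pair distance, which reduce to the minor/major axes for
elliptical sections and stay well defined for irregular lumens. Stations
that miss the surface are skipped with a warning. 100 stations is the
default; means are insensitive to this beyond ~50.

**Group statistics.** Two-sided Mann-Whitney U per descriptor x vessel
type, exact by full enumeration when samples are tie-free and
$\binom{n_1+n_2}{n_1} \le 2\times 10^5$, otherwise the normal
approximation with continuity and tie corrections (a fully tied pooled
sample returns $p = 1$). Medians and IQRs use the linear-interpolation
(type-7) percentile convention. Two-sided testing is assumed, and **no
multiple-testing adjustment** is applied across the 15 descriptors x 3
vessel grid — the report carries an explicit note; this mirrors the
raw-p convention of comparative hemodynamics studies and is reproduced,
not endorsed.

## The synthetic vessel generator

Because patient/animal CFD datasets are not redistributable, the package
generates its own ground-truth inputs:

* **Geometry.** Tubes swept along parametric centerlines (straight
  segments, arcs, circular helices, perturbed helices) with elliptical
  sections of radius $r(s)$ and eccentricity $e(s) \in (0,1]$.
  Cross-sections ride on rotation-minimizing frames (double-reflection
  method) rather than Frenet frames, which are undefined on straight
  segments and flip at inflections. A guard rejects specs with
  $\max\kappa \cdot \max(\text{semi-axis}) \ge 1$ (folding sections).
  Prisms between stations are split into tetrahedra with diagonals
  through the smallest global node index, which keeps faces conforming
  across slabs. Geometry is in mm (clinical convention) and converted to
  SI inside the integral operators.
* **Flow.** Plug or parabolic axial profiles (centerline speed $U$) plus
  rigid-body swirl $\Omega$ (optionally varying along the vessel to
  create counter-rotating helical structures), all modulated by a
  periodic waveform. The default waveform is a two-harmonic strictly
  positive multiplier, $T = 0.8$ s and 40 samples per cycle — a generic
  cardiac-like pulsatility; real inlet waveforms vary per subject and no
  claim of waveform realism is made. Closed-form vorticity
  ($2\Omega$ axial plus $2U\rho/R^2$ azimuthal for the parabolic
  profile) is attached for straight tubes as a discretization oracle.
  The analytic wall shear for the parabolic profile is
  $2\mu U/R_{loc}$ along the local axis — the Poiseuille closed form
  under the centerline-speed convention used throughout — plus a
  synthetic azimuthal component $\mu\Omega$, each scaled by the
  waveform (the azimuthal scaling can be phase-shifted to make the WSS
  direction rotate over the cycle, producing nonzero OSI/transWSS).
* **Cohorts.** Descriptor tables for two species x three vessel types
  are sampled log-normally, parameterized by target median $m$ and
  multiplicative spread ($x = m\,e^{\sigma Z}$), because the descriptors
  are positive and right-skewed; signed descriptors ($h_1$, $h_3$) keep
  the sign of their median. Default medians are set to physiologically
  plausible coronary values with realistic species contrasts (higher
  OSI and inflow pulsatility in swine LAD, higher helicity intensity in
  human RCA/LCX, more eccentric human sections).

What the generator does *not* emulate: non-Newtonian rheology, branch
flow splits, wall compliance, image-segmentation noise, or
subject-specific waveforms. Passing tests therefore demonstrate that the
descriptor operators are correct on fields with known structure — not
that any physiological claim transfers to real vessels.

## Problem sizes and reproducibility

The demo pipeline (`demoConfig()`: 2 species x 3 vessel types x 6
vessels) uses 16 circumferential x 20 axial x 3 radial meshes and 16
time samples per cycle — a full run takes well under a minute and every
draw flows from a single seed, so the same config + seed reproduces all
CSV/JSON outputs byte for byte. Validation suites use finer meshes where
a convergence order is being measured (2-3 level refinement ladders).
For real data, resolution is whatever the CFD export provides; the
operators are linear in mesh size and 10^5-node surfaces are unproblematic.

```{r demo, eval = FALSE}
res <- runPipeline(demoConfig(), seed = 1, outDir = "coroflow_out")
head(reportTable(res$comparison))
```

## Known limitations

* Vorticity at boundary nodes is one-sided and less accurate; bulk
  integrals dilute this but thin meshes (1-2 radial rings) bias $h_1,
  h_2$ by a few percent.
* The shape index assumes the slicing plane cuts a single loop near the
  centerline; pathological geometries (kissing walls, near-closed bends)
  would need centerline-aware clipping.
* The exact Mann-Whitney branch requires tie-free data; heavily
  discretized descriptors fall back to the corrected normal
  approximation.
* Free-knot refinement uses a local simplex search from a uniform start;
  strongly non-uniform optimal knot layouts (abrupt curvature bursts)
  may need a larger `maxInteriorKnots` instead.
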