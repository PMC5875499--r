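---
title: "Designing modulated electron bolus: model, operators and numerical choices"
author: "mertbolus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing modulated electron bolus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mertbolus)
```

## The problem

Electron beams treat superficial targets: dose builds up to a maximum a few
centimeters under the skin and then falls off steeply, sparing everything
deeper. The planner picks an energy and applicator so that a high isodose
surface — conventionally 90% of the prescription — covers the deepest
(distal) aspect of the planning target volume (PTV). With a flat bolus the
90% surface is roughly a plane, so wherever the distal PTV surface is not a
plane, tissue beyond the target is carried to full dose. Modulated electron
radiation therapy (MERT) with a thickness-modulated bolus bends the 90%
surface onto the distal PTV surface: where the target is shallow the bolus
is thick, where it is deep the bolus is thin. A 3D printer turns the
designed thickness map into a solid PLA part that sits on the skin.

## The design model

All geometry is ray-parametric. A virtual point source sits on the beam
axis at the source-axis distance (SAD, default 1000 mm). Bolus thickness is
represented on a **design grid** in the plane that contains the isocenter
and is perpendicular to the central axis (2.5 mm spacing by default,
covering the applicator projection plus a 10 mm margin). One divergent ray
connects the source to each grid point.

For a ray that intersects the PTV, let $T_2$ be the distal PTV depth and
$T_1$ the distal depth of the 90% isodose surface in the current dose
distribution. The shift of bolus thickness (SBT) at grid point $p$ is the
water-equivalent length of the gap, scaled to bolus material:

$$\mathrm{SBT}_p \;=\; \frac{1}{\mathrm{CET}(\mathrm{bolus})}
  \int_{T_2}^{T_1} \mathrm{CET}(z)\, dz ,$$

where $\mathrm{CET}(z)$ is the coefficient of equivalent thickness at depth
$z$ — the local density relative to water, obtained from a piecewise-linear
HU-to-density table. A positive SBT (isodose deeper than the target) adds
bolus; a negative SBT thins it. On a no-bolus first pass every PTV ray has
a positive SBT, because the plan is set up so the 90% surface covers the
distal PTV. Thickness is accumulated along the diverging ray — not the beam
axis — and clamped at zero (a physical bolus cannot be negative; a 40 mm
printability cap is also applied, with a warning).

The CET-as-density approximation is the method's central simplification:
it scales depth correctly through slab-like heterogeneity but ignores
scatter perturbations at lateral interfaces. The iteration absorbs the
residual: each pass recomputes the dose with a full engine and corrects the
remaining gap.

## The five regional operators

The raw SBT map conforms the isodose but ignores secondary effects; five
operators run in a fixed order after each SBT estimate. Three are regional
Gaussian smoothings on the design grid, acting on points $p$ of a region of
interest with neighbors $q$ at distance $r_{pq} < SF$ and weights
$w_q = \exp(-r_{pq}^2 / 2 SF^2)$ ($SF$ = smoothing factor, 5/10/20 mm for
low/medium/high; default 10):

* **mode 1** replaces the value entirely:
  $\mathrm{SBT}_p \leftarrow \sum_q w_q \mathrm{SBT}_q / (1 + \sum_q w_q)$
  (the constant 1 in the denominator pulls toward zero — appropriate when
  the region's own values are unreliable);
* **mode 2** blends the point with its neighbors:
  $\mathrm{SBT}_p \leftarrow (\mathrm{SBT}_p + \sum_q w_q \mathrm{SBT}_q) /
  (1 + \sum_q w_q)$ (preserves constant fields exactly).

1. **Hot-spot smoothing** (mode 1): voxels above 110% of prescription are
   projected along their rays onto the design grid and smoothed; no action
   when the maximum dose is below 110%.
2. **Coverage smoothing** (mode 2): PTV voxels below 90% project to a
   region whose (negative) values are kept, while an annulus of width $SF$
   around it is smoothed with neighbors drawn from region plus annulus —
   thinning must extend somewhat beyond the projected cold spot to be
   effective. The annulus width is a package choice; the construction only
   requires "somewhat beyond".
3. **Irregularity smoothing** (mode 2): cells whose central-difference
   gradient magnitude exceeds twice the grid mean are smoothed; re-applied
   up to 3 passes or until nothing is flagged. The pass cap guarantees
   termination; one pass almost always empties the region.
4. **Margin adjustment**: the outer 10 mm border of the PTV projection is
   thinned to counter the reduced lateral scatter near the applicator edge.
   With $\mathrm{Kerf}(x) = \exp(-x^2/2\sigma^2)$ and
   $K_1 = \sigma\sqrt{-2\ln 0.01}$ (the radial distance over which the
   kernel rises from 0.01 to 1, so $\mathrm{Kerf}(K_1) = 0.01$ exactly),
   a point at radial distance $r_{pm}$ outside the border's inner boundary
   is scaled by $1 - \mathrm{Kerf}(\max(K_1 - r_{pm}, 0))$ when its SBT is
   positive and by $1 + \mathrm{Kerf}(\cdot)$ when negative: positive
   shifts shrink (factor in $[0, 1)$), negative shifts deepen (factor in
   $(1, 2]$), and both effects strengthen toward the PTV edge. The kernel
   width defaults to $\sigma = \sqrt{E[\mathrm{MeV}] \cdot
   A[\mathrm{cm}]}$ mm (9.49 mm for 9 MeV, 10 cm), which grows with both
   energy and applicator size and stays commensurate with the 10 mm
   border; it is configurable. $r_{pm}$ is found by marching from $p$
   toward the central-axis projection until the distance-to-edge field
   reaches the border width; when the axis lies outside the PTV projection
   (or the PTV is narrower than twice the border) the nearest-boundary
   distance is used instead, with a warning.
5. **Outside-PTV extrusion**: every grid point between the PTV projection
   and 1 cm beyond the applicator edge copies the SBT value at the first
   PTV-projection cell crossed by the segment from the point toward the
   central axis; beyond that expanded aperture the SBT is zero. The
   operator is idempotent. For projections the radial segment never enters
   (strongly concave shapes), the nearest boundary cell is used, with a
   warning.

## The dose stage

The loop is engine-agnostic: `designConfig(engine = ...)` accepts any
function returning a dose grid, so a clinic can recalculate each iteration
in its planning system and feed the exported dose back in (the CLI's
`dose:` config key does exactly that). For desk-scale work the package
ships a broad-beam surrogate:

* central-axis depth dose per energy $E$: $R_{50} = E/2.33$ cm,
  $R_p = E/2$ cm, $z_{max} = 0.6 R_{50}$, 85% surface dose, 2%
  bremsstrahlung tail; parabolic build-up and a logistic falloff of width
  $(R_p - R_{50})/3$ whose midpoint is solved so that dose($R_{50}$) = 50
  exactly;
* each point is evaluated at its water-equivalent depth (bolus CET path
  plus tissue CET line integral along its ray), multiplied by
  error-function field edges with penumbra $\sigma(z) = 2 + 0.05 z$ mm,
  and renormalized to 100% at the open-field $z_{max}$ on the axis.

The surrogate is deterministic, monotone beyond $z_{max}$ along every ray,
and heterogeneity-aware through the same CET physics the design inverts.
That last property means the loop converges faster on the surrogate than it
would against a Monte Carlo engine (typically one iteration instead of the
clinical one-or-two): passing the convergence tests here demonstrates the
machinery, not clinical performance. Lateral scatter from bolus shape
gradients — the mechanism that creates midline hot spots under strongly
modulated bolus in reality — is off by default; `scatterGain` adds a
minimal version (extra dose proportional to the local thickness deficit
relative to the Gaussian-blurred neighborhood) so the hot-spot operator can
be exercised end-to-end.

Dose is computed on a fan grid (one ray per design point, 0.5 mm radial
step) and resampled to CT voxels trilinearly in fan coordinates; at 2.5 mm
CT resolution the on-axis falloff position is reproduced to better than
0.1 mm.

## Stopping rule

The iteration stops when three conditions hold (all configurable):
V90 $\ge$ 98%, Dmax $\le$ 110%, and the RMS of the residual distal gap
$\le$ 2 mm. The first two quantify "acceptable" coverage and hot-spot
control; the third is the conformity objective itself. The gap is measured
in **water-equivalent** millimeters (the CET-weighted integral the design
acts on) because the geometric crossing depth is ill-conditioned where the
dose gradient collapses — beyond the target inside an air cavity, a dose
difference of 0.1% moves the geometric 90% crossing by centimeters while
the water-equivalent gap stays near zero. It is evaluated over the
**interior** of the PTV projection, excluding the 10 mm margin border,
because the margin operator deliberately trades conformity there for
edge-scatter compensation. A non-improving V90 (two consecutive
iterations) aborts early only while coverage is still below target.

## Synthetic phantoms: what they emulate and what they do not

`wedgePhantom()` reproduces the benchmark geometry of the method's
validation: a 20 × 20 × 20 cm water cube (8000 cm³), a wedge PTV whose
distal surface ramps from 15 to 35 mm depth over an 80 mm square footprint,
and bone (+800 HU) and air (−1000 HU) slabs at 40–55 mm depth distal to the
target. The PTV dimensions and slab placement are package defaults chosen
to sit inside a 12 MeV beam's 90% range — the original study does not print
them. `curvedPhantom()` provides sinusoidal and spherical-cap entrance
surfaces with a surface-following PTV (foot/head analogs).
`pddFixture()` produces depth-dose curves through slab stacks for the CET
calibration (HU values: water 0, bone +800, air −1000, PLA +160 — the PLA
value is measured in the source study, the others are conventional).
Optional Gaussian HU noise (σ = 10 HU, seeded, off by default) adds CT
realism without breaking exact tests.

What passing on these phantoms does **not** show: performance against a
Monte Carlo engine in heterogeneous anatomy, behavior with real RTSTRUCT
contour sets, air gaps between printed bolus and skin, or printability of
the STL beyond watertightness. Those require a planning system and
physical phantoms.

## Numerical choices

* Grids: voxel center of index $i$ (1-based) at
  $\mathrm{origin} + (i - \tfrac12)\,\mathrm{spacing}$; half-open extents.
* Ray–mask intersections: fixed-step sampling at half the smallest voxel
  dimension, bisection refinement of the 0.5 level-crossing of the
  trilinearly interpolated mask to 0.01 mm; "distal/proximal" are per-ray
  last exit / first entry.
* Distal isodose depth: deepest down-crossing of the level, sampling plus
  bisection to 0.05 mm; a dose still at or above the level at the last
  in-grid sample returns no crossing rather than a spurious boundary hit.
* CET line integral: composite midpoint rule, 0.5 mm step — error well
  below print-layer height (0.1–0.3 mm) and within 0.05 mm of a 0.01 mm
  brute-force reference on heterogeneous fixtures. Additivity across a
  split point is exact on smooth paths and $O(\mathrm{step})$ across
  material interfaces (sample placement shifts).
* Smoothing neighborhoods use the strict inequality $r_{pq} < SF$; a point
  is never its own neighbor; a point with an empty neighbor set maps to 0
  (mode 1) or keeps its value (mode 2).
* PTV rays with no isodose crossing in the current dose are flagged and
  filled from the mean of their valid 8-neighbors so one pathological ray
  does not stall the design.
* Bolus CET defaults to 1.119 (the PLA density ratio, self-consistent with
  the 160 HU default table entry); the slab-measured 1.13 can be
  substituted. `cetCalibration` reproduces 1.13 to ±0.01 from
  surrogate-generated slab curves via χ² falloff matching (20–80% window,
  0.05 mm grid with parabolic refinement; shift applied to the reference
  curve, positive = slab curve shallower).
* The solid is a height field over the design grid along the diverging
  rays: inner vertices at ray–skin entry, outer vertices displaced toward
  the source, quad grid triangulated with a vertical skirt; watertightness
  is checked as oriented-edge manifoldness, volume by the divergence
  theorem, voxelization through the same fan construction (exact for this
  geometry, no general mesh voxelizer needed).
* Gamma (3%/5 mm global) searches a disk of radius 3 × the distance
  criterion on the common grid; no sub-grid interpolation, matching the
  exhaustive oracle it is tested against.

## Problem sizes

Unit tests run on 40–60³ voxel slabs at 1–2.5 mm; the end-to-end checks run
the full 20 cm wedge phantom at 2.5 mm (80 × 80 × 88 voxels, 49 × 49 design
grid), where one design iteration — two dose computations, 2401 ray
extractions, the five operators and the mesh build — takes about half a
minute on one core.

## Known limitations

* The surrogate shares the CET approximation with the design; convergence
  against engines with independent scatter physics will be slower and is
  the realistic use case for the external-engine adapter.
* DICOM dialects are not parsed; volumes travel as NIfTI and contours as
  JSON (rasterized with the even-odd rule, axial planar contours only).
* Star-shaped PTV projections are assumed by the radial constructions of
  the margin and extrusion operators; strongly concave projections fall
  back to nearest-boundary rules with warnings.
* Square applicators only; no cutouts, skin collimation or oblique-incidence
  corrections.
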