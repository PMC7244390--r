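---
title: "Methods: simulating M/EEG signal cancelation on folded surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating M/EEG signal cancelation on folded surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `cerebsim`, the choices made
where the design was genuinely open, and the limits of what the synthetic
geometry can show about real anatomy.

## Source model

Neural currents are modeled as current dipoles placed at the vertices of a
triangulated cortical sheet and oriented along the angle-weighted vertex
normals (a fixed-orientation source model). Each vertex carries one third
of the area of its incident faces, so vertex areas tile the surface
exactly. Physiological scaling assumes a current-dipole density of
`q0 = 1 nAm/mm²`, the standard estimate for cortical (pyramidal-cell) and
cerebellar (Purkinje-cell) dendritic currents alike; sensitivity maps use
a 100 nAm dipole, the moment of roughly a 10 mm patch at a conservation
factor of 0.3. All internal geometry is SI (meters); millimeters and nAm
appear only in configurations and reports, which avoids an entire class of
unit mistakes in `q0`-scaled quantities.

## Synthetic anatomy

Real cerebellar tessellations at folia resolution are not generally
available, so the package generates surrogates: a two-scale sinusoidal
height field over a spherical cap,

```
displacement(s) = A_lobule sin(2π s / λ_lobule) + A_folia sin(2π s / λ_folia + φ(seed)),
```

with `s` the arc-length coordinate along one tangential axis of the cap.
This reproduces the geometric mechanism that drives cancelation — opposed
fold walls carrying nearly antiparallel dipoles — at controllable scales.
The default study surfaces, inside an 80 mm inner-skull sphere:

| surface | base radius | cap | folds | edge length |
|---|---|---|---|---|
| cerebellum-like | 55 mm, posterior–inferior | 25° | folia 2 mm / 1 mm + lobules 20 mm / 3 mm | 0.2 mm |
| cortex-like | 70 mm, superior | 60° | single 20 mm / 5 mm scale | 1.2 mm |
| smoothed-shell | 55 mm, posterior–inferior | 25° | lobules 20 mm / 1 mm only | 0.5 mm |

Folia of 2 mm wavelength and 1 mm amplitude give maximal wall tilts of
about 72°, i.e. opposed-wall dipoles roughly 145° apart — strong but not
perfect anti-alignment, as in a height field generally. The mesh edge
length must resolve the folds: generation is refused unless
`edge ≤ λ_folia/10`. The smoothed-shell surrogate mimics an outer-shell
segmentation of the cerebellum, which erases the folia and shows barely
any sulci; we keep a 1 mm lobular undulation rather than a perfectly
smooth cap because an exactly spherical concentric cap would make every
dipole exactly radial and hence exactly silent for MEG, a degenerate case
with an undefined conservation factor.

The cap positions implement the depth disadvantage of the cerebellum (55
vs 70 mm base radius under a 120°-coverage helmet centered on +z), which
the sensitivity tests confirm: mean single-dipole norms on the
cerebellum-like surface are below the cortex-like ones in every modality.

## Head model, sensors, forward engines

The conductor is a concentric three-shell sphere (brain/skull/scalp at
80/85/92 mm, conductivities 0.3/0.006/0.3 S/m). Sensor surrogates are
Fibonacci-lattice caps: 102 MEG sites (one radial magnetometer plus two
orthogonal planar gradiometers with a 16.8 mm two-point baseline, 306
channels total) at 102 mm radius, and 72 electrodes on the scalp sphere
with coverage down to 135° polar angle. Real measured layouts can be
loaded from CSV instead; inferior EEG coverage in particular matters for
cerebellar sensitivity and is a configuration parameter, not a claim.

Three forward engines are provided:

* **Sphere MEG** — the closed-form field of a dipole in a spherically
  symmetric conductor. Radial dipoles and dipoles at the center are
  silent; the tests verify the field against a finite-difference gradient
  of the magnetic scalar potential.
* **Sphere EEG** — a Legendre-series solution for the three-shell scalp
  potential, with per-degree radial transfer factors computed by an
  inward two-coefficient propagation whose quantities stay O(1) at any
  harmonic degree (a naive per-degree linear solve becomes numerically
  singular near degree 130). The series truncates adaptively when three
  consecutive terms contribute less than 1e-8 relative; non-convergence is
  an error, not a silent truncation. With equal conductivities the series
  collapses onto an independently derived closed form (generating-function
  summation) to 1e-6.
* **BEM** — linear collocation on three closed nested boundary meshes:
  per-triangle solid angles with analytically integrated linear shape
  functions, an auto-solid-angle diagonal making constants an exact null
  space, deflation of the singular system, and an isolated-skull treatment
  of the small skull conductivity (solve the insulated-brain problem on
  the inner skull first, then the correction). EEG is read at electrodes
  by barycentric interpolation on the scalp mesh; MEG adds the
  volume-current boundary integral (centroid quadrature) to the primary
  field. On concentric icospheres at subdivision 3 the BEM agrees with the
  analytic engines within 5% relative ℓ2 for both EEG and MEG, improving
  with refinement.

The sphere engine is the default: it is exact, fast, and the Monte Carlo
statistics are ratios of linear functionals of the gain, so the engine
choice does not affect the cancelation mechanism being studied. The BEM
exists for non-spherical conductor surrogates and as the §-style method
check.

## Cancelation statistics and Monte Carlo design

For an active set of `n` columns of a single-modality gain matrix: net
signal `A` (norm of the column sum), absolute signal `B` (sum of column
norms), conservation factor `C = A/B`, and density-scaled norms
`α = A a_n q0 / n`, `β = B a_n q0 / n` with `a_n` the activated area.
Norms are never pooled across modalities (units T, T/m, V differ). EEG
columns are average-referenced before any norm; the reference is an
explicit operator so it can be disabled, and the tests confirm it
annihilates common offsets.

Two designs, 200 samples per grid point by default: *distributed* (uniform
draws without replacement; grid up to `n = 10,000`) and *coherent* (patches
grown around uniform random seed vertices until the summed vertex area
first reaches `π r²` for nominal radius `r`, 1–30 mm by default). Patch
growth adds vertices in rings of increasing shortest-path (geodesic)
distance on the edge graph, ties broken by vertex index — deterministic
given the seed. Patch seeds may repeat across samples (with ≥10⁴ vertices
collisions are immaterial). Patches that exhaust the surface are retained
at their realized area and counted. Normalized curves divide
cerebellum-like means by cortex-like means at equal radius;
`α̃` is defined multiplicatively as `C̃·β̃` so the identity `α = Cβ`
carries to the normalized curves exactly (the direct ratio of mean α,
which differs by a sampling-covariance factor, is reported alongside).
All randomness flows from one seed through documented per-stage child
seeds; reruns are byte-identical.

## Mesh convergence and grid-density invariance

`mesh_convergence_study()` mirrors a source-grid convergence study: a
finely resolved cerebellum-like surface (edge 0.1 mm = λ_folia/20, 10°
cap, ~29,000 vertices) is decimated by geodesic farthest-point sampling to
55% of its vertices with vertex areas reassigned to the nearest selected
vertex (total area conserved exactly). For 20 random 10 mm patches, the
patch region is grown once on the full grid and represented on both grids
at the fixed density `q0`; the relative change of the sensor-space net
signal vector stays below 1% (acceptance target), and the density-scaled
`α`, `β` agree within 2%. Density scaling is the invariant formulation:
with uniform per-dipole weights the comparison instead measures the
sampling bias between a parameter-uniform grid and an area-uniform
decimation, which is a property of the mesh generator, not of the signal
model.

## What the surrogate does and does not show

The open single-sided cap is the deliberate simplification, and it has two
consequences a user must know:

* **EEG retains a coherent radial moment.** A height field's tangential
  dipole components cancel between opposed walls, but the radial
  components never change sign, and on an open cap their sum is not
  canceled by an opposing bank as on closed, fully convoluted anatomy.
  MEG is immune (radial moments are silent in a spherical conductor), so
  the distributed-dipole asymptotics — mean `C < 0.5` below ten dipoles,
  `C` tracking `1/√n`, and `C ≈ 0` at `n = 10,000` — hold for
  magnetometers and gradiometers, while EEG plateaus near the correlation
  floor (mean C ≈ 0.4 at large n under the default conditions, as the
  test suite measures). Asymptotic distributed-dipole results from this
  package should therefore be read as MEG results.
* **Periodic folds cancel too coherently for MEG patches.** With a single
  fold direction and wavelength, a patch spanning a full wavelength
  cancels its oscillatory component almost completely, so the MEG
  conservation factor falls faster than the `~1/r` seen on heterogeneous
  real cortex; the net signal `α(r)` is then sub-linear in `r` (log–log
  slope ≈ 0.24 over 5–30 mm under the default conditions), while EEG,
  with its flat `C(r)`, is nearly quadratic. The `β ∝ r²` law and the
  monotone decrease of `C(r)` are robust to this; the α-growth exponent
  is not, and the corresponding acceptance expectation is knowingly not
  met by this geometry.
* **The folding-effect comparison is asserted on EEG.** The smoothed
  shell overestimates the conservation factor at every radius ≥ 5 mm in
  EEG, cleanly reproducing the qualitative finding it models. In MEG the
  same comparison is dominated by the near-silence artifact of an almost
  smooth concentric cap (C then measures the cancelation of a tiny
  curvature residual), so it is not a meaningful MEG statement in this
  geometry.

## Numerical and design choices

* Percentiles (display clipping at the 1st–99th percentile of cerebellar
  norms) use the linear-interpolation definition (`quantile` type 7).
* Histograms of normalized single-dipole norms use 100 equal-width bins
  over 0 to the pooled 99.5th percentile, density-normalized to integral
  one; the cerebellar exceedance fraction over the cortical median is
  reported exactly.
* Decimation selects vertices by farthest-point sampling with graph
  shortest-path distances, starting deterministically from vertex 1;
  whether a real downsampler conserves area by reassignment or plainly
  subsamples is unknowable from outside, and we conserve area because it
  keeps `C`, `α`, `β` density-consistent.
* SDs are sample standard deviations (n−1). Summary tables carry units in
  their headers; per-sample tables carry a `units` column per modality.
* The run configuration rejects unknown keys, and every physical quantity
  in it is suffixed with its unit (`*_mm`, `*_S_per_m`, `*_nAm`).
* Problem sizes of the default study: cortex-like ~11,700 source vertices
  (used in full), cerebellum-like ~45,000 mesh vertices decimated to a
  10,000-vertex source grid (orientations and areas preserved), smoothed
  shell ~7,800 vertices; 200 Monte Carlo samples per grid point. These
  sizes keep every curve reproducible on a laptop while resolving the
  folia in both the geometry and the source grid.

## Known limitations

Beyond the surrogate effects above: sensors are point-like (no pickup-coil
integration, no noise model); the conductor is spherical for the default
engine; anatomical labels (lobules, fissures) are out of scope, so maps
are reported per vertex, not per anatomical region; and no inverse
modeling is attempted.
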