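---
title: "Designing multi-density lung nodule phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multi-density lung nodule phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulefab)
```

## The problem

Part-solid pulmonary nodules combine a solid core above 0 HU with
ground-glass components spanning roughly 0 to −750 HU. Physical phantoms of
such nodules are needed to optimise CT protocols without patient exposure,
but stereolithography (SLA) printing cures a single resin at a single
density: a dense print of a nodule reproduces its shape, not its internal
radiodensity structure. `nodulefab` implements a digital workflow that works
around this limit by designing sub-voxel air voids into the print, and it
implements the observer-study statistics used to judge whether the resulting
phantoms are distinguishable from real nodules.

## Partial-volume density model

A CT voxel much larger than the print's internal features reports the
volume-weighted mean attenuation of its contents. Since HU is affine in
attenuation, a structure with material volume fraction $f$ inside a voxel
images at

$$\mathrm{HU}(f) = f\,\mathrm{HU}_\mathrm{mat} + (1 - f)\,\mathrm{HU}_\mathrm{air},$$

with $\mathrm{HU}_\mathrm{air} = -1000$ fixed by the CT scale and
$\mathrm{HU}_\mathrm{mat}$ the effective HU of the fully dense cured resin
(default 120 HU, consistent with a resin density of about 1.17 g/cm³, and
configurable). `fit_material_hu()` estimates
$\mathrm{HU}_\mathrm{mat}$ by least squares through the air point from
measured mean HU of printed calibration cubes.

The model is deliberately the *ideal* mixing law. Printed lattices deviate
from it systematically — trapped uncured resin raises the density of
small-void designs, and occasional air gaps lower it — and those deviations
are surfaced through the fit residuals rather than absorbed into the model.
This matters for design selection (below).

## Beam lattices and their fill fraction

The density-reduction structure is a cubic lattice of three orthogonal
families of square-section beams: thickness $t$, void side $g$, period
$p = t + g$, all integer multiples of the printer's 85 µm spot size because
the printer cannot realise finer lateral features. A point is material
exactly when at least two of its three axis coordinates fall within a beam,
which gives the unit-cell fill fraction by inclusion–exclusion:

$$f = 3r^2 - 2r^3, \qquad r = t/p .$$

`build_lattice_mesh()` constructs the lattice as an *exact rectilinear
solid*: per axis, the beam intervals define breakpoints; a cell of the
resulting non-uniform grid is material iff at least two of its axis
indicators are set. Two design choices:

* **Trimming.** Beams are clipped at the cube boundary so the outer faces
  are closed and printable, rather than leaving protruding stubs.
* **Phase.** For a cube side that is not a multiple of $p$, the clipped
  per-axis beam fraction generally differs from $r$, which would bias the
  printed density by several percent. The beam phase is therefore solved
  (the clipped fraction is continuous and periodic in the phase with mean
  $r\,\times$ side, so a root always exists) so that each axis fraction
  equals $r$ exactly; by separability the enclosed volume then equals
  $f \cdot \mathrm{side}^3$ to floating point.

The default calibration grid — thicknesses {340, 510, 680} µm crossed with
voids {680, 850, 1020, 1360, 1700, 2040} µm, 18 designs — lives in
`inst/extdata/default_config.json`, not in code. Five of the six void values
are fixed by the workflow's published description; 1360 µm (16 × 85) is the
interpolated sixth required to complete the 3 × 6 grid and is marked as an
assumption in the configuration.

## Geometry kernel: exact rectilinear Booleans

No robust mesh-Boolean library is available to this package, and Boolean
robustness is exactly where generic mesh pipelines fail. The kernel
therefore exploits the structure of the problem: every mesh the pipeline
produces — thresholded HU classes on a voxel grid, lattice cubes, boxes,
and previous Boolean results — is the boundary of an axis-aligned cell
complex (`rect_solid`). For two such solids, the union of their breakpoints
defines a merged grid on which every cell lies entirely inside or outside
each operand, so intersection/union/difference reduce to exact logical
operations, and enclosed volumes are exact sums of cell volumes.
Surface extraction emits one outward quad per material/non-material cell
interface; the divergence-theorem volume of the mesh equals the cell-sum
volume identically, and closedness is validated by requiring the boundary
operator to vanish (every directed edge balanced by its reverse — the
correct criterion for voxel surfaces, where four faces may meet along an
edge).

Surface extraction from label volumes is therefore exact voxel-boundary
extraction rather than marching cubes: with no marching-cubes dependency
available it is the robust, volume-faithful choice (a cuboid mask meshes to
exactly voxel count × voxel volume; a digitised 3 mm ball at 0.1 mm spacing
is within a fraction of a percent of the analytic sphere). The cost is a
blocky, staircase surface at the voxel scale — irrelevant below printer
resolution, but a visible simplification for coarse grids.

Meshes read from arbitrary STL files carry no rectilinear representation;
Booleans involving them voxel-remesh all operands at a configurable
resolution and flag the result `"voxel-remeshed"` in its provenance. Such
results are approximate at the voxel scale and are validated against the
same volume oracles as exact results.

## Occupancy voxelization and the virtual CT

`voxelize_occupancy()` converts a mesh to per-voxel material fractions, the
input to the virtual-CT simulator. Two paths:

* **Exact** (default for pipeline meshes): separable 1-D overlap matrices
  between voxel intervals and solid cells, contracted against the occupancy
  array — exact to floating point.
* **Sampling** (general meshes, and the independent oracle): ray columns on
  a `supersample²` in-plane grid per voxel; along each ray the
  inside-intervals from parity of triangle crossings are integrated against
  the voxel extents exactly, so only the in-plane directions contribute
  discretisation error. Columns carry deterministic low-discrepancy
  intra-cell offsets to avoid grazing mesh planes and to break
  commensurability with periodic geometry (uniform columns alias badly when
  the lattice period is a multiple of the column pitch). Residual error is
  at the 1% level for fine lattices at the default settings and falls well
  below that at higher supersampling; tests that use the sampling path as a
  volume oracle choose the column pitch so the oracle error is several
  times smaller than the tolerance being checked.

Because the exact and sampling paths share no code beyond the mesh itself,
their agreement (asserted in the test suite at 0.02 absolute occupancy over
the whole design grid) is a genuine two-route check of the geometry.

`simulate_ct()` maps occupancy to HU through the partial-volume model,
applies a separable Gaussian PSF (default σ = 0.6 mm, the order of clinical
CT resolution; edge kernels renormalised so constants are preserved), and
adds seeded i.i.d. Gaussian noise. Beam hardening, scatter,
reconstruction kernels and dose dependence are out of scope; the simulator
is a desk-scale stand-in for a scanner, good for mean-HU and
pattern-visibility questions, not for noise-texture realism.

## Lattice visibility

When voids exceed the effective resolution, the periodic print pattern
becomes visible on CT and inflates ROI standard deviations.
`lattice_visibility_score()` quantifies this as the ROI coefficient of
spatial variation plus the mean normalised spectral amplitude at the lattice
frequency $1/p$; the default threshold of 0.2 (in configuration) sits well
between unresolved lattices (score near the 0.05 measurement floor) and
resolved ones (score near or above 1). Observed visibility thresholds per
beam thickness — 340 µm beams visible from 1700 µm voids (hard
reconstruction kernels), 680 µm beams from 1020 µm on both kernels, with the
510 µm rule interpolated between the two anchors — are shipped as
configuration rules and exclude designs from selection.

Monotonicity of the score in void size is asserted in the tests at
σ = 0.3 mm, where the PSF leaves all default lattices at least partially
resolvable; at the default σ = 0.6 mm the sub-resolution designs all sit at
the score floor, where ordering is dominated by discretisation noise, so
there the tests assert the weaker property that the *visible* flag switches
on at most once along the void axis.

## Design selection

`select_lattice()` returns a design for a target HU band. The shipped
band anchors map (−750, −500) HU to t 340/g 1020 µm, (−500, −300) to
510/850, and (−300, 0) to 680/680 — the published part-solid design. These
anchors are configuration, not a computation, for a substantive reason: the
published mapping derives from *measured* HU of printed cubes, and no
affine ideal-mixing model reproduces it. The midpoint fill fractions of the
two lower bands are in fixed ratio 1.6 under any affine model anchored at
air, while the anchored designs' fill ratio is 2.025; equivalently, with a
realistic resin near 120 HU the ideal model cannot reach the (−300, 0) band
at all (a 50 % lattice predicts −440 HU). Real prints are denser than
designed at small voids (trapped resin), which is precisely the deviation
the ideal model declines to absorb. When no anchor covers the requested
range, selection falls back to the model: among designs not excluded by the
visibility rules, the one whose predicted HU is nearest the range midpoint,
ties broken toward thicker beams (coarser beams print more reliably).

## Reader-study statistics

The proof-of-concept analysis treats "3D-printed" as the positive class, so
a false negative — a printed nodule read as real — is the error that
indicates phantom realism. The module provides:

* `classification_rates()`: accuracy and class-conditional rates as
  percentages rounded half-up to one decimal (the convention of the
  published tables); undefined rates are `NA`, never 0. The published
  counts themselves ship in `printed_count_fixtures()` with their internal
  identities asserted (senior + resident = overall cellwise; totals
  1071 = 17 readers × 63 presentations). One printed value does not
  recompute from its own counts: resident accuracy 430/756 = 56.88 % rounds
  to 56.9, not the printed 56.8; the discrepancy is noted and excluded from
  assertions.
* `bootstrap_ci()`: percentile bootstrap with the resampling unit exposed
  (response, reader, or case) because the published intervals are wider
  than a response-level normal approximation suggests, consistent with
  clustering by reader or acquisition; the unit choice is surfaced, not
  hidden. Degenerate resamples are redrawn up to a cap.
* `conger_kappa()`: the exact multi-rater generalisation of Cohen's κ,
  with chance agreement the mean over rater pairs of their category-marginal
  inner products. For two raters it reduces to Cohen's κ exactly (tested on
  random tables); with per-rater data unavailable in the published record,
  its behaviour is validated by simulation — seventeen independently
  guessing readers over 63 presentations yield |κ| well below 0.05,
  matching the magnitude of the reported near-zero agreement.
* `chi2_goodness_of_fit()`: two-cell χ² of correct/incorrect counts against
  an explicit null proportion (default 0.5, guessing). The published
  headline statistics (136.13 overall, 70.0 and 72.0 by experience) cannot
  be reconstructed from the printed counts under chance or independence
  nulls — the test construction is underdetermined — so the operation takes
  its null explicitly and those statistics are not asserted anywhere.
* `confidence_summary()`: Likert-level frequencies with likelihood ratios
  of correct versus incorrect, reporting undefined ratios as `NA` with
  counts rather than as infinities.

## Synthetic data

`make_synthetic_nodule_volume()` builds a concentric-sphere part-solid
nodule: a 2 mm core at +150 HU and shells to 3, 4, 5 mm at −150, −400 and
−625 HU by default — inside the clinically observed ranges for solid cores
and subsolid components, and inside their segmentation bands — on a 0.1 mm
isotropic grid with optional Gaussian noise (30 HU default) and an optional
deterministic lobulation of the radius field. It returns per-band ground
truth for recovery tests. What it does *not* emulate: irregular patient
morphology, lung parenchyma background, and spatially correlated CT noise;
passing recovery tests therefore demonstrates correctness of the
segmentation arithmetic, not robustness to anatomical complexity.

`make_synthetic_responses()` simulates the blinded reading: 5 senior + 12
resident readers, 21 acquisitions of which 14 are printed (matching the 2:1
positive balance of the study), 3 presentations each (1071 responses),
per-group sensitivity/specificity defaulting to the observed near-chance
operating points (seniors 0.424/0.514, residents 0.568/0.571), and a
confidence distribution peaked at the lower levels, reflecting the overall
low reported confidence. Every fixture is reproducible byte-for-byte from
its recipe and seed.

## Numerical choices and problem sizes

* HU volumes are clamped to the 12-bit CT range [−1024, 3071] on load.
* Band intervals: core HU > 0, gg1 (−300, 0], gg2 (−500, −300],
  gg3 [−750, −500]; closures make 0 and −750 assignable exactly once.
  Whether HU = 0 belongs to the core or the first ground-glass band is not
  externally fixed; assigning it to gg1 is this package's explicit
  convention.
* Trilinear interpolation for intensity resampling, nearest-neighbour for
  labels; ROI statistics use the population SD, matching image-analysis
  tools.
* Breakpoints closer than 1e−12 of the coordinate scale are merged when
  grids are combined, absorbing floating-point near-duplicates.
* The test and acceptance workloads run synthetic nodules at 0.15 mm
  spacing with a 0.6 mm margin and voxelize lattices at a 0.2–0.25 mm voxel
  grid with 4–6× in-plane supersampling; these sizes keep every quantity's
  numerical error several times below its assertion tolerance while the
  whole suite completes in minutes on one core.
* DICOM series input is not implemented (no DICOM reader is available to
  the package); volumes load from NIfTI, and the rescale slope/intercept
  calibration is exposed as `hu_rescale()`.

## Known limitations

Blocky class surfaces at coarse voxel sizes; ideal mixing only (systematic
print-density deviations appear as fit residuals, not corrections); no
reconstruction-algorithm or dose modelling in the virtual CT; no support
structures, hollowing or printability analysis beyond the spot-size
constraint; selection anchors trust the published measured mapping rather
than re-deriving it, by design.
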