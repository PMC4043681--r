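---
title: "Measuring bone microstructure: BV/TV, connectivity density, and MIL fabric anisotropy"
author: "bonefabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring bone microstructure: BV/TV, connectivity density, and MIL fabric anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Desktop micro-CT of rodent long bones is the standard way to quantify how
disease changes bone microstructure. The most widely reported index, bone
volume fraction (BV/TV), measures *how much* bone there is; it is blind to
*how the bone is arranged*. That distinction matters for bone tumors such
as osteosarcoma, which destroy organized bone (osteolysis) while
simultaneously depositing new, structurally disorganized woven bone on the
periosteal surface. BV/TV reads the second process as growth; a measure of
structural *organization* reads both processes as degradation.

The organization measure implemented here is the **degree of anisotropy
(DA)** derived from the **mean intercept length (MIL)** fabric tensor.
`bonefabric` implements the full measurement chain on calibrated density
volumes — segmentation, region and compartment definition, morphometry,
fabric analysis, group statistics — together with a synthetic phantom
generator that provides ground-truth structures on which every stage can be
validated quantitatively.

## The measurement chain

### Segmentation

Input volumes are calibrated mineral density grids (mgHA/cm^3) on an
isotropic voxel lattice (12 µm by convention for murine tibia). Bone is
separated from soft tissue by a truncated-Gaussian noise filter followed by
a global threshold:

* `threshold = 439.0` mgHA/cm^3 — the conventional bone/soft-tissue cut
  for murine tibia at this calibration;
* `sigma = 0.2`, `support = 1` voxel — a very mild 3×3×3 smoothing whose
  weights are the Gaussian evaluated at integer offsets, renormalized to
  unit sum *after* truncation. Whether such filters normalize before or
  after truncation is rarely documented by vendors; unit-sum-after-truncation
  is the assumption here, recorded in every mask's provenance.

Two deliberate conventions: the threshold comparison is inclusive (a voxel
at exactly 439.0 is bone), chosen for determinism; and volume boundaries
are handled by edge replication, so the filter never fabricates bone or
marrow beyond the scanned field. `sigma = 0` or `support = 0` is the exact
identity.

### Regions and compartments

Analysis regions are contiguous axial slice runs. Slice counts are
`ceiling(length_mm * 1000 / voxel_size)` — rounding up so a segment always
covers at least the requested physical length (a 2.48 mm segment at 12 µm
spans 207 slices). Segments are half-open intervals `[start, start + n)`
with 0-based starts, so adjacent regions partition their union without
double counting. There is no anatomical landmark detection: region starts
are explicit configuration, because the usual anatomical anchor (the growth
plate) has no synthetic analog.

Trabecular indices exclude cortical bone; anisotropy includes both
compartments. The split is a per-slice morphological procedure:

1. background connected to the slice border is *exterior*; enclosed
   background is *marrow*;
2. closing the marrow with a small disk (`marrow_close_radius`, default 3
   voxels — it must exceed half the trabecular thickness) bridges it across
   thin trabeculae, producing the medullary (endosteal-envelope) region;
3. bone inside that envelope is trabecular; all other bone — the shell
   between endosteum and periosteum plus periosteal deposits — is cortical.

Slices with no enclosed cavity are classified by the bone fraction of their
closed silhouette (`solid_fraction`, default 0.75): solid cross-sections
are all cortical, open lattices fall back to all-trabecular with a warning.
All closings are computed on zero-padded slices because clipped dilation at
the image border would otherwise inflate the closed set. The procedure is
deterministic and invariant under in-plane right-angle rotations.

The medullary region also serves as the total volume (TV) for trabecular
BV/TV and connectivity density, matching how trabecular indices are
reported in practice.

### Morphometry

* **BV/TV** is an exact voxel-count ratio; volumes are reported in mm^3.
* **Euler characteristic** χ is computed on the cubical complex of the
  bone voxels (χ = V − E + F − C over vertices, edges, faces, cubes).
  Voxels sharing only a corner share a complex vertex, so bone is
  26-connected and background 6-connected — the standard convention in
  bone topology. The computation is exact and additive over disjoint
  structures.
* **Connectivity density** uses the standard estimator
  Conn.D = (1 − χ)/TV, valid when the structure is one connected component
  without enclosed cavities (then β1 = 1 − χ). When fragmentation makes the
  raw value negative it is reported as 0 with a note rather than silently
  returned: a negative density would mislead downstream group comparisons.
  No largest-component purification is applied by default, because
  tumor-lysed structures legitimately fragment.

### MIL fabric and DA

The directional mean intercept length is estimated two independent ways:

* **Test lines** (the classical estimator, kept as the oracle): a grid of
  parallel rays (spacing 2 voxels) is marched through the volume at ≤ 0.5
  voxel steps; MIL(ω) = total in-bone length / number of marrow→bone
  crossings. Crossings are only counted strictly inside the region, so rays
  entering through a region face contribute length but no interface.
* **Surface projection** (the production estimator): the bone surface is
  triangulated and MIL(ω) = 2·BV / Σₜ aₜ·|nₜ·ω| — the stereological
  chord-length relation through the total projected triangle area.

Both estimators deliberately measure the same geometric object: the 0.5
level set of the Gaussian-smoothed binary field (width 0.9 voxels,
truncation radius 2). A raw binary staircase surface overestimates oblique
projected area by tens of percent, and raw-field ray marching counts the
same staircase as spurious crossings; both biases vanish on the smoothed
level set, and on voxelized spheres both estimators then agree with the
closed form 4R/3 to within a few percent. The smoothing width is the
smallest that reliably removes staircase bias while preserving two-voxel
plates and two-voxel marrow channels; structures thinner than about two
voxels are below the method's resolution (they vanish from the level set,
and the code falls back to the raw field with a warning if smoothing would
erase the bone phase entirely).

Triangulation is by marching tetrahedra: each dual-grid cube is split into
the six Kuhn tetrahedra around its main diagonal, and the level set crosses
tet edges at linearly interpolated points. This decomposition was chosen
because shared cube faces always carry the same diagonal (the mesh is
crack-free and closed) and because the tet set maps onto itself under any
axis permutation, making the mesh exactly permutation-equivariant. Flat
caps are forced where bone meets the volume boundary; those triangles are
flagged as region cuts and excluded from projection sums — they are where
the region was cut, not bone surface. The decomposition is *not* symmetric
under reflections; reflection changes DA by an amount on the order of the
mesh discretization error (a few percent on jagged structures, far less on
smooth ones).

The fabric tensor M is fitted by linear least squares to
n′ M n = MIL(n)^(−2) over a deterministic spherical-Fibonacci hemisphere
lattice (default 256 directions; 9 is the minimum that overdetermines the
six parameters). By default the fit is evaluated on all six coordinate
permutations of the lattice, which makes the evaluated direction multiset
itself permutation-invariant and therefore makes DA exactly invariant under
axis permutations of the mask. Principal MILs are Lᵢ = mᵢ^(−1/2) for
eigenvalues m₁ ≤ m₂ ≤ m₃, and

> **DA = L₁ / L₃ — the ratio of the longest to the shortest principal
> mean intercept length.**

This is deliberately *not* an eigenvalue ratio of M (which would equal
DA²); vendor conventions differ on this point, so the package follows the
MIL-ratio definition and documents it prominently. DA = 1 is isotropy;
competent organized bone is strongly anisotropic. A non-positive-definite
fit aborts with the offending eigenvalue — it signals degenerate structure
or inadequate sampling, not a value to propagate.

Directions along which a prismatic structure projects zero area (e.g.
looking exactly down an extruded shape with its cut ends excluded) have
unbounded MIL; these are capped at the bounding-box diagonal with a
warning. The cap mirrors what happens physically when a diaphyseal cortex
spans the entire scan: the longest intercepts are limited by the field of
view, which is why diaphyseal DA values are much larger than metaphyseal
ones and why absolute DA magnitudes are tied to the region conventions
while *orderings* between conditions are robust.

### Group statistics

The study-level comparisons are the two-sided Mann-Whitney rank-sum test
(exact p by enumeration for small tie-free samples, tie-corrected normal
approximation with continuity correction otherwise; the branch taken is
recorded), the Wilcoxon signed-rank test on paired differences (zeros
dropped, statistic = smaller signed-rank sum, exact for n ≤ 15 without
ties), Dunn's rank-based multiple-comparison follow-up (pooled midranks,
tie correction, Bonferroni family-wise adjustment over the k(k−1)/2 pairs),
Pearson correlation with the t-transform p-value, and the radiographic
percent-increase measure 100·(tumor − control)/control. Branch thresholds
are fixed constants so p-values are bit-reproducible.

## The phantom generator: what it emulates and what it does not

The generators provide structures whose volume fraction, topology and
principal directions are known by construction:

* `make_plate_phantom()` — periodic parallel plates; exact BV/TV by
  construction, longest MIL in the plate plane. The cleanest "organized
  bone" reference.
* `make_isotropic_boolean()` — a Boolean model (union of spheres at random
  centers, sphere count adjusted until the achieved fraction is within
  0.02 of target). Isotropic by construction: the reference condition
  DA ≈ 1 against which organized structures are calibrated.
* `make_cortical_cylinder()` — a hollow tube along the long axis; the
  diaphysis analog with analytic BV/TV and one independent loop.
* `make_metaphysis_like()` — the composite used in the tumor experiments: a
  cortical shell with a gentle linear flare (the metaphyseal cone, default
  15% over the segment) and circumferential periosteal ridging (default
  amplitude 1.5 voxels, period 8 slices — real periosteal surfaces are not
  smooth), enclosing an axial trabecular lattice: a central honeycomb prism
  whose seven axial channels carry the structure's independent loops, plus
  a ring of free vertical rods. Every interior structure is prismatic along
  the long axis, as metaphyseal trabeculae align with load.

Three design choices in the composite phantom deserve explanation, because
they were driven by measurement physics rather than convenience:

* **Flare and ridging** give the shell a *stable* axial surface-projection
  term. Without them the axial MIL of a purely prismatic phantom is
  governed entirely by smoothing artifacts at junctions, and removing
  interior structure can perversely *raise* DA. With a fixed axial
  projection anchor, interior loss reduces the in-plane projected area and
  therefore reduces DA, monotonically — the behavior the tumor experiments
  measure. As a side effect, baseline DA lands near 3.5, the right regime
  for a murine metaphysis.
* **Structural elements are disjoint.** Osteolysis removes whole elements
  (the honeycomb, individual rods), not random voxels — voxel-wise deletion
  would thin surfaces without degrading connectivity the way tumor
  permeation does. Keeping elements disjoint means removing one never
  exposes fresh contact surface on another, so projected area falls in
  proportion to what was removed.
* **Loops are carried by vertical channels.** Any loop built from
  horizontal struts would add axial projected area that osteolysis then
  removes, again coupling connectivity to DA in the wrong direction. Axial
  channels give β1 > 0 with zero axial projection.

`apply_tumor()` adds the disease processes: element-wise osteolysis, an
optional cortical window (one quadrant, middle third of the axis), and
woven-bone deposition — cylindrical spicules (radius 2–4, length 10–30
voxels, orientation uniform on the sphere) accumulated in the periosteal
band until a target fraction of that band is bone. The spicule geometry is
a stand-in: the literature gives no quantitative description of periosteal
spicules, so the parameters are configuration, not claims about biology.
All generators are bit-deterministic under their seed. Density values are
two-phase (700 bone / 0 background mgHA/cm^3) so the 439.0 threshold
cleanly bisects them before noise; `add_noise()` makes the filter stage
testable.

What the phantoms do **not** emulate: scanner physics (beam hardening,
ring artifacts, spatially correlated noise), partial-volume gradients at
interfaces, growth-plate anatomy, biological variability of trabecular
architecture, or any mechanistic tumor growth. Passing the package's tests
therefore demonstrates that the *measurement chain* is correct and that it
responds to structural degradation in the right direction — not that any
particular in-vivo DA value would be reproduced. In particular, published
in-vivo group means for murine tibia (metaphyseal DA near 3 in controls,
diaphyseal DA near 10, control BV/TV near 12%) are order-of-magnitude and
ordering references only; absolute agreement would require the original
scans and the vendor's exact region conventions.

## Numerical choices, in one place

| choice | value | why |
|---|---|---|
| threshold comparison | inclusive (≥) | determinism at exact threshold |
| filter truncation | renormalize after truncation | vendor behavior undocumented; assumption recorded |
| slice count rounding | ceiling, 1e-9 guard | segment covers at least the requested length; guard absorbs floating-point excess |
| segment convention | 0-based, half-open | adjacent regions never double count |
| mesh pre-smoothing | σ = 0.9, support 2 | removes staircase bias; preserves 2-voxel features |
| level-set interpolation clamp | t ∈ [0.02, 0.98] | avoids degenerate zero-area triangles |
| region cut faces | forced planar, excluded from projections | cuts are not bone surface |
| MIL cap | bounding-box diagonal | intercepts are physically limited by the field of view |
| direction lattice | spherical Fibonacci, hemisphere | deterministic, quasi-uniform, antipodally unique |
| fit symmetrization | 6 coordinate permutations | exact DA invariance under axis permutation |
| Conn.D < 0 | clamped to 0, with a note | β0 = 1 assumption violated; raw negative misleads |
| exact-test branches | fixed constants | bit-reproducible p-values |
| per-sample seeds | global seed + id hash | adding a sample never perturbs others |

## Problem sizes

The test suite validates the estimator agreement and isotropy calibration
on 128³ Boolean phantoms with 64–256 directions, organized phantoms at
96³–128³, the tumor monotonicity experiments on 80×88×88 composites
averaged over five seeds, and the bundled demo study on ten 116×88×88
samples; these sizes were chosen as the smallest at which the measured
quantities are stable against further refinement. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities at the same scales
from a single seed.

## Known limitations

* DA from any fixed finite direction set is exactly
  permutation-invariant here but only approximately reflection-invariant
  (the Kuhn decomposition has a handedness); the deviation is bounded by
  the mesh discretization error.
* Structures thinner than ~2 voxels are below the resolution of the
  smoothed level set, exactly as they are below the resolution of a real
  scanner at comparable voxel size.
* The compartment split is a documented heuristic standing in for
  operator-drawn contours; it recovers ≥95% of phantom ground truth but has
  no notion of anatomy.
* Conn.D on heavily fragmented structures saturates at 0 by design.
* The TIFF volume format quantizes densities to ~1.5e-5 mgHA/cm^3 (32-bit
  samples on a fixed scale); NIfTI is the lossless interchange format.
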