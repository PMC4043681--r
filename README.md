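# bonefabric

Trabecular bone morphometry and mean-intercept-length (MIL) fabric
anisotropy for micro-CT density volumes, with a synthetic phantom generator
for validating every stage against known ground truth.

## The problem

Micro-CT studies of rodent long bones usually report bone volume fraction
(BV/TV) to track disease. BV/TV measures how much bone there is, not how it
is *organized* — and bone tumors such as osteosarcoma destroy organized
bone (osteolysis) while simultaneously depositing disorganized woven bone
on the periosteum, which BV/TV misreads as growth. Structural organization
is captured by the **degree of anisotropy (DA)** of the MIL fabric tensor:
competent, load-aligned bone is strongly anisotropic (high DA), while both
osteolysis and haphazard new bone push DA toward 1 (isotropy).

`bonefabric` is aimed at preclinical bone labs and methodologists who want
this measurement chain as inspectable, tested code rather than a scanner
vendor's black box:

- **Segmentation** — truncated-Gaussian noise filter (sigma 0.2, support 1)
  and global density threshold (439.0 mgHA/cm³), the standard murine-tibia
  protocol.
- **Regions and compartments** — axial segments (a 2.48 mm segment at
  12 µm voxels spans 207 slices), plus a morphological cortical/trabecular
  split: trabecular indices exclude the cortex, anisotropy includes both.
- **Morphometry** — BV/TV; the Euler characteristic of the voxel complex
  (26-connected bone); connectivity density Conn.D = (1 − χ)/TV in 1/mm³.
- **Fabric anisotropy** — bone surfaces triangulated by marching
  tetrahedra on the smoothed 0.5 level set; directional MIL from projected
  surface area, MIL(ω) = 2·BV / Σₜ aₜ|nₜ·ω|; the classical test-line
  estimator kept as an independent oracle; fabric tensor fitted by least
  squares to n′Mn = MIL(n)⁻²; **DA = L₁/L₃**, the ratio of longest to
  shortest principal MIL (1 = isotropic).
- **Phantoms** — parallel-plate, isotropic Boolean, cortical-cylinder and
  metaphysis-like generators with analytic ground truth, plus tumor-like
  perturbation (element-wise osteolysis, cortical breach, random periosteal
  spicules) and Gaussian density noise, all bit-deterministic under a seed.
- **Statistics** — two-sided Mann-Whitney (exact or tie-corrected normal),
  Wilcoxon signed-rank, Dunn's multiple-comparison follow-up, Pearson
  correlation, radiographic percent-increase.
- **Pipeline** — `run_study()` runs configured samples end-to-end with
  per-sample seeding, CSV/JSON outputs and full provenance; a thin CLI
  (`inst/cli/bonefabric.R`) wraps the same functions.

Volumes are read and written as NIfTI (lossless) or multi-page TIFF; meshes
export to PLY; configurations round-trip through YAML. Results are tibbles
with broom-style `tidy()`/`glance()` and `ggplot2::autoplot()` methods.

## Worked example

Generate an isotropic phantom and an organized (tube-like) phantom, segment
them, and compare their anisotropy:

```r
library(bonefabric)

iso <- make_isotropic_boolean(c(64, 64, 64), sphere_radius = 5,
                              target_bvtv = 0.3, seed = 1)
mask <- segment_bone(iso$volume)
mask
#> <binary_volume> 64 x 64 x 64 voxels @ 12 um, 82411 bone voxels (31.4%)

morphometry(mask)
#> # A tibble: 1 x 5
#>      bv    tv  bvtv euler conn_d
#>   <dbl> <dbl> <dbl> <int>  <dbl>
#> 1 0.142 0.453 0.314   -55   124.

degree_of_anisotropy(mask, n_directions = 128)
#> <fabric_tensor> DA = 1.061 (principal MILs 112.0 >= 109.1 >= 105.6 um, 128 directions)

cyl <- make_cortical_cylinder(c(64, 64, 64), outer_radius = 20, inner_radius = 14)
degree_of_anisotropy(segment_bone(cyl$volume), n_directions = 128)
#> <fabric_tensor> DA = 10.007 (principal MILs 1124.0 >= 113.7 >= 112.3 um, 128 directions)
```

The Boolean phantom measures DA ≈ 1.06 — essentially isotropic, its MIL
distribution a sphere — while the cortical tube, whose structure runs along
one axis, measures DA ≈ 10 with its longest principal MIL aligned with the
tube. The morphometry row says the isotropic phantom is 31.4% bone with a
highly connected structure (χ = −55, about 124 independent connections per
mm³ of region).

The bundled demo study runs five control and five tumor-bearing
metaphysis-like phantoms through the whole pipeline (tumor = 80% of
trabecular elements removed, cortical breach, woven bone over 35% of the
periosteal band):

```r
res <- run_study(demo_config(seed = 1))
res
#> <study_results> 20 result rows, 6 comparisons, 0 failed sample(s)
#> # A tibble: 4 x 5
#>   group   region       bvtv conn_d    da
#>   <chr>   <chr>       <dbl>  <dbl> <dbl>
#> 1 control diaphysis  0.323    60.7  3.32
#> 2 control metaphysis 0.372    70.0  3.43
#> 3 tumor   diaphysis  0.0963    0    1.43
#> 4 tumor   metaphysis 0.121     0    1.45
```

Tumor phantoms come out lower than controls in trabecular BV/TV (osteolysis),
in connectivity density (lost trabecular loops), and in DA (lost
organization) in both regions; `res$comparisons` holds the Mann-Whitney
p-values (all < 0.05 here) and `autoplot(res)` plots the groups. Note the
asymmetry that motivates DA: the tumor phantoms contain *more* total bone
than controls (the woven deposits), yet every organization measure falls.

## Documentation

The methods vignette (`vignettes/bone-fabric-anisotropy.Rmd`) describes the
measurement model, every tunable parameter with its default and rationale,
what the phantom generator does and does not emulate, the numerical
conventions, and known limitations.
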