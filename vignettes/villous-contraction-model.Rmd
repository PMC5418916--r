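---
title: "An actively contracting villous-tree model of the human placenta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An actively contracting villous-tree model of the human placenta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(villiwave)
```

## The model

The human placenta exchanges gases and nutrients between two blood
circulations across the surface of the villous trees. The thick structural
branches of each tree — the stem villi — carry contractile cells along
their longitudinal axes. When these cells contract, they displace the
surrounding tissue (intermediate, terminal and mesenchymal villi plus the
maternal blood of the intervillous space, treated here as a single soft
continuum). That displacement cannot be measured in vivo, so `villiwave`
reconstructs it computationally in three stages.

**1. Geometry.** The stem villi are built as a three-tier branch graph
between the chorionic plate (z = 0) and the basal plate:

* *Truncus chorii* (z = 0–2.9 mm): a single vertical trunk whose radius
  tapers from `r_max` = 1.5 mm to `r_min` = 0.5 mm along a quarter-ellipse
  `r(z) = r_max − (r_max − r_min) √(z_tr² − (z − z_tr)²) / z_tr`, chosen so
  dr/dz = 0 at the boundary and the trunk joins the next tier smoothly.
* *Rami chorii* (2.9–13.5 mm): two complete binary subtrees of four
  generations (16 tips, bifurcation ratio exactly 2). Each branch departs
  its junction horizontally in its own split azimuth and curves toward the
  basal plate as a circular arc — radius 1.74 mm for the first two
  generations, 8.99 mm beyond — with the fourth generation bending up to
  vertical so all tips land at z = 13.5 mm. Diameters taper linearly with
  arclength from 1 mm to 0.5 mm.
* *Ramuli chorii* (13.5–24.5 mm): sixteen unequally dichotomous subtrees,
  one per rami tip. Their topology comes from 2D lattice
  diffusion-limited aggregation: random walkers stick to a growing
  cluster, the cluster's face-adjacency graph is reduced to its
  breadth-first spanning tree, degree-2 chains are contracted to straight
  chords, and the skeleton is lifted into the 13.5–24.5 mm slab (radial
  distance from the seed maps to depth; the perpendicular coordinate
  becomes the lateral spread). Diameters increase with centripetal order
  from 0.3 mm at the tips to 0.5 mm at the subtree root, with junction
  radii matched.

The tree is rasterized into a voxel occupancy grid (flat-ended tube union:
a straight branch of radius R and length L occupies πR²L). The reference
grid is 1200 × 1200 × 847 voxels at 29 µm/pixel (34.8 × 34.8 × 24.6 mm).

**2. Contraction direction.** Every occupied voxel with an unoccupied
face-neighbour is a surface element. On the truncus, where the radius
changes steeply, the contraction direction is the surface tangent closest
to the axis direction (0, 0, −1): with φₒ = π + atan(dr/dz), the unit
vector is (sin φₒ cos θₒ, sin φₒ sin θₒ, cos φₒ). At the truncus–rami
boundary dr/dz = 0 and the pull is straight down; toward the chorionic
plate dr/dz → −∞ and the pull flattens into the plane. On the rami and
ramuli the diameter change is small, so the direction is the branch-axis
tangent at the nearest axis point, oriented toward the proximal junction
(each branch contracts along its axis toward its parent).

**3. Displacement.** Soft tissue is incompressible, so only the shear
(transverse) wave survives and the shear modulus is µ = ρλ²ν². With tissue
density ρ = 1000 kg/m³ and contraction frequency ν = 1 Hz, the studied
wavelengths λ = 0.29, 0.58, 1.45 mm correspond to µ = 8.41×10⁻⁵,
3.36×10⁻⁴ and 2.10×10⁻³ Pa. The displacement of a voxel at distance r from
the villous surface is

u(r) = ξ₀ cos(Φ(r)) · d(nearest surface element),

with amplitude ξ₀ = 0.1 µm, evaluated at t = 0 (the time dependence is
deliberately dropped). Viscoelastic attenuation is folded into a hard
cutoff: u ≡ 0 beyond a maximum propagation distance d_max ∈ {1.45, 2.9,
4.35} mm. The wavelength is either constant or increases with distance
from the surface (0.29 mm in the first third of d_max, 0.58 in the second,
1.45 in the last), giving 4 × 3 = 12 computational conditions. For the
increasing profile the phase Φ(r) is accumulated piecewise (∫ 2π/λ(s) ds),
so it is continuous across the band boundaries and the amplitude shows no
artificial jumps.

Each voxel takes the direction and distance of its *single nearest*
surface element — no vector superposition. The wave expression is written
with one distance from the surface, and the per-slice statistics are
descriptions of direction inherited from the local branch; summing
overlapping sources would require assumptions the model does not make.

## Analysis

The displacement field is decomposed into magnitude, the polar angle φ
from the +z axis (0–180°; 90° means parallel to the plates) and the
azimuth θ (−180° to <180°). Where the displacement is purely axial, θ is
undefined and those voxels are excluded from θ statistics. Per z-slice the
package reports the displaced area (voxels with |u| > 0), mean and SD of
the magnitude, the SD normalized by the mean, mean and SD of φ and θ, the
area fraction with φ ∈ [45°, 135°], and SD_in — the population SD of the
360 one-degree θ-bin area fractions, a uniformity measure of azimuthal
direction. SDs are population SDs (divide by N), which stay well defined
for every bin count; θ is averaged arithmetically on [−180, 180), the
convention under which a four-fold-symmetric pattern averages to zero.

Four characteristic positions recur in every condition: `z_d`, the peak of
the normalized magnitude SD near the truncus–rami boundary; `z_phi1` and
`z_phi2`, the two peaks of SD(φ); and `z_theta`, the dip of mean θ near
the rami–ramuli boundary. Profiles are smoothed with a 5-slice moving
average; a peak is significant when its prominence reaches 5× the median
absolute slice-to-slice change of the smoothed profile. Two details of the
peak rule matter and were genuinely open choices:

* Profile endpoints are never peaks, and a side walk that reaches a
  profile end without meeting higher ground contributes no prominence
  base. The model domain is physically truncated at the plates; the
  SD(φ) dome just above the chorionic plate is a real structure whose
  left flank is cut off by the boundary, and treating the edge as a
  valley would discard it.
* A noise-scale threshold (rather than a fraction of the profile range)
  is used because the deep peak — SD(φ) → 90° where the rami run
  vertical and the flipped directions concentrate at 0° and 180° — is an
  order of magnitude taller than the shallow truncus-flare peak, and a
  range-relative rule would see only one peak.

Under this rule the reported pair reproduces the expected structure:
`z_phi1` lies between the truncus midpoint and the rami midpoint with more
than 90% of the displaced area in-plane (φ ∈ [45°, 135°]), and `z_phi2`
lies deep in the model where the displacement is nearly axial.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `r_max`, `r_min`, `z_tr` | 1.5, 0.5, 2.9 | mm | truncus taper |
| `xi0` | 0.1 | µm | contraction amplitude |
| `nu` | 1.0 | Hz | contraction frequency |
| `rho` | 1000 | kg/m³ | tissue density |
| `lambda` | 0.29 / 0.58 / 1.45 / increasing | mm | shear wavelength |
| `d_max` | 1.45 / 2.9 / 4.35 | mm | propagation cutoff |
| `n_particles` | 300 | — | DLA particles per ramuli subtree |
| `lateral_halfwidth` | 4 | mm | lateral extent of a lifted subtree |
| `pixel_size_um` | 116 | µm | working voxel size (29 = reference) |

`n_particles` was calibrated once so that the lifted subtrees' tip
generation counts stay within the anatomically reported 4–20 for the
default seed set; the resulting per-subtree bifurcation ratios disperse
above 2, as an unequally dichotomous tier should. The DLA walker
parameters (launch margin 5 sites, kill radius 3× launch radius,
stick-on-first-face-contact) are standard lattice DLA choices; the
aggregates' mass–radius dimension (≈1.6 on 2000-particle clusters) is
consistent with the 2D DLA literature value of ≈1.71.

## Numerical choices

* **Distance transform.** An exact separable squared Euclidean distance
  transform (lower-envelope algorithm) in integer voxel units, followed by
  a shell lookup that enumerates all lattice offsets at exactly the found
  squared distance in ascending linear-index order. Ties therefore always
  resolve to the smallest surface-element id, and the result is identical
  whether the volume is processed in one pass or streamed in z-slabs with
  a halo of ⌈d_max/pixel⌉ slices (the halo guarantees every in-band source
  is visible to its slab).
* **Geometry contradictions.** The tabulated rami axial lengths are not
  mutually consistent with the tier's z extent under any arclength
  reading; the construction honours the curvature radii, the generation
  count, the 16 tips at z = 13.5 mm, and the per-tree territory
  (equivalent diameter 26–28 mm from the placental-disc arithmetic), and
  treats the per-branch-point z values as nominal.
* **Ordering convention.** Centripetal orders are Strahler: tips are 1 and
  a parent increments only when its children's maximum order is tied.
  This is the convention under which branch counts of an equally
  dichotomous tree form the geometric series N_u = R_b^(u_max−u) and
  under which the anatomical ramuli range R_b ≈ 2.2–6 is reproducible;
  always-increment ordering would compress R_b toward 1 on
  DLA-like trees.
* **Displaced-area membership.** |u| > 10⁻¹²·ξ₀, so voxels that sit
  exactly on cosine zeros are excluded.
* **Degenerate inputs.** Empty slices report area 0 with missing
  statistics; a DLA aggregate whose skeleton has fewer than two edges is
  regrown with a shifted seed; aggregates with adjacency loops are pruned
  to the breadth-first spanning tree with a warning.

## What the generator does and does not emulate

The synthetic model reproduces the published morphometry of the stem
villi: tier depths and diameters, equal dichotomy of the rami, unequal
dichotomy and generation counts of the ramuli, and a deepest point at
24.5 mm consistent with plate separation (25 mm thickness − 243 µm
membrane ≈ 24.8 mm). It does **not** model individual intermediate or
terminal villi (they are part of the continuum), blood flow, contraction
timing, or viscoelastic attenuation beyond the hard cutoff, and the
specific DLA realizations — hence the exact deep-model statistics — differ
from any other implementation's. Passing tests therefore validate the
pipeline's mechanics and the robust, tier-driven features of the
displacement statistics (the in-plane band above the chorionic plate, the
axial band where the rami run vertical, mean φ ≈ 90° throughout), not
voxel-level agreement with any particular placenta.

Problem sizes used in the test suite: unit tests run on small analytic
fixtures and 150³-voxel (232 µm) grids; the full-model statistics are
computed at 116 µm/pixel (300 × 300 × 212), with the 29 µm reference
resolution available through slab streaming.

## A short tour

```{r tour, eval = FALSE}
tree <- build_villous_tree(master_seed = 1)
grid <- rasterize_tree(tree, pixel_size_um = 116)
surface <- assign_contraction(extract_surface(grid), tree)

params <- wave_params(lambda = 1.45, d_max = 4.35)
field <- compute_displacement(grid, surface, params)
stats <- slice_stats(to_polar(field))

autoplot(stats)
find_characteristic_positions(stats)
```

## Known limitations

* The analysis of the deepest slices rests on few voxels; mean-φ band
  checks are applied only to slices with a displaced area of at least 100
  voxels.
* The displaced area is not monotone slice-by-slice inside the rami tier:
  between the radius where the rami arcs turn vertical and the ramuli fan
  there is a shallow dip (−2% per slice at d_max = 4.35 mm). The overall
  trend — growth with depth, steep from the truncus into the rami — is
  robust.
* At working resolutions coarser than ~232 µm the thinnest ramuli
  (0.3 mm) rasterize thinner than a voxel and may break into fragments;
  the connectivity invariant is guaranteed only at the reference
  resolution.
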