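---
title: "Reconstructing complete tooth models from intraoral scans and CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing complete tooth models from intraoral scans and CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothfusion)
```

## The problem

Computer-aided orthodontics needs complete digital tooth models: crown and
root. The two imaging modalities in routine use each see only half the
picture. Intraoral (laser) surface scans resolve the exposed crowns at tens
of micrometres but carry no root information; CBCT volumes image the whole
tooth, but at voxel sizes around 0.125 mm the crown surface they yield is too
coarse for appliance design, and repeated CT acquisitions are undesirable.
`toothfusion` reconstructs per-tooth models from each modality, rigidly
registers them, and fuses the laser crown with the CT root into a single
surface whose crown keeps the optical-scan accuracy.

The pipeline has five stages, each usable on its own:

1. **Crown segmentation** (`watershed_segment`): marker-based watershed on
   the arch mesh's dual graph, driven by an edge height function.
2. **CT tooth segmentation** (`propagate_contours`,
   `reconstruct_surface`): slice-by-slice hybrid level-set segmentation with
   Radon-transform separation lines between neighbouring teeth, then
   isosurface extraction.
3. **Registration** (`register_crowns`): plane-sectioned CT crown, PCA
   coarse alignment, quaternion ICP refinement; the laser crown stays fixed.
4. **Fusion** (`dbrg_fuse`): Delaunay-based region growing over the combined
   vertex set.
5. **Evaluation** (`average_distance`): directed average distance (AD) from
   the laser crown, which serves as the ground truth surface.

## The height function and watershed

For an edge between facets $t_1$ and $t_2$,

$$H(t_1, t_2) \;=\; w\,\frac{\operatorname{area}(t_1) +
\operatorname{area}(t_2)}{\max_i \operatorname{area}(t_i)} \;+\;
(1 - w)\, C(t_1, t_2),$$

where the maximum ranges over $t_1$ and its first-order neighbours and
$C \in [0,1]$ is a dihedral curvature score: zero for coplanar facets,
growing with the fold angle, with convex ridges attenuated to a fraction
(default 0.2) of their magnitude so that the concave valleys between crowns
dominate. The default weight is $w = 0.16$. The normalizer is asymmetric in
$(t_1, t_2)$; the per-edge watershed barrier is the conservative
$\max(H_{12}, H_{21})$, and including $t_1$ itself in the normalizer keeps
$H \le 2w + (1-w)$.

Seeds (one per tooth) are grown into occlusal caps by region growing below
an $H$ threshold (default: the 60th percentile), which prevents the
over-segmentation a plain watershed of this height field produces. The
remaining faces are flooded in ascending barrier order.

Two design choices matter for the crown/gingiva boundary, and both came out
of failure analysis on the synthetic arches:

* **Crease blocking.** The flood never crosses an edge whose accumulated
  concave turning (its own plus the strongest adjacent concave edge) exceeds
  `gingival_crease` (default $0.3\pi$). Per-edge dihedrals of smooth crown
  surface vanish with the sampling pitch while creases — the gingival sulcus
  and inter-tooth grooves — do not, so this rule is pitch-independent. The
  two-edge accumulation matters because a triangulated grid smears a crease
  over two consecutive edges. A quantile cutoff on the barrier height, the
  obvious alternative, is not robust: on our arches the sulcus barrier sits
  *below* the upper quantiles of the $H$ distribution, and a single
  sub-threshold gap anywhere on the margin ring lets the flood percolate
  into the entire gingiva.
* **Background basin.** The mesh's open border (certainly gingiva on an arch
  patch) is seeded as an explicit background marker, and queue ties are
  broken first-in-first-out so competing basins advance as fair wavefronts.
  The crown/gingiva boundary then settles where the tooth and background
  fronts meet — on the maximal-height margin ring — rather than depending on
  any global threshold.

## CT segmentation

Transverse slices are segmented tooth-by-tooth with an explicit-scheme
hybrid level set: a region term pulling the contour toward the Otsu split
between tooth and background intensities (`lambda1`, default 1), an edge
term advecting it toward gradient maxima (`lambda2`, default 1), and
curvature smoothing (`mu`, default 0.2), with a time step of 0.45 px and
periodic reinitialization to a signed distance. Between neighbouring teeth a
separation line is extracted as the minimum of a Radon sinogram (mean
intensity per line, restricted to lines separating the two blob centroids)
and enforced as a hard wall: the level set is clamped negative outside the
tooth's half-plane. A clean interproximal gap admits a family of equally
dark lines; among them the one most transverse to the centroid axis is
chosen, which is both deterministic and the anatomically meaningful
separation plane.

Propagation starts from a user-chosen slice in the crown, marches toward
crown and root ends using the previous slice's contour as the next
initialization, and stops a tooth when its contour area falls below 4 voxels
(the root apex) or the contour is lost.

Per-tooth contours are filled into an occupancy volume and surfaced at the
0.5 level. The extractor is the tetrahedral decomposition variant of
marching cubes (six Freudenthal tetrahedra per cell), which is watertight by
construction. Two numerical choices: interpolated vertices are kept at least
0.2 of a lattice step away from lattice corners (`snap`), so downstream
triangulations never see near-duplicate vertices — the positional bias is
below 0.2 voxel — and the result receives 10 iterations of shrink-free
Taubin smoothing to remove voxel-scale ripple. One visible cost: an isolated
single filled voxel reconstructs to a cell of about half the voxel volume.
Voxel index $(i,j,k)$ maps to mm as $\text{origin} + (\text{index} - 0.5)
\cdot \text{voxel size}$ (voxel-centre convention; 1-based indices).

## Registration

The CT tooth is sectioned with a plane perpendicular to its principal axis
at the height of maximal cross-sectional area — a proxy for the cervical
bulge — lifted by `plane_offset` (default 0.3 mm) toward the crown so the
registered CT part lies inside the region the laser scan also covers;
without the lift the below-margin band pulls ICP off by a systematic
fraction of a millimetre.

Coarse alignment follows the eigenvector-frame construction
$R_1 = EM_\text{laser} \cdot EM_\text{CT}^{-1}$,
$T_1 = \text{centroid}_\text{laser} - R_1\,\text{centroid}_\text{CT}$.
Eigenvalue ties are reported as ambiguous (a sampled cylinder errors out).
Two robustness choices were forced by observed failures:

* **Sign fixing by skewness.** Eigenvector signs are chosen so the cloud's
  third moment along each axis is positive, falling back to the
  farthest-point direction for symmetric clouds. The farthest point itself
  changes under subsampling and can flip the frame by 180°.
* **Multi-start over axis relabelings.** The two modality clouds cover
  different parts of the crown, so their eigenvalue *order* can differ;
  `register_crowns` therefore probes all 24 proper axis relabelings of the
  CT frame with 10 trimmed-ICP iterations on 600-point subsamples and keeps
  the best by a two-way (symmetric) mean-squared error — a directed score
  alone favours false optima where one cloud nests inside a subset of the
  other.

Fine registration is classical point-to-point ICP: kd-tree nearest
neighbours, closed-form quaternion fit, error
$E_C = \tfrac1M \sum_i D_{ij}^2$ (MSE, mm²) recorded after every applied
transform, stopping at $E_C < E_\text{th}$ (default $10^{-4}$ mm²) or
`max_iter` (default 100; the result then carries `converged = FALSE`, not an
error). $E_C$ is non-increasing. An optional distance-percentile trim
(`trim`; the pipeline default is 0.2) drops the worst correspondences from
each fit for partial-overlap robustness.

## Fusion

Fusion is a Delaunay-based region growing. The candidate set $T$ is the set
of all triangular facets of the 3D Delaunay tetrahedralization of the
combined crown + root vertices (CT vertices within `overlap_band`, default
0.1 mm, of the crown surface are discarded first, so the double-walled
overlap region does not seed non-manifold shells). The start triangle is the
minimum-circumradius facet at the globally highest vertex (z is the tooth
axis, crown up). Growth repeatedly admits the frontier facet with the
largest local smooth degree — the cosine between the consistently oriented
normals of the candidate and its accepted neighbour, averaged over shared
boundary edges — subject to edge-manifoldness, orientability and a
vertex-fan condition.

A greedy maximum-smoothness order alone is fragile on real candidate sets,
and the engine adds four safeguards:

* **Three priority tiers**: facets that coincide with an input-mesh face,
  then facets whose circumradius is at most 1.4× the local sampling spacing
  (distance to the 6th nearest neighbour), then the rest. Oversized facets
  skip over a sample point and bury it, leaving a hole no remaining
  candidate can fill; input-face preference reproduces the source surfaces
  verbatim wherever the Delaunay complex contains them.
* **Strict versus relaxed vertex rule**: during normal growth a candidate
  must reach every occupied vertex through a shared edge (growth never
  *creates* a pinched vertex, though it may heal one); when growth stalls
  with open boundary left, the smoothest frontier candidate is admitted
  under a relaxed rule that tolerates a transient pinch at an open boundary
  vertex — fronts legitimately meet this way and later acceptances merge the
  fans. Interior vertices (complete fans) are untouchable in both modes.
* **Normal guidance**: candidates whose oriented normal disagrees with the
  mean input-surface normal of their vertices (cosine below `min_align`,
  default 0.5) are never admitted; this suppresses chord facets spanning
  below the surface and fold-backs, and anchors the global orientation.
* **Peel-and-regrow**: if boundary remains after the queue drains, the
  accepted faces along it are removed and growth resumes, up to 6 rounds —
  escaping locally inconsistent frontiers.

Accepted facets further than twice the local spacing from both input
surfaces are dropped in a final pass. The exported `dbrg_admissible` keeps
the strict predicate (edge saturation, exhaustive vertex-fan enumeration,
orientation consistency) for local topology testing.

On well-sampled smooth surfaces the growth closes: complementary hemisphere
samplings of a sphere fuse into a closed, edge-manifold surface with Euler
characteristic 2, also when the two densities differ five-fold. On full
phantom teeth the output is edge-manifold and reproduces the laser crown to
well below the sampling pitch, but sharply concave occlusal fissures at
coarse sampling can leave isolated small holes in the root region — a known
limitation, reported per run in the fusion report attribute.

### The Delaunay backbone

The tetrahedralization is an incremental Bowyer–Watson construction with
three robustness measures worth recording. The insphere test is the 4×4
determinant evaluated in extended precision (an explicit circumcentre
cancels catastrophically for flat tets). Each insertion cavity is expanded
until it is star-shaped around the new point, using the parity-correct
signed volume of the prospective refill tet. And the enclosing super
tetrahedron is placed at $10^6$ times the data scale: a thin hull sliver of
depth $d$ has circumradius of order $1/d$, so nearer super vertices would
(correctly, for the augmented point set) forbid such slivers and dent the
hull. A deterministic symbolic perturbation of $10^{-9}$ of the bounding box
makes the triangulation unique on gridded or cospherical inputs; facets
always reference the original coordinates.

## The error metric

`average_distance(source, target)` computes, for every source vertex, the
true point-to-triangle distance to the target surface, and reports the mean
(AD), standard deviation, maximum and a histogram (50 bins to the 99.5th
percentile). The metric is directed and the laser data are the reference:
registration error is measured laser crown → registered CT crown, fusion
error laser crown → fused model. Source *vertices* (not uniform surface
points) are sampled, which slightly over-weights densely meshed regions; a
symmetric variant is available but off by default.

## The synthetic phantom

No clinical scans ship with the package; every claim is validated on an
analytic phantom with known ground truth (`phantom_scene`). A scene is a row
of teeth along the arch with per-tooth ±5 % size variation, a rigid
ground-truth modality transform between the CT and laser frames (rotation
drawn from 4–8°, translation up to ±2 mm per axis), and modality-specific
noise. All randomness derives from one seed.

Each tooth is a superelliptic crown capped by a cusped occlusal dome and
continued by a tapered root with a rounded apex. Several features exist
specifically so that the phantom poses the same difficulties as clinical
data, and their absence was in each case discovered by failure:

* the crown wall is a 0.6 mm quadratic **emergence-profile bulge**, steepest
  (≈80°) at the cervix — an unresolvable cliff wall thinner than the
  sampling pitch would make the margin crease invisible at any resolution;
* the gingiva is a **collar** that meets each tooth exactly at its cervix
  line and falls away at 20°, as real gums hug the tooth neck — with a flat
  gingiva floor the ground-truth label switch would sit on a featureless
  smooth slope that no geometric segmenter could find;
* the occlusal table is **buccolingually asymmetric** (lingual cusps 0.15 of
  the crown height lower), as on real molars — a mirror-symmetric crown
  makes per-tooth rigid registration genuinely ambiguous under 180°;
* the inter-tooth `gap` (default 0.3 mm) is the clearance between the
  *bulged* silhouettes, so crowns do not interpenetrate.

The laser analog samples the arch height field on a 0.05 mm grid (the
resolution class of intraoral scanners) with 5 µm vertex jitter; the CT
analog voxelizes the solid teeth at 0.125 mm (CBCT class), intensity 1000
on 0, blurred by a 0.1 mm Gaussian and degraded with noise of sd 30. What
the phantom does *not* emulate: enamel/dentin/pulp contrast, metal
artifacts, soft-tissue intensities, scan shadowing, or strongly angled teeth
— the slice-wise propagation strategy is known to struggle with the latter,
so passing tests here say nothing about tilted molars.

## Problem sizes and runtime choices

The default test suite exercises every stage at reduced sizes (two-bump
meshes of 10²–10⁴ faces, 64² slices, spheres of ≤1000 vertices) and runs the
full pipeline twice at the study resolutions on two-tooth scenes; the
acceptance script runs one three-tooth scene at 0.05 mm pitch and 0.125 mm
voxels (≈130 000 laser faces, ≈2·10⁶ voxels), which completes in a few
minutes on a single core. Teeth are premolar-sized (4 mm nominal width);
the sizes were chosen so a three-tooth scene represents the crowded-arch
geometry while the Delaunay complexes stay in the 10⁵-facet range.

## Worked example

```{r example, eval = FALSE}
library(toothfusion)

sc <- phantom_scene(n_teeth = 3, seed = 1)
gt <- scene_ground_truth(sc)
laser <- sample_laser_mesh(sc, pitch = 0.05)
ct <- voxelize_ct(sc, voxel = 0.125)
seeds <- phantom_ct_seeds(sc, ct$volume)

res <- run_pipeline(laser$mesh, ct$volume, gt$laser_seeds, seeds$seeds,
                    seeds$start_slice, out_dir = "recon_out")
print(res)

# how well was the hidden modality transform recovered?
err <- compose_transform(res$registrations[["1"]]$transform,
                         invert_transform(gt$modality_transform))
rotation_angle(err)     # degrees
sqrt(sum(err$t^2))      # mm
```

## Known limitations

* The slice-propagation CT stage assumes the tooth long axis is roughly the
  slice normal; strongly angled teeth are out of scope.
* Fused root regions can retain small holes where the CT mesh is sharply
  concave relative to its sampling; the surface remains edge-manifold and
  the crown region is unaffected.
* AD samples source vertices, not uniform surface area.
* The separation-line model is a straight line per slice; curved
  interproximal contacts in severely crowded arches would need a curved
  separation surface.
* STL files are assumed to be in millimetres; other units must be
  pre-scaled.
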