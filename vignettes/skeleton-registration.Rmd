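---
title: "Registering cross-source vascular point clouds by skeleton features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering cross-source vascular point clouds by skeleton features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelreg)
```

## The problem

Ultrasound-guided liver interventions need the intraoperative ultrasound (US)
view fused with a preoperative CT scan.  Both modalities can be reduced to a
3-D point cloud of the hepatic vessels, but the two clouds are *cross-source*:
they differ in sampling density, noise level, and coverage (the US sweep sees
only part of the organ), so surface-based rigid registration is brittle.
`skelreg` instead reduces both clouds to *homologous skeleton feature curves*
— smooth centreline curves of the vessel tree — and registers those.  Because
a centreline is far less sensitive to which part of the lumen surface was
sampled, the feature representation is the robustness mechanism.

The pipeline is:

1. **Voxel down-sampling** (0.8 mm lattice) and **Laplacian contraction** of
   the cloud onto a coarse curve skeleton;
2. **Graph extraction**: Euclidean minimum spanning tree over the contracted
   points, degree classification (endpoints = degree 1, junctions = degree
   ≥ 3), twig pruning, junction-cluster simplification, and splitting into
   branch/trunk segments;
3. **Feature curves**: each segment's skeleton points are ordered by PCA,
   original vascular points are assigned to centre stations, centres are
   recalculated robustly, and a quadratic space curve is fitted per segment;
4. **Two-stage registration**: a globally optimal branch-and-bound ICP
   (trimmed, over the full rotation space) for coarse alignment, then a
   plain point-to-point ICP for refinement;
5. **Evaluation**: skeleton RMSE, tumour-centre target registration error
   (TRE), Dice, volume similarity, and surface Dice at a 5 mm tolerance.

## Contraction model

Positions `X` are updated by the least-squares system

$$\begin{bmatrix} W_L L \\ W_H \end{bmatrix} X' =
  \begin{bmatrix} 0 \\ W_H X \end{bmatrix},$$

where `L` is an umbrella Laplacian over the symmetrized k-nearest-neighbour
graph with inverse-distance weights \(w_{ij} = 1/\max(\lVert p_i-p_j\rVert,
\varepsilon)\), \(\varepsilon = 10^{-6}\) mm.  The kNN graph and `L` are
built once from the down-sampled input and held fixed; because `L 1 = 0`,
the update commutes exactly with rigid motions of the input (given identical
neighbourhoods), which the test suite asserts.

Per iteration the scalar contraction weight `W_L` is multiplied by 2 and the
per-point attraction weight is rescaled by (initial local extent / current
local extent), where the local extent of a point is its mean distance to its
k neighbours.  Iteration stops after `max_iter` rounds or when the summed
extent changes by less than the termination ratio between rounds.

Defaults (down-sample 0.8 mm, k = 100, initial contraction weight 0.5,
initial attraction weight 4 for phantom data and 10 for human data, 10
steps, termination ratio 0.003) are the vascular skeleton-contraction
settings; they can be overridden per cloud in the YAML configuration, since
no single parameter set suits every vascular cloud.

**Contraction weight cap.**  The doubling schedule must be capped: left
unchecked, the smoothing term grows geometrically while the attraction term
grows only like the inverse extent ratio, and on millimetre-scale vascular
clouds of a few thousand points the system then collapses side branches into
the trunk (we observed a complete tree reduced to a single short curve).
The default cap is 8: tubes still collapse onto their axes within the
10-step budget (a 5 mm-radius test cylinder reaches the axis to within
0.9 mm), while the coarse skeleton stays close to the true centreline.  The
gentler contraction leaves more spurious graph structure, which the twig
pruning and the station validity gates below absorb.  This is the single
most consequential numerical choice in the pipeline.

**Known artefact.**  Laplacian contraction shortens segments axially (ends
pull inward).  The feature stage compensates: extra candidate centre
stations are placed past each segment end along the end tangent, and only
those that actually collect vascular points survive, so fitted curves
recover the true vessel span without extrapolating the quadratic.

## Skeleton graph

The minimum spanning tree of the complete Euclidean graph on the contracted
points is computed with Prim's algorithm and on-the-fly distances (O(N²)
time, O(N) memory; identical result to materializing the complete graph).
Degree-2 vertices are chain points, never nodes.  Two clean-up passes
precede segmentation:

* **Twig pruning** removes terminal chains shorter than
  `min_branch_length` (default 5 mm).  An MST over a contracted cloud grows
  spurious one-to-two-vertex leaves wherever a point sits slightly off the
  skeletal curve; without pruning these masquerade as vessel branches.  A
  junction-free path graph is never pruned.
* **Junction simplification** collapses clusters of junctions closer than
  `merge_radius` (default: twice the mean MST edge length) along the tree
  into a single vertex at their centroid, together with the chain vertices
  between them.

Segments are the maximal chains between nodes; a branch has at least one
endpoint, a trunk connects two junctions.  On a tree the Dijkstra shortest
path and the unique simple path coincide; the tests check both against an
exhaustive path enumeration.

## Feature curves

For each segment, ordered by projection onto its PCA axis, centre stations
are placed every `center_spacing` (default 2.5 mm) of arc length.  Original
vascular points are assigned to their globally nearest station within
`assign_radius` (15 mm, closed inclusion); the nearest-station rule resolves
the overlap between neighbouring search balls so every point is used once.

Each station's centre is recalculated: the initial centre `C` is the member
centroid; the second principal component of the members (projected
perpendicular to the vessel axis) defines the *vertical*; the two member
points nearest `C` within 15°-half-angle cones about ±vertical are the wall
points `A`, `B`; members within `d/2 = ‖A−B‖/2` of `C` are averaged into the
refined centre `C′`.  A strict ray would almost never hit a discrete point,
hence the cone; if a cone is empty the nearest member overall is used, and
degenerate stations fall back to `C′ = C`.

Three validity gates follow, motivated by the partial-coverage and
branching failure modes:

* stations whose members leave an **angular gap** larger than 200° around
  the axis are discarded — a half-seen lumen biases *any*
  centroid-of-neighbours estimate toward the visible wall, so such stations
  cannot be de-biased, only removed.  Full cross-sections with 30% random
  dropout stay far below the gate.
* stations closer than `junction_margin` (5 mm) to a junction vertex are
  discarded: their search balls mix points of two or more vessels, so their
  centroids sit between the lumens rather than on either axis;
* after fitting, **curve samples farther than 4 mm** (about the largest
  vessel radius plus the noise scale — a sample on a vessel axis lies
  within one radius of the lumen surface) from the segment's member points
  are discarded as off-vessel artefacts.

Stations with fewer than `min_station_points = 5` members are discarded (a
centroid of a handful of surface points is too noisy to anchor the curve),
and the assignment/refinement round is iterated `refine_passes = 4` times:
with the gates in place the later passes pull high-leverage end stations
onto the axis (on a straight test tube the maximum curve deviation drops
from about 1.5 mm to below 0.5 mm).

Each coordinate of the surviving centres is fitted by least squares as a
quadratic polynomial in the normalized axial parameter and sampled at
`curve_samples = 25` uniform parameter values — dense enough for ICP
correspondences, sparse enough to keep the representation simple.  In the
human profile, curves are weighted by normalized polyline length (reducing
the influence of short irrelevant branches; the actual weights used for the
published human experiments are not reported, so length-normalization is
this package's choice, overridable per segment) and terminal branch curves
are thinned to every 5th sample (first and last kept).

### What the centre refinement does and does not do

The `d/2`-ball refinement is an *outlier rejector*: it protects the centre
estimate when a station's member set contains points of a neighbouring
structure beyond the local diameter.  It cannot repair a half-seen
cross-section — on a half ring every proximity-selected subset is biased
toward the seen wall, and in simulation the refinement leaves such centres
unchanged (the far cone is empty and the operation degenerates).  That is
why the angular-gap gate exists: partial cross-sections are dropped, not
repaired.

## Registration

Both curve sets are flattened to point sets (per-curve weights realized by
proportional seeded resampling) and jointly normalized: translated by the
joint centroid and scaled by the largest joint extent.  The coarse stage is
a branch-and-bound search over the joint rotation (axis-angle cube of width
2π) and translation cube, best-first on the standard per-point
uncertainty-radius lower bound

$$\underline{e}_i = \max\bigl(d_i - 2\sin(\min(\sqrt3\,\sigma_r/2,\,\pi/2))
  \lVert x_i \rVert - \sqrt3\,\sigma_t,\ 0\bigr),$$

with trimming (fraction 0.1) applied to both bounds, octant splits of
whichever cube family currently contributes the larger uncertainty, and an
inner trimmed ICP that polishes incumbents — both when a node's upper bound
improves on the incumbent and periodically from the most promising node's
centre, which finds the global basin long before the bounds close.  The
search stops when the incumbent trimmed MSE reaches `MSEThresh = 0.001`,
when the bounds close, or at the expansion budget.

Distances inside the branch-and-bound are measured with the joint cloud
scaled to span 2 (extent [−1, 1]³), the convention of the original
globally-optimal ICP tool in which `MSEThresh = 0.001` and the ±0.5
translation cube are calibrated; evaluated on a span-1 normalization the
same threshold is four times looser and admits wrong-basin stops.

The fine stage is plain point-to-point ICP from the coarse result: at most
20 iterations, no scale, no farthest-point filtering, all correspondences
kept, a seeded uniform subsample above 50,000 source points, stopping when
the RMS decrease falls below 10⁻⁶.  The update that would increase the RMS
is rejected, so the residual trace is non-increasing.  A parallelism bound
(`max_workers = 7`) is carried as a resource contract; no result depends on
it.

Internally the optimizer always matches the US-like (fixed) features as
source onto the CT-like (moving) features as target — the partial set onto
the complete set, which keeps every source point explainable.  The
`direction` flag selects only the reported mapping; the default `ct_to_us`
reports the transform that carries the CT image onto the US frame (the
inverse of the optimized one), which is the mapping a fusion display needs.

## Evaluation metrics

* `skeleton_rmse`: directed nearest-neighbour RMSE from the transformed
  feature samples of one set to the other (the quantity the fine ICP
  minimizes; the correspondence-free definition suits unpaired feature
  sets).
* `target_registration_error`: ‖T·c_moving − c_fixed‖ for tumour mass
  centres.
* `dice_and_vs`: voxel Dice `2|A∩B|/(|A|+|B|)` and volume similarity
  `1 − ||A|−|B||/(|A|+|B|)` on a shared grid (default 1 mm voxels).
* `surface_dice`: symmetric surface overlap at tolerance τ (default 5 mm,
  the clinical ablation margin).

## The synthetic phantom

`vessel_tree_spec()`/`make_case()` generate branching vessel trees at
liver-portal-vein scale: a ~150 mm quadratically bent trunk (radius 3 mm),
3–8 side branches of 40–80 mm (radius 2 mm) at 35–70° take-off angles.
Tube surfaces are rendered per source profile:

* **CT-like**: 0.7 points/mm², σ = 0.2 mm noise, no dropout;
* **US-like**: 0.45 points/mm², σ = 0.35 mm noise, 30% random dropout, and
  an optional coverage cone (`"auto"` fits a seeded viewpoint keeping about
  85% of the tree) emulating the limited scanning range of the probe.

The moving (CT-like) cloud is displaced by a seeded rigid transform sampled
uniformly within magnitude bounds (default rotation ≤ 30°, translation
≤ 20 mm in a ball); spherical tumour markers (radius 6–10 mm) near the
vessels are recorded in both frames with 1 mm voxel masks.  The generating
centreline is stored and serves as the ground-truth oracle for every
skeleton and feature accuracy test.

What the phantom does **not** emulate: ultrasound speckle and shadowing,
reconstruction distortion, anastomoses (the skeleton is forced to a tree,
as the MST requires), deformable motion, and real segmentation errors.
Passing the synthetic suite therefore demonstrates the geometry of the
method — contraction, graph segmentation, curve fitting, globally optimal
alignment — not clinical performance.

## Numerical choices and degenerate inputs

* Voxel binning uses the origin-aligned lattice `floor(p/edge)`, making the
  down-sampling exactly idempotent (each centroid stays in its own cell).
  The lattice is rotation-anisotropic; rigid equivariance of the pipeline
  holds exactly when down-sampling is disabled and approximately otherwise.
* Coincident points get epsilon-floored Laplacian weights (warning) rather
  than an abort; exact duplicates are merged before the MST.
* kNN ties break toward the lower index; MST edge ties resolve by scan
  order; tie-broken results are deterministic across runs and thread
  counts.
* The `d/2`-ball membership test uses a 10⁻⁹ mm closed-inclusion epsilon so
  exact-diameter configurations (a perfect ring) are handled exactly.
* All randomness (rendering, dropout, transform sampling, weighted curve
  resampling, ICP subsampling) derives from explicit seeds; generation
  restores the caller's RNG state.
* Desk-scale problem sizes: synthetic clouds of roughly 2,000–6,000 points
  after down-sampling, feature sets of 100–250 samples, and a
  branch-and-bound budget of 5,000 expansions are used throughout the
  bundled evaluations; clouds one order larger are handled by the same
  code path.

## Known limitations

* The coarse skeleton inherits the classic Laplacian-contraction artefacts
  (axial shortening, junction blending); the feature stage compensates but
  segment coverage of the true centreline is typically 50–80% on sparse
  ultrasound-like renders.
* The MST forces a tree: vascular loops are broken arbitrarily.
* Rigid registration only; respiratory deformation is out of scope.
* The branch-and-bound certificate (bound closure) is rarely reached within
  the desk-scale budget; in practice the incumbent found via the threshold
  stop or budget exhaustion is returned, flagged by `converged`.
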