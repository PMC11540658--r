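---
title: "Measuring plant traits from 3D point clouds: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring plant traits from 3D point clouds: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocloud)
```

phenocloud turns a metrically calibrated 3D point cloud of a greenhouse
plant into three standard growth-survey traits: inter-node length along
the main stem, single-leaf area, and fruit volume. The clouds it
expects are the kind exported from neural-radiance-field (NeRF) or
structure-from-motion reconstructions of a plant imaged from a limited
dome of camera poses: dense and clean on the camera-facing side, noisy
at the millimeter scale, and sparse or absent on the far side. This
vignette explains each stage's model, the tunable parameters and their
defaults, the numerical choices that matter, and what the synthetic
fixtures do and do not establish about real data.

## Units and metric calibration

All trait operations report physical units, so they require clouds
whose coordinates are meters (`is_metric = TRUE`); non-metric clouds
are refused rather than silently mismeasured. Reconstruction output
arrives in arbitrary units; the scale factor is recovered from a
calibration marker of known physical size (default 0.30 m edge) that
was reconstructed along with the scene:

\[ s = \frac{1}{|E|}\sum_{(i,j) \in E} \frac{L_\mathrm{phys}}{\lVert c_i - c_j \rVert}, \]

the mean over marker edges of physical over reconstructed edge length.
Edge-ratio averaging needs no correspondence to a canonical marker
frame and is exactly invariant to rigid motion of the reconstruction.
The residual RMS — the spread of the per-edge physical-minus-scaled
lengths, in meters — is the calibration's quality diagnostic; it is
zero for a noise-free reconstruction. A calibration is computed once
and persisted as JSON, because a repeatable camera rig lets the same
pose set (and hence the same scale) serve many captures.

```{r calibration}
mk <- generate_marker(scale = 5, corner_noise_sd = 0.001, seed = 1)
estimate_scale(mk$observation)
```

## Inter-node length: contraction, spanning tree, nodes

The stem stage reduces a tubular stem-and-branches cloud to a curve
skeleton, organizes the skeleton into a tree, and reads inter-node
lengths as distances between branch nodes.

**Laplacian-based contraction.** Each iteration solves, per coordinate,
the regularized sparse least-squares system

\[ \begin{bmatrix} w_L \, \mathbf{L} \\ \mathrm{diag}(w_{H,i}) \end{bmatrix} X' =
   \begin{bmatrix} 0 \\ \mathrm{diag}(w_{H,i})\, X \end{bmatrix}, \]

balancing a graph-Laplacian smoothness term against per-point
attraction to the current positions. The Laplacian uses a
k-nearest-neighbor graph (k = 12) with inverse-distance weights,
row-normalized. Two numerical choices proved essential:

* **The neighborhood graph is built once, from the original cloud, and
  kept fixed.** If the graph is recomputed on contracted positions,
  collapsed clusters become their own nearest neighbors, the Laplacian
  force inside a cluster vanishes, and contraction freezes in a
  "clumped" state well before reaching the curve skeleton.
* **Iteration stops when progress stalls.** The contraction weight
  $w_L$ is amplified (×3 per iteration, capped at 2048) while the
  attraction weights grow as local extent shrinks
  ($w_{H,i} \propto S^0_i / S_i$). Left running to the cap, the solve
  enters a regime where the whole structure drifts toward a global
  harmonic (straight-line) configuration and junction geometry
  degrades. The mean distance to the k nearest neighbors — the "local
  extent" — collapses rapidly and then plateaus exactly when the cloud
  has reached its curve skeleton, so contraction stops either at
  `convergence_ratio` (1% of the original extent) or when an iteration
  improves the mean extent by less than 5%.

**Skeleton graph.** Contracted points are voxel-downsampled (5 mm
default) and connected by the minimum spanning tree of their complete
Euclidean graph (Kruskal with lexicographic tie-breaking; a k-NN graph
with a connectivity check above 5000 vertices). Voxel binning happens
in the cloud's canonical principal frame — axes from the covariance,
signs oriented by the skewness of the projections, an intrinsic
property of the data — so the same plant measured in two poses yields
the same skeleton. Terminal twigs shorter than 4 voxel spacings are
pruned: contraction noise leaves one-or-two-voxel spurs that would
otherwise masquerade as branch nodes. Degree classifies the remaining
vertices (branch ≥ 3, end = 1), and branch vertices closer than twice
the voxel spacing are merged to their centroid, since contraction can
split one anatomical node across adjacent vertices.

**Distance semantics.** An inter-node length is the straight-line
Euclidean distance between two node coordinates, not the along-tree
path length; both are reported (`stem_internodes()` returns
`path_lengths` alongside), and for a curved stem the path length is
the larger of the two. Which anatomical node pair constitutes "the"
measurement stays with the caller; `extract_node_positions()` lists
the candidates sorted by height.

```{r stem}
fx <- generate_stem(node_spacings = c(0.10, 0.25, 0.40), seed = 1)
res <- stem_internodes(fx$cloud)
round(res$lengths, 4)   # truth: 0.10 0.25 0.40
```

## Leaf area: smoothing, ball pivoting, triangle sum

**Moving least squares.** Each point is projected onto a local
weighted-least-squares polynomial surface: the neighborhood's principal
plane supplies a frame, an order-2 polynomial height field is fitted
with Gaussian weights, and the point moves to its height on that
surface. Order 2 is the default because leaves are curved; order 1
flattens them. The default search radius is 4× the median
nearest-neighbor distance with bandwidth radius/2 — appropriate for
the sub-millimeter noise of a good reconstruction. The radius must
resolve the noise amplitude: for noise of standard deviation σ a
radius near 10σ is appropriate, and the density-derived default cannot
know σ, so heavier noise calls for an explicit
`mls_params(search_radius = ...)`. Points with fewer than
`min_neighbors` neighbors pass through unchanged and are flagged.

**Ball pivoting.** A ball of fixed radius rolls over the cloud,
settling on three points to seed a triangle and pivoting around front
edges, emitting a triangle whenever it rests on a third point with no
other point inside. Radii ascend through a schedule — default
{2, 3, 4}× the median nearest-neighbor spacing — with each larger ball
re-attempting the boundary edges the smaller one left, bridging
sampling gaps. The schedule starts at 2× rather than the 1.5× a
regular grid would tolerate because Poisson-like random sampling
leaves gaps of several times the median spacing; schedules starting
lower leave pinholes and bias area low by ~20% on test surfaces.
Normals are estimated per point (neighborhood PCA) and oriented
consistently by propagation along a minimum spanning tree; leaves are
open surfaces with no global inside/outside, so only consistency
matters. Pivoting runs in the cloud's canonical principal frame so the
emitted connectivity is identical for rigidly moved inputs. The mesh
is not forced watertight — leaves are bordered surfaces, and closing
them would fabricate area. Coincident duplicate triangles (same vertex
set, opposite winding), which pivoting can emit on open surfaces, are
counted once by `mesh_area()`.

**What the area means.** The reported value is the single-sided area
of the reconstructed surface: the sum over faces of half the
cross-product magnitude of two edge vectors. Two biases are inherent
and documented rather than corrected: the mesh is inscribed in the
true surface (negligible at leaf curvatures), and a boundary strip of
roughly half a sample spacing around the leaf margin is not covered by
any triangle. The boundary deficit scales with (perimeter × spacing) /
area — about 2–4% for the fixture sizes used here — and shrinks as
density grows, which the density-convergence test checks.

```{r leaf}
leaf <- generate_leaf("half-cylinder", seed = 1)
res <- leaf_area_pipeline(leaf$cloud)
c(measured = res$area_m2, truth = leaf$truth$leaf_area)
```

## Fruit volume: ellipsoid least squares

A partially observed fruit is modeled as an ellipsoid; fitting the
visible cap extrapolates the unobserved rear under a symmetry
assumption. For a centered, axis-aligned cloud the semi-axes minimize

\[ f(a,b,c) = \sum_{i=1}^{M} \left( \frac{x_i^2}{a^2} +
   \frac{y_i^2}{b^2} + \frac{z_i^2}{c^2} - 1 \right)^2, \]

and the volume is $V = \tfrac{4}{3}\pi abc$. The optimizer is
Levenberg–Marquardt in $(\log a, \log b, \log c)$ — positivity without
constraints — with an analytic Jacobian, initialized from the per-axis
maximum absolute coordinate, converging at relative objective change
below 1e-12 or 500 iterations. A two-stage exhaustive grid search over
$(a, b, c)$ (40³ cells, then a refined 40³ around the best cell)
serves as the independent oracle in the tests; the objective is
evaluated on the grid through its second-moment matrices, which makes
the oracle exact and fast.

**Pose.** The objective contains no center or rotation, so a pose must
be chosen. The plain centroid fails badly under occlusion — the
centroid of a half-shell sits in the middle of the cap, not at the
body center, and at 50% coverage volume errors reach ~40%. The pose is
therefore estimated in two steps: (1) `align_to_principal_frame()`
centers on the algebraic least-squares *sphere* center (linear in its
parameters, exact for spherical caps, with a centroid fallback when
the linear system degenerates) and takes covariance eigenvectors about
it; (2) `fruit_volume_pipeline()` calls
`fit_ellipsoid(refine_center = TRUE)`, which re-minimizes the same
objective jointly over semi-axes, a center offset, and a small
rotation (9 parameters). The rotation matters because a nearly
isotropic observed cap has near-degenerate covariance eigenvalues,
making PCA axes arbitrary; an axis-aligned model in an arbitrary frame
cannot fit. With pose refinement, median volume errors on seeded
fixtures are ~0.3% at full coverage, ~0.4% at 75%, and ~6% at 50%
coverage. Sphere-like fruits leave the axes (and the refinement
rotation) unidentifiable among themselves, which is harmless: volume
is symmetric in $(a, b, c)$.

The `coverage` diagnostic — the fraction of directions from the fitted
center that contain observed points, on a 64-cell Fibonacci lattice —
lets downstream users filter fits from badly occluded fruit.

```{r fruit}
fr <- generate_fruit(c(0.040, 0.030, 0.030), coverage = 0.7, seed = 1)
res <- fruit_volume_pipeline(fr$cloud)
c(volume_cm3 = res$volume_cm3,
  truth_cm3 = fr$truth$fruit_volume * 1e6,
  coverage = res$coverage)
```

## Synthetic fixtures: what they emulate, what they do not

Every stage is testable without data downloads because the generators
in `generate_stem()`, `generate_leaf()`, `generate_fruit()` and
`generate_marker()` produce organ clouds with *analytic* ground truth
— node spacings, areas and volumes are computed from the generator
parameters in closed form, never measured from the generated points.
Fixtures are seeded and regenerate bit for bit (a single
Mersenne-Twister stream per fixture, sub-streams at fixed offsets).

The generators emulate the features of forward-facing capture that
drive the method's error behavior: area-uniform surface sampling
(rejection sampling with the exact area-element weight — naive
parameter-uniform sampling would distort the meshing tests), isotropic
Gaussian surface noise (2 mm for stems, 0.5 mm for leaves and fruit),
and one-sidedness — fruit clouds keep only points whose outward normal
lies within the angular cap around the view direction covering a given
fraction of the normal sphere, and the s-curl leaf can drop its
far-facing half, reproducing the real failure mode where a curled
leaf's hidden side is never captured and the measured area biases low.

Default conditions: stems are 8 mm-radius tubes with 5 mm-radius,
6 cm lateral branches on a golden-angle phyllotaxy at 6×10⁴ points/m²;
leaves are sampled at 2×10⁵ points/m² (about 1 600 points for a 5 cm
disc), chosen so that the boundary-strip deficit stays a small
fraction of the 5% recovery budget; fruits carry 1 500 surface points
before the coverage cut. These densities are realistic for close-range
reconstructions of single organs.

What passing fixtures does *not* establish: real NeRF exports have
spatially correlated, view-dependent noise, ghost points near
silhouette edges, and segmentation imperfections (neighboring-organ
fragments) — none of which the generators model. The tests certify
the geometry pipeline, not the upstream reconstruction or the manual
segmentation step it replaces programmatically (`crop_cloud()`).

## Evaluation conventions

`evaluate()` reports $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ about
the truth mean — the predicted-versus-truth convention, which equals 1
only for exact agreement — and also the squared Pearson correlation
(`pearson_r2`) for users who expect that definition; the two differ
when predictions are biased. MAPE is the mean of
$|{\hat y} - y| / |y|$; zero-truth pairs are excluded with a warning.
Pairs are exchangeable, so both metrics are invariant to reordering.

## Problem sizes and determinism

The test-suite fixtures use ~1 000–6 000 points per organ, 10 seeds
per recovery experiment, 50 seeds per occlusion level, and
brute-force oracles at sizes where exhaustive enumeration is exact
(all labeled trees on up to 8 vertices for the spanning tree; 40³
grids for the ellipsoid). These sizes make every statistical claim in
the tests reproducible in minutes on one core while keeping the
estimates' own uncertainty well below the tolerances being checked.
All randomness is seeded; identical configurations reproduce identical
trait reports, and fixture files are byte-identical across runs.

## Known limitations

* Node-pair selection for inter-node measurement is exposed, not
  automated; anatomically informed selection is out of scope.
* Leaf area is single-sided reconstructed-surface area with a small
  systematic boundary deficit; no thickness model.
* The ellipsoid model under-represents strongly lobed fruit; the
  residual and coverage diagnostics flag, but do not fix, such cases.
* The programmatic crop regions (box, projected polygon) replace an
  interactive segmentation step; no semantic organ segmentation is
  attempted.
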