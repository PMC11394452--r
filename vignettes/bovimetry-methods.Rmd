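---
title: "Measuring cattle body size from segmented point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cattle body size from segmented point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovimetry)
```

# Overview

`bovimetry` implements a two-stage pipeline for non-contact livestock
morphometry. First, a hierarchical point-cloud network segments a standing
cow into seven anatomical parts — four legs (labels 0–3) and the front,
middle and back of the trunk (labels 4–6). Second, a geometric pipeline
measures six body-size parameters from the segmented parts: withers height
(WH), hip height (HH), body length (BL), thoracic circumference (TC),
abdominal circumference (AC) and cannon circumference (CC), all in
centimetres. Working per part, rather than on the whole cloud, lets each
measurement anchor its keypoints in the anatomy it actually needs, which is
what makes the pipeline robust to nonstandard stances and occlusion.

Throughout the package the frame is right-handed with x running
anteroposteriorly (head to tail), y mediolaterally, z up, the ground at
z = 0, and units of centimetres. Real herd scans are not redistributable,
so a parametric synthetic-cow generator with analytic ground truth serves
as the test bed; its assumptions and limits are described below.

# DUOS sampling

Farthest point sampling, the usual choice for the set-abstraction stages of
hierarchical point networks, is oblivious to density: on livestock scans —
characteristically dense on the trunk and sparse on the limbs — it
under-represents exactly the parts that segmentation most needs. Dynamic
unbalanced octree grouping (DUOS) replaces it with three steps:

1. **Capacity-constrained octree.** The bounding cube is subdivided at cell
   midpoints whenever a cell holds more than `leaf_capacity` points
   (default 64) and is shallower than `max_depth` (default 10, which also
   guards against coincident points). Dense regions therefore produce deep,
   small leaves and sparse regions shallow, large ones; the leaves always
   partition the cloud.
2. **Proportional quotas.** The requested number of centres `n1` is split
   across leaves proportionally to leaf population using largest-remainder
   rounding. Remainder ties go to the larger leaf, then to the earlier leaf
   in depth-first octant order; quotas are capped at leaf sizes with the
   excess redistributed one slot at a time to the leaf with the most
   remaining capacity. These tie-breaks make the allocation fully
   deterministic.
3. **Density-filtered selection.** Within a leaf, candidates are ranked by
   distance to the leaf-cell centre (ties by point index). A candidate
   whose local density — the number of other points within
   `density_radius` (default 2.5 cm) — falls below `density_threshold`
   (default 3) is skipped as probable sensor noise and recorded; the next
   ranked candidate takes its place. A leaf that runs out of eligible
   candidates hands its deficit to the leaves with the most remaining
   eligible candidates, and if the whole cloud runs dry the threshold is
   relaxed to zero for the remaining deficit, so exactly `n1` unique
   centres are always returned (the relaxation is flagged in the result).

Density is measured against the whole cloud by default; a `density_scope =
"leaf"` option confines it to the candidate's leaf. Whole-cloud density was
chosen because noise near a part boundary should be judged against
everything nearby, not only the points that happen to share a cell. Local
density always excludes the query point itself, so an isolated point has
density 0 and "density below threshold" cleanly captures isolated noise.

Neighbour searches (fixed-radius counts, ball queries, k-nearest
neighbours, FPS) run through a uniform-grid spatial hash in compiled code;
the grid only prunes candidates, so results are exactly those of the
brute-force computation, and the tests assert that equivalence.

# The segmentation network

The network follows the familiar encoder–decoder design for point clouds:
set-abstraction stages sample centres (with DUOS), gather fixed-size ball
neighbourhoods around them (nearest-first, underfull groups padded by
repeating the centre, coordinates re-expressed relative to the centre),
apply a shared per-point linear+ReLU map and max-pool channel-wise; feature
propagation stages interpolate coarse features back to finer levels with
inverse-distance weighting, concatenate skip features and apply another
shared map; a final linear layer scores the seven classes, and each point
takes the argmax (ties to the lowest class index).

The IDW interpolation uses the `k = 3` nearest known points with weights
`1/d^p`, `p = 2`; a query coinciding with a known point copies that point's
feature exactly (the `d = 0` branch), and `k` is clamped when fewer known
points exist. The training objective is the mean cross-entropy
`-mean(log p[true class])` over points, with probabilities clamped at
`1e-12` before the logarithm. Segmentation quality is summarized by overall
accuracy (OA), the fraction of correctly labelled points, and mean
intersection-over-union (mIoU) with per-class
`IoU = p_ii / (row_i + col_i - p_ii)` on the confusion matrix. Classes
absent from both truth and prediction are excluded from the mIoU mean by
default (an `include_absent` flag scores them as 1 instead); averaging over
never-present classes would only dilute the statistic.

No deep-learning framework is assumed: layers, max-pool routing, IDW
operators and Adam are implemented directly in matrix algebra with
hand-written gradients. The decisive simplification is that the sampling
and grouping structure depends only on coordinates, never on weights, so it
is computed once per cloud and cached as sparse gather/interpolation
operators; every training step is then dense BLAS. The default toy
configuration (two stages of 256 and 64 centres, group size 32, feature
widths 64/128, Adam at `5e-3`, one step per cloud per epoch with
deterministic reshuffling) trains on twenty 1,024-point clouds for 40–50
epochs in about two minutes on one CPU core. Optimizer, learning rate and
widths are configuration, documented in `network_config()`; training is
bit-reproducible given a seed, and checkpoints reload to identical
predictions.

This scale is deliberately small: it demonstrates that the architecture
learns the part structure (the tests require ≥ 0.90 training OA and
≥ 0.85 held-out OA on separable synthetic cows), not that it reaches
field-grade accuracy on real herds.

# The measurement pipeline

All measurements share a ground reference `z0`, the 2nd percentile of z
over all leg points — a hoof-level estimate robust to below-ground
outliers. Transverse slices are slabs `|x - x0| <= thickness/2` (default
3 cm) projected to the (y, z) plane.

**Heights.** The top keypoint of each relevant leg is the centroid of its
top `q`% of points by height (default 5%). The slicing plane passes through
the midpoint of the two leg keypoints — using the midpoint keeps the plane
between the legs even in a nonstandard stance — and the height is the
maximum-z point of the body slice minus `z0`. WH uses the front body and
front legs; HH the back body and hind legs.

**Circumferences.** A transverse slice is contoured with a 2D alpha shape
(`alpha` 5 cm): a pair of points at distance ≤ 2·alpha forms a boundary
edge when one of the two radius-alpha disks through them is empty, and the
boundary points are ordered by angle about their centroid. TC slices the
front body at the front-leg keypoint midpoint; AC slices the middle body
through its lowest point p4 (the belly line). The slice is body-only; leg
points would only perturb the contour with structure that is not girth.

**Occlusion repair.** A fence often hides one flank. The repair detects the
largest angular gap between consecutive contour points; a gap is real when
its chord exceeds `gap_threshold` (8) times the median spacing *and* 15% of
the contour's bounding-box diagonal — the second guard stops locally uneven
sampling from masquerading as occlusion. The intact arc is mirrored across
the vertical line through the contour's topmost point (the dorsal midline,
the anatomical symmetry axis in a transverse slice), rigidly shifted so the
reconstruction meets the gap flank, and only the mirrored points falling
inside the gap's angular range are kept, so the repair never double-covers
the intact side. On symmetric cross-sections this restores the perimeter to
within 2% for occlusions up to ~45%.

**Cannon circumference.** The foreleg is cut into z-bins (default 6 cm);
among the bins in the lower half of the leg — the restriction that avoids
the knee flare — the one with the smallest anteroposterior extent locates
the cannon. Because the region below the knee is close to cylindrical,
every populated lower-half bin contributes to the radius estimate, with the
radius linearly detrended against z and evaluated at the selected bin, so a
residual taper does not bias the result. If the points subtend less than a
full turn (largest angular gap above `gap_angle`, 60°), the scan was
one-sided and the observed points are mirrored across the chord between the
gap flanks before the perimeter is taken.

**Body length.** Two-pass density extraction isolates keypoint candidates
on the front+back body: pass 1 keeps points whose local density falls below
a threshold (by default the 25% density quantile — the shoulder and ischial
ends read as low-density because of their high surface curvature, and a
quantile adapts the threshold to each animal's sampling density); pass 2
drops, within the kept set, points below a small density floor (isolated
noise). K-means with k = 2, initialized at the x-extremes for determinism,
splits the candidates into a shoulder-end cluster D and an ischial-end
cluster E; BL is the distance from the minimum-x point of D to the
maximum-x point of E. The maximum-x reading for p6 (a mirrored minimum-x
option exists behind a flag) pairs the two anatomical extremes.

**Perimeter numerics.** The raw polygon perimeter of an ordered contour is
the sum of consecutive distances plus the closing edge — exactly the
closed-polygon formula, and the tests pin it to closed forms (a unit square
gives 4; a regular 100-gon with circumradius 1 gives `200*sin(pi/100)`).
The circumference *measurements* add three numerical refinements, each
needed for a different failure mode of raw polygons on sampled slices:

- *Angular bin-averaging with radius smoothing.* Slice points are binned by
  angle about the contour centroid and each bin contributes its mean angle
  and mean radius, followed by a circular moving average (window 3) of the
  radius only. Averaging the radius rather than the points suppresses the
  chord-length inflation that radial sensor noise causes without shrinking
  the shape.
- *Chord-to-arc correction.* An m-vertex polygon inscribed in a smooth
  convex contour understates the arc length by the factor
  `sin(pi/m)/(pi/m)`; multiplying by its inverse removes the bias, which
  matters for sparse cannon slices (m ≈ 10–30).
- *Curvature debias.* Isotropic noise of standard deviation sigma pushes
  the apparent radius of a small cross-section outward by about
  `sigma^2 / (2r)`; the cannon estimator removes the corresponding factor,
  with sigma estimated from the within-bin radial spread. For the trunk
  girths (r ≈ 30 cm) the effect is negligible; for the cannon
  (r ≈ 3 cm) it is several percent.

Relative errors against manual tape measurements are reported as
`|measured - manual| / manual * 100`, rounded half-up to two decimals,
matching how such comparisons are conventionally printed.

`measure_all()` runs all six measurements with a shared ground reference,
records per-parameter failures (for example an empty part after bad
segmentation) without aborting the rest, and serializes reports to JSON
with the full configuration embedded, so any report can be regenerated from
its own metadata.

# The synthetic cow

The generator builds a parametric cow with analytic ground truth:

- The trunk is a superellipsoid: cross-sections at x are ellipses with
  semi-axes `a_y*s(x)` and `a_z*s(x)`, where
  `s(u) = (1 - |u|^m)^(1/m)`, `u = x/a_x`, `m = 4`. The profile is nearly
  flat over the mid-body and rolls off at the ends, so measurement planes
  sit on well-defined girths while the body ends read as high-curvature,
  low-density regions — the property the body-length extraction relies on.
- Legs are vertical cylinders with a cannon-like radius profile: constant
  `r_min` over the lower 60%, then a linear flare to `r_top` at the trunk.
  This mirrors the anatomy (the cannon bone has nearly constant girth) and
  gives CC the well-defined truth `2*pi*r_min`.
- Ground truth: `WH = h_c + a_z*s(chest)`, `HH = h_c + a_z*s(hip)`,
  `BL = 2*a_x` (the end-to-end chord under bending), TC/AC are Ramanujan
  ellipse perimeters at the chest/belly planes, `CC = 2*pi*r_min`. The
  Ramanujan approximation is exact to far below measurement tolerance at
  these eccentricities, and generator truth and test oracles use the same
  form.
- Sampling is approximately uniform per unit surface area (rings weighted
  by circumference and slant), with the trunk at least 3× denser than the
  limbs, emulating multi-view depth-camera coverage. Defaults: 24,000 trunk
  points, 400 per leg, i.e. roughly 0.8 and 0.2 points/cm².
- Degradations: isotropic Gaussian sensor noise (`noise_sd`, cm); a bent
  posture implemented as a constant-curvature yaw of the body axis (the
  C-shape a cow adopts when turning, total angle `bend_angle`), with the
  chord kept as BL truth; and one-sided fence occlusion that removes a
  stated fraction of trunk points beyond a lateral chord, legs untouched.
- Herds draw dimensions uniformly from ranges typical of adult dairy
  cattle (body length 140–180 cm, trunk width/depth 54–66 cm, ground
  clearance 62–72 cm, cannon radius 2.8–3.6 cm), reproducibly from one
  seed.

What the generator does *not* emulate: head, tail and udder geometry (the
real pipeline excludes head and tail before measurement), registration
artefacts between camera views, non-Gaussian depth noise, coat or
environment returns, and breed-specific shape priors. Passing the recovery
suite therefore shows that the geometry of the pipeline is correct under
controlled degradations, not that field accuracy on real herds is
guaranteed.

# Verification conditions and tolerances

The test suite checks recovery on herds of 20 synthetic cows: noise-free,
every parameter of every cow must come back within 3% of analytic truth;
at 1 cm sensor noise, the herd-mean relative error per parameter must stay
within 5%. The herd-mean reading for the noisy condition reflects what the
noise makes identifiable: at 1 cm noise on a ~3 cm cannon radius the
per-animal information bound alone puts individual CC estimates at a few
percent spread, so individual animals can exceed the bound while the
estimator remains unbiased; means over a herd are the quantity the
tolerance can meaningfully constrain. Occlusion repair is checked by
re-measuring AC on the same cow with 40% of one flank removed (within 3% of
the un-occluded value). The toy segmentation experiment trains on twenty
1,024-point cows (0.5 cm noise) for up to 50 epochs and evaluates four
held-out cows. DUOS invariants (leaf capacity, partition, quota sums,
density guarantees) are exercised on 200 random clouds of up to ~600
points against brute-force oracles. These sizes keep the full suite to a
few minutes on one core while leaving each check statistically meaningful.

# Known limitations

- The alpha-shape boundary test is O(pairs × neighbours); it is meant for
  slice-sized inputs (hundreds of points), not whole clouds.
- The occlusion repair assumes lateral symmetry of the cross-section and a
  single contiguous gap; bilateral occlusion or dorsal gaps would need a
  different completion.
- The cannon estimator assumes the below-knee region is approximately a
  (possibly tapered) cylinder; a strongly non-circular cannon would bias
  CC low or high by the ellipse-vs-circle perimeter difference.
- The toy network shares no weights across scales and uses single-scale
  grouping; multi-scale grouping variants and GPU-scale training are out
  of scope.
- `measure_all()` trusts its input labels; segmentation errors at part
  boundaries propagate to keypoint placement, which is mitigated but not
  eliminated by the part-anchored constructions.
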