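---
title: "Methods: robust affine mosaicking of fetoscopic video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust affine mosaicking of fetoscopic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In laser therapy for twin-to-twin transfusion syndrome the surgeon inspects
the placental vascular anastomoses through a fetoscope whose field of view
covers only a small circular patch of the placenta. Mosaicking — registering
consecutive video frames into one coordinate frame and compositing them —
builds an expanded view of the placental surface. Fetoscopic video is a
hostile registration target: visibility is poor, vessels may be thin or
absent, amniotic-fluid debris ("floating particles") drifts across the
scene, and specular highlights ride with the light source rather than with
the tissue. Both artifact classes produce apparent motion inconsistent with
the camera motion and must be excluded from any motion estimate.

## Motion model and estimation pipeline

Camera-induced image motion between consecutive frames is modelled by a
6-parameter affine transform

$$
\begin{bmatrix} x' \\ y' \end{bmatrix} =
\begin{bmatrix} a_{11} & a_{12} & b_1 \\ a_{21} & a_{22} & b_2 \end{bmatrix}
\begin{bmatrix} x \\ y \\ 1 \end{bmatrix},
$$

deliberately not a projective (8-dof) model: when hundreds of pairwise
transforms are chained, affine estimates are more stable and less prone to
runaway shrinking or enlargement of the mosaic.

Per frame pair the pipeline is:

1. **Dense flow.** A per-pixel displacement field from frame $i$ to frame
   $i+1$, either computed by the built-in pyramidal Lucas–Kanade
   implementation (`lk_pyramidal()`) or imported from disk (`load_flow()`)
   when an external (e.g. deep-network) flow engine is preferred. The
   package deliberately contains no network: flow import is an interface,
   not an implementation.
2. **Correspondences.** Every valid flow pixel $(x, y)$ inside the circular
   fetoscope mask contributes the pair $(x, y) \to (x+u, y+v)$
   (`flow_to_correspondences()`). Masked-out pixels are excluded entirely
   rather than mapped to a sentinel value — a sentinel coordinate would be
   a gross outlier, not a removal. Destination points may leave the field
   of view; only the source side is constrained, and the robust estimator
   absorbs the consequences.
3. **Robust estimation.** Three-point minimal samples (the minimal set for
   6 dof) generate candidate affines inside RANSAC; a pair is an inlier
   when its re-projection error satisfies $\lVert P_D - P_R \rVert_2 \le
   6$ px (boundary inclusive). The iteration count adapts as
   $\log(1-0.99)/\log(1-w^3)$ with $w$ the best inlier ratio so far,
   capped at 2000. Degenerate samples are rejected by a triangle-area test
   before solving.
4. **Refinement.** Levenberg–Marquardt minimisation of the summed squared
   inlier re-projection error
   $E=\sum_i (x_i - a_{11}x_i' - a_{12}y_i' - b_1)^2 +
   (y_i - a_{21}x_i' - a_{22}y_i' - b_2)^2$.
   The model is linear in its parameters, so the LM minimiser coincides
   with the closed-form least-squares solution — the test suite asserts
   exactly that equivalence, which makes the optimizer itself testable.
5. **Chaining and blending.** Pairwise transforms are composed outward from
   a reference frame (default: the middle of the sequence, so accumulated
   drift spreads both ways) by left-hand matrix multiplication; all frames
   are inverse-warped onto a common canvas with bilinear interpolation and
   blended.

An alternative robust-regression path (`robust_regression_affine()`)
replaces steps 3–4 by direct minimisation of a soft-L1 cost
$f^2 \sum_i 2(\sqrt{1 + (r_i/f)^2} - 1)$ via iteratively reweighted least
squares, initialised from the plain least-squares fit. Its scale $f$
defaults to the RANSAC threshold (6 px) so the two robust schemes share an
influence scale.

### Transform direction

The package fixes one direction and names it everywhere: a pairwise
transform maps frame $i{+}1$ coordinates **into** frame $i$ coordinates.
This is the direction implied by the residuals in $E$ above (primed
coordinates predicted onto unprimed), and it makes chaining toward an
earlier reference a plain left multiplication; the opposite direction is
`affine_invert()`. The transform JSON schema carries a mandatory
`convention` string so serialized transforms cannot be silently
misinterpreted.

## The built-in Lucas–Kanade backbone

`lk_pyramidal()` is the classic coarse-to-fine scheme: factor-2 Gaussian
pyramids (3 levels by default), and at each level 8 warp-and-refine
iterations of the windowed normal equations over a Gaussian-weighted
21-pixel window. Three numerical choices matter in practice:

* **Pre-smoothing (`presmooth_sigma = 0.8`).** Both frames are smoothed
  before differentiation at every level, including the finest. The
  brightness-constancy linearisation assumes a band-limited signal; on
  noisy video the unsmoothed estimate carries a texture-correlated bias
  that survives averaging over thousands of correspondences and shows up
  as a systematic affine error. A light Gaussian removes most of it.
* **Validity floor (`eig_floor = 1e-5`) with a texture-poor fallback.**
  Pixels whose window-averaged structure tensor has smallest eigenvalue
  below the floor (aperture problem: edges and flat regions) are marked
  invalid and never reach the correspondence stage. The floor is absolute
  as long as it leaves at least 5% of the field of view valid; on frames
  where usable texture collapses below that, the relatively best 30% of
  pixels are kept instead. The rescue set is deliberately broad: with few
  strong pixels the affine fit needs spatial spread more than per-pixel
  quality, because its corner error is dominated by the lever arm of the
  support. The statistics are computed inside the field-of-view mask (the
  `roi` argument), since the bright rim of the fetoscopic circle would
  otherwise hide a collapse of scene texture.
* **Warping by Catmull-Rom bicubic interpolation.** Bilinear warping
  attenuates high frequencies by an amount that depends on the fractional
  part of each sample position; in an iterative warp-and-compare loop that
  attenuation acts as a spatially periodic blur field and biases the
  estimate. The cubic kernel keeps it an order of magnitude smaller; the
  same sampler is used when warping frames onto the mosaic canvas.
* **Model-refinement passes (`passes = 3` for the built-in backend).**
  After each affine estimate, the target frame is warped by it, residual
  flow is re-estimated on the warped pair (a shallow 2-level pyramid — the
  residual motion is small — on a slightly eroded mask to avoid the moving
  warp boundary) and the correction is composed in. This is standard
  model-based alignment. It also mitigates a subtle failure mode of
  texture-poor regions: pixels whose flow is stuck near zero have residual
  errors below the 6-px inlier bound whenever the camera step is small, so
  RANSAC cannot reject them — but in the residual passes "stuck at zero"
  becomes approximately correct, and their drag on the fit contracts
  geometrically with each pass. One pass is used verbatim for imported
  flow, whose accuracy the package cannot iterate on.

These defaults were set by measuring ground-truth transform recovery on
simulated sequences (see below); the window size follows common practice,
as no canonical value exists for fetoscopy.

## Drift evaluation

Ground-truth motion is unobtainable for in vivo fetoscopy, so registration
quality is quantified without it: for each frame $i$ and offset
$t \in \{1,\dots,N\}$ (default $N = 5$), the $t$ pairwise transforms are
composed, frame $i{+}t$ is warped into frame $i$'s coordinates, and the
structural similarity (SSIM) between the two is recorded. Chaining
accumulates error, so SSIM decays with $t$ at a rate that measures drift.
Distributions per $t$ are summarised as boxplots — median, Q1, Q3,
whiskers at the most extreme data within $Q1 - 1.5\,\mathrm{IQR}$ and
$Q3 + 1.5\,\mathrm{IQR}$ — because the low-side outliers, not the median,
are what flag outright registration failures. The $t=1$ slice plotted over
frame index (`ssim_timeplot()`) localises failures to specific pairs.

SSIM uses the standard parameterisation (Gaussian 11×11 window,
$\sigma=1.5$, $k_1=0.01$, $k_2=0.03$, dynamic range 1) on grayscale
(Rec. 601) intensities, averaged over windows fully inside the valid
region. Scoring is restricted to the intersection of the two frames'
warped fields of view (`use_overlap_mask`): including the black canvas
outside the fetoscopic circle would reward any registration with inflated
similarity. Quantiles are linear-interpolation (type 7); the choice moves
outlier counts only marginally.

## The simulator

`simulate_sequence()` generates placenta-like sequences with exact ground
truth, which is what makes every stage of the pipeline testable without
any external data:

* **Scene** — a reddish low-frequency random field crossed by dark smooth
  curvilinear vessels (random-walk-heading polylines with soft Gaussian
  cross-sections), additive Gaussian pixel noise (default σ = 0.02).
* **Camera** — per-step similarity increments (translation ≤ 5 px,
  rotation ≤ 2°, scale ≤ 1% by default) smoothed by an AR(1) process
  (coefficient 0.6), emulating hand-held drift rather than white jitter.
  The defaults are the motion regime used throughout validation.
* **Field of view** — circular mask (radius 0.45·min(h, w)) with quadratic
  vignetting, both anchored to the camera frame as in a real fetoscope.
* **Artifacts** — floating particles as soft bright blobs performing
  independent random walks (steps 15–30 px/frame, large relative to camera
  steps, as debris swirling in amniotic fluid moves on its own), and
  near-saturated specular blobs anchored to the camera frame, modelling
  light-source reflections. Particle count is derived from the configured
  areal density via the second moment of the diameter distribution, so the
  labelled fraction matches the configured density.
* **Ground truth** — pairwise transforms, analytic flow fields, and
  per-pixel artifact labels. The stored flow carries the *background*
  motion everywhere; `corrupted_flow()` switches artifact pixels to the
  artifact's own apparent motion (the particle's random-walk step; zero
  for camera-anchored speculars), producing the "flow oracle is
  corrupted" regime in which RANSAC must identify and reject exactly the
  labelled pixels.

What the simulator does **not** emulate — and hence what passing tests do
not establish about clinical video: photorealistic tissue appearance,
non-planar placental geometry (real motion is only approximately affine),
fluid turbidity, motion blur, rolling-shutter effects, and deep-flow
failure modes. The simulator validates the estimation machinery, not the
flow backbone's behaviour on real tissue.

## Validation conditions and problem sizes

The test suite and `scripts/acceptance.R` run: solver-vs-oracle agreement
on 1000 random correspondence sets (n = 3…500); RANSAC recovery over 200
seeded trials of 500 correspondences with 30% gross outliers (offsets
15–40 px, threshold 6 px); LM convergence from 100 perturbed starts; and
two 50-frame 320×320 simulated sequences — one with particle density 0.1
evaluated through corrupted ground-truth flow, one artifact-free evaluated
through the built-in LK backend with the SSIM drift metric on top. Small
unit fixtures use 160×160 frames. These sizes keep the full validation
desk-scale while leaving the motion regime at its defaults.

## Degenerate inputs and tie-breaks

* Collinear minimal samples (twice-area below 1e-8 px²) are rejected
  before solving; rank-deficient least-squares designs raise an error.
* A pair for which no model reaches 3 inliers raises a registration
  failure; sequence-level policy is configurable — `"stop"` truncates the
  mosaic at the break (the default, matching how a surgeon-facing tool
  should fail), `"identity_bridge"` inserts an identity transform,
  flags it in the diagnostics, and continues.
* RANSAC sampling happens in a canonical coordinate-sorted order with a
  per-pair seed derived from the master seed, so results are reproducible
  and invariant to the storage order of correspondences.
* `ssim()` raises an error when no window fits in the valid region rather
  than returning a value from partial windows.
* Singular transforms (|det| < 1e-12) cannot be inverted or used for
  warping; the error names the offending operation.

## Blending

Feathering (default) weights each warped frame by the distance transform
of its valid footprint and normalises; it is deterministic, cheap, and
sufficient for evaluation work. Multi-resolution spline blending
(`"multiband"`) decomposes each warped frame into a 4-level Laplacian
pyramid, blends level-wise with Gaussian-smoothed weights, and collapses —
low frequencies blend over wide transition zones, high frequencies over
narrow ones, hiding seams without ghosting. Before decomposition each
frame's out-of-footprint area is filled with the feathered composite so
pyramid smoothing never drags in background zeros. The blender is
self-contained; it makes no claim of matching any external tool's output
bit for bit.

## Known limitations

* Purely sequential chaining: drift accumulates without bound; no loop
  closure or global optimisation is attempted.
* The affine model cannot represent parallax or tissue deformation; it is
  the right trade-off for chaining stability, not a physical model.
* The LK backbone degrades on texture-poor regions and large
  displacements; imported dense flow is the intended production backbone,
  and LK is the self-contained baseline.
* SSIM drift is a relative metric: it compares methods on the same
  sequence but does not certify metric accuracy in millimetres.
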