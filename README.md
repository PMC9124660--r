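# fetomosaic

Video mosaicking for fetoscopy. During laser therapy for twin-to-twin
transfusion syndrome (TTTS) the surgeon sees the placenta through a
fetoscope whose circular field of view covers only a small patch of the
placental surface. `fetomosaic` registers consecutive video frames with a
robust affine motion model and composites them into a single
expanded-view mosaic, while rejecting the floating particles and specular
reflections whose apparent motion is inconsistent with the camera motion.

## Method

For each consecutive frame pair:

1. **Dense optical flow** — built-in pyramidal Lucas–Kanade
   (`lk_pyramidal()`), or externally computed flow imported with
   `load_flow()` (two-channel `.flo` binaries or float64 planes with a
   JSON sidecar).
2. **Correspondences** — every valid flow pixel `(x, y)` inside the
   circular fetoscope mask yields the pair `(x, y) → (x + u, y + v)`;
   pixels outside the mask are excluded (`flow_to_correspondences()`).
3. **Robust affine estimation** — 3-point minimal solver inside RANSAC
   with inlier rule ‖P_D − P_R‖₂ ≤ 6 px, followed by Levenberg–Marquardt
   refinement of the inlier re-projection error

       E = Σᵢ (xᵢ − a₁₁x′ᵢ − a₁₂y′ᵢ − b₁)² + (yᵢ − a₂₁x′ᵢ − a₂₂y′ᵢ − b₂)²

   (`ransac_affine()`, `refine_lm()`). A soft-L1 robust-regression
   alternative is available (`robust_regression_affine()`).
4. **Mosaicking** — pairwise transforms are chained to a reference frame
   by left-hand matrix multiplication (`chain_to_reference()`), frames are
   inverse-warped onto a common canvas and blended by feathering or
   multi-resolution Laplacian-pyramid splining (`render_mosaic()`).

Registration quality is quantified without ground truth by the SSIM drift
metric (`drift_metric()`): SSIM between frame *i* and the warped frame
*i + t* for t = 1…5, summarised as boxplots whose low-side outliers flag
registration failures.

A synthetic fetoscopy simulator (`simulate_sequence()`) generates
placenta-like sequences — vessel texture, smooth camera motion, circular
field of view, drifting particles, camera-anchored speculars — with
ground-truth transforms, flow and artifact labels, so the entire pipeline
is testable offline.

## Worked example

```r
library(fetomosaic)

# simulate a 20-frame sequence with floating particles
seq <- simulate_sequence(
  scene     = scene_config(seed = 7),
  motion    = motion_config(n_frames = 20, seed = 7),
  artifacts = artifact_config(particle_density = 0.1, seed = 7))

# register one pair from a dense flow field whose artifact pixels carry the
# particles' own motion: RANSAC puts them in the outlier list
reg <- register_pair(seq$frames[[1]], seq$frames[[2]],
                     flow = corrupted_flow(seq, 1), mask = seq$mask,
                     cfg = ransac_config(seed = 1))
reg
#> pairwise registration: 14744/16292 inliers, rmse 0.101 px
nrow(reg$outlier_points)
#> [1] 1548

# register the whole sequence and compare against the ground truth
rec <- recovery_experiment(seq, flow_source = "gt_corrupted",
                           cfg = ransac_config(seed = 1))
summary(rec$per_pair$corner_error)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0060  0.0168  0.0307  0.0349  0.0410  0.0989
rec$endpoint_drift
#> [1] 0.306

# chain, blend, and evaluate drift
traj <- chain_to_reference(rec$registrations)
mosaic <- render_mosaic(seq$frames, traj, seq$mask)
mosaic
#> mosaic canvas 324 x 326, 69.9% covered
report <- drift_metric(seq$frames,
                       lapply(rec$registrations, `[[`, "transform"),
                       N = 5, mask = seq$mask)
report
#> SSIM drift report, N = 5
#>   t = 1: median SSIM 0.6163 (0 outliers)
#>   t = 2: median SSIM 0.6277 (0 outliers)
#>   t = 3: median SSIM 0.6179 (0 outliers)
#>   t = 4: median SSIM 0.6144 (0 outliers)
#>   t = 5: median SSIM 0.6127 (3 outliers)
```

`reg$outlier_points` holds the frame coordinates of the rejected pixels —
overlaying them on the source frame shows them clustering on the injected
particles (95.7% of artifact pixels are flagged across this sequence).
`corner_error` is the largest displacement of a frame corner between the
estimated and true transform: maxima below 0.1 px mean the chain stays
locked to the true trajectory, and the composed 20-frame chain ends only
0.3 px off. The SSIM medians sit near 0.62 at every offset — at this
(deliberately heavy) debris density the metric is capped by particles
moving between frames, not by registration drift, which is exactly the
appearance-versus-motion distinction the robust estimator exploits.

The same pipeline runs from the shell via the bundled script:

```sh
Rscript inst/cli/fetomosaic.R simulate --output sim --n-frames 30 --seed 7
Rscript inst/cli/fetomosaic.R mosaic   --input sim --output out --seed 7
Rscript inst/cli/fetomosaic.R evaluate --input sim --output out --seed 7
```

writing `mosaic.png`, `transforms.json` (with an explicit transform
direction convention), `diagnostics.csv`, `drift.csv` and plots.

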