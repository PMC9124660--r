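test_that("chaining matches the cumulative homogeneous-matrix product", {
  # all-identity chain
  pw <- replicate(4, affine_identity(), simplify = FALSE)
  traj <- chain_to_reference(pw, reference_index = 1)
  for (A in traj$absolute) {
    expect_equal(unclass(A), unclass(affine_identity()))
  }
  # pairwise translations accumulate: pairwise maps k+1 -> k, so frame 3
  # sits at 2t in frame-1 coordinates
  t1 <- affine_translation(3, -1)
  traj <- chain_to_reference(list(t1, t1), reference_index = 1)
  expect_equal(unclass(traj$absolute[[3]]),
               unclass(affine_translation(6, -2)))
  # 20 random transforms vs brute-force product, reference at the start
  with_seed(41, {
    pw <- replicate(20, random_affine(max_angle = 3, max_t = 5),
                    simplify = FALSE)
    traj <- chain_to_reference(pw, reference_index = 1)
    acc <- unclass(affine_identity())
    for (k in 1:20) {
      acc <- oracle_compose(as_affine(acc), pw[[k]])
      expect_equal(unclass(traj$absolute[[k + 1]]), acc, tolerance = 1e-9)
    }
  })
})

test_that("changing the reference frame is a gauge transformation", {
  with_seed(42, {
    pw <- replicate(7, random_affine(max_angle = 3, max_t = 5),
                    simplify = FALSE)
    t1 <- chain_to_reference(pw, reference_index = 4)
    r2 <- 7
    t2 <- chain_to_reference(pw, reference_index = r2)
    G <- affine_invert(t1$absolute[[r2]])
    for (f in 1:8) {
      expect_equal(unclass(t2$absolute[[f]]),
                   unclass(affine_compose(G, t1$absolute[[f]])),
                   tolerance = 1e-6)
    }
  })
})

test_that("a broken chain reports the failing pair index", {
  pw <- list(affine_identity(), NULL, affine_identity())
  expect_error(chain_to_reference(pw, reference_index = 1), "pair 2")
})

test_that("canvas bounds cover every transformed mask corner", {
  # single identity frame: bounds are frame size plus margin
  traj <- chain_to_reference(list(), reference_index = 1)
  cv <- compute_canvas(traj, c(100, 120), margin = 2)
  expect_equal(cv$width, 120L + 4L)
  expect_equal(cv$height, 100L + 4L)
  # two frames offset by (100, 0): width grows by 100
  traj2 <- chain_to_reference(list(affine_translation(100, 0)),
                              reference_index = 1)
  cv2 <- compute_canvas(traj2, c(100, 120), margin = 2)
  expect_equal(cv2$width, 120L + 100L + 4L)
  expect_equal(cv2$height, 100L + 4L)
  # random trajectory: every transformed corner inside the bounds
  with_seed(43, {
    pw <- replicate(10, random_affine(max_angle = 5, max_t = 15),
                    simplify = FALSE)
    traj3 <- chain_to_reference(pw)
    cv3 <- compute_canvas(traj3, c(100, 120))
    corners <- cbind(c(0, 119, 0, 119), c(0, 0, 99, 99))
    for (A in traj3$absolute) {
      p <- affine_apply(A, corners)
      expect_true(all(p[, 1] >= cv3$xmin & p[, 1] <= cv3$xmin + cv3$width - 1))
      expect_true(all(p[, 2] >= cv3$ymin & p[, 2] <= cv3$ymin + cv3$height - 1))
    }
  })
})

test_that("warping is exact for identity and integer translations", {
  seq <- tiny_clean_seq()
  f <- as_gray(seq$frames[[2]])
  m <- seq$mask
  traj <- chain_to_reference(list(), reference_index = 1)
  cv <- compute_canvas(traj, dim(f), m, margin = 2)
  wp <- warp_frame(f, affine_identity(), m, cv)
  # inside the mask footprint the frame is reproduced exactly
  g <- fetomosaic:::pixel_grid(cv$height, cv$width)
  fx <- g$x + cv$xmin; fy <- g$y + cv$ymin
  inside <- wp$valid
  expect_gt(sum(inside), 1000)
  orig <- f[cbind(fy[inside] + 1, fx[inside] + 1)]
  expect_lt(max(abs(wp$image[inside] - orig)), 1e-12)

  # integer translation: pixel-exact shifted copy
  A <- affine_translation(7, -3)
  traj2 <- chain_to_reference(list(), reference_index = 1)
  cv2 <- list(height = 200, width = 200,
              origin_offset = affine_translation(0, 0))
  wp2 <- warp_frame(f, A, m, cv2)
  sel <- which(wp2$valid, arr.ind = TRUE)
  src_r <- sel[, 1] - (-3); src_c <- sel[, 2] - 7
  ok <- src_r >= 1 & src_r <= 160 & src_c >= 1 & src_c <= 160
  expect_lt(max(abs(wp2$image[sel[ok, , drop = FALSE]] -
                      f[cbind(src_r[ok], src_c[ok])])), 1e-12)
})

test_that("warp then inverse warp returns a smooth image within bounds", {
  seq <- tiny_clean_seq()
  f <- fetomosaic:::gauss_smooth(as_gray(seq$frames[[3]]), 2)
  A <- affine_similarity(4, 1.02, 2.5, -1.5, center = c(80, 80))
  cv <- list(height = 160, width = 160,
             origin_offset = affine_translation(0, 0))
  fwd <- warp_frame(f, A, NULL, cv)
  back <- warp_frame(fwd$image, affine_invert(A), NULL, cv)
  both <- back$valid & warp_frame(matrix(1, 160, 160), affine_identity(),
                                  NULL, cv)$valid
  # erode the doubly-valid region to dodge boundary interpolation effects
  er <- fetomosaic:::box_sum(both + 0, 5) >= 24.5
  expect_gt(sum(er), 5000)
  expect_lt(max(abs(back$image[er] - f[er])), 0.02)
})

test_that("blending conserves constants and stays within intensity bounds", {
  m <- circular_mask(40, 40, 30, c(80, 80))
  mk <- function(val, dx) {
    img <- matrix(val, 80, 120)
    valid <- matrix(FALSE, 80, 120)
    valid[, dx + 1:80][m$raster] <- TRUE
    img[!valid] <- 0
    list(image = img, valid = valid)
  }
  # one frame: mosaic equals the frame inside its footprint
  one <- blend(list(mk(0.37, 0)), mode = "feather")
  expect_equal(one$image[one$covered],
               mk(0.37, 0)$image[one$covered], tolerance = 1e-12)
  # two identical constants: overlap stays that constant (both modes)
  for (mode in c("feather", "multiband")) {
    two <- blend(list(mk(0.37, 0), mk(0.37, 30)), mode = mode)
    expect_lt(max(abs(two$image[two$covered] - 0.37)), 1e-9)
  }
  # differing constants: feathered overlap lies between them
  mix <- blend(list(mk(0.2, 0), mk(0.8, 30)), mode = "feather")
  overlap <- mk(0.2, 0)$valid & mk(0.8, 30)$valid
  expect_true(all(mix$image[overlap] >= 0.2 - 1e-9 &
                    mix$image[overlap] <= 0.8 + 1e-9))
})

test_that("incremental previews end at the full mosaic", {
  seq <- tiny_clean_seq()
  traj <- chain_to_reference(seq$gt_pairwise)
  # k larger than the sequence: single final mosaic
  pv <- incremental_preview(seq$frames, traj, every_k = 100, mask = seq$mask)
  expect_length(pv, 1)
  # k = 1: one preview per frame, last equals the full blend
  pv1 <- incremental_preview(seq$frames, traj, every_k = 1, mask = seq$mask)
  expect_length(pv1, length(seq$frames))
  full <- render_mosaic(seq$frames, traj, seq$mask)
  expect_equal(pv1[[length(pv1)]]$image, full$image, tolerance = 1e-12)
})

test_that("a ground-truth mosaic reproduces the underlying texture", {
  # vignette-free render so the texture comparison is photometrically clean
  sc <- scene_config(texture_size = 400, illumination_falloff_strength = 0,
                     seed = 103)
  tex <- make_texture(sc)
  traj_steps <- sample_trajectory(motion_config(n_frames = 6, seed = 103),
                                  c(160, 160), 400)
  seq <- render_sequence(tex, traj_steps, sc, NULL, c(160, 160))
  traj <- chain_to_reference(seq$gt_pairwise)
  mos <- render_mosaic(seq$frames, traj, seq$mask)
  # texture crop in mosaic-canvas coordinates: canvas -> reference frame
  # -> texture via the reference camera pose
  poses <- attr(traj_steps, "poses")
  ref_pose <- poses[[traj$reference_index]]
  to_tex <- affine_compose(ref_pose, mos$canvas$origin_offset)
  g <- fetomosaic:::pixel_grid(mos$canvas$height, mos$canvas$width)
  tp <- affine_apply(to_tex, cbind(as.numeric(g$x), as.numeric(g$y)))
  crop <- matrix(fetomosaic:::bilinear_sample(as_gray(tex), tp[, 1], tp[, 2],
                                              outside = 0),
                 mos$canvas$height, mos$canvas$width)
  s <- ssim(as_gray(mos$image), crop, valid = mos$covered)
  expect_gte(s, 0.95)
})
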