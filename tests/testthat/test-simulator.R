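test_that("texture generation is deterministic and respects vessel count", {
  sc <- scene_config(texture_size = 160, seed = 61)
  t1 <- make_texture(sc)
  t2 <- make_texture(sc)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 1))
  # red channel dominates: placenta-like coloring
  expect_gt(mean(t1[, , 1]), mean(t1[, , 2]))
  # without vessels there is no dark tail beyond what noise explains
  sc0 <- scene_config(texture_size = 160, vessel_count = 0, seed = 61)
  t0 <- make_texture(sc0)
  g_with <- as_gray(t1); g_without <- as_gray(t0)
  expect_lt(quantile(g_with, 0.005), quantile(g_without, 0.005) - 0.05)
  expect_gt(quantile(g_without, 0.005),
            mean(g_without) - 4 * sd(g_without))
})

test_that("trajectories honour caps, determinism and pure-rotation structure", {
  mc <- motion_config(n_frames = 10, max_translation_step = 0,
                      max_rotation_step = 0, max_scale_step = 0, seed = 62)
  steps <- sample_trajectory(mc, c(100, 100), 400)
  for (s in steps) expect_equal(unclass(s), unclass(affine_identity()))
  # rotation-only: each linear part is orthogonal with unit determinant
  mr <- motion_config(n_frames = 10, max_translation_step = 0,
                      max_rotation_step = 3, max_scale_step = 0, seed = 63)
  steps_r <- sample_trajectory(mr, c(100, 100), 400)
  for (s in steps_r) {
    L <- unclass(s)[, 1:2]
    expect_lt(max(abs(t(L) %*% L - diag(2))), 1e-9)
    expect_lt(abs(det(L) - 1), 1e-9)
  }
  # same seed, same trajectory
  expect_identical(lapply(sample_trajectory(mr, c(100, 100), 400), unclass),
                   lapply(steps_r, unclass))
  # excursions beyond the texture raise a config error
  big <- motion_config(n_frames = 60, max_translation_step = 20,
                       smoothness = 0.9, seed = 64)
  expect_error(sample_trajectory(big, c(300, 300), 320), "excursion")
})

test_that("rendering is deterministic and static cameras give static frames", {
  sc <- scene_config(texture_size = 300, seed = 65)
  mc <- motion_config(n_frames = 4, max_translation_step = 0,
                      max_rotation_step = 0, max_scale_step = 0, seed = 65)
  s1 <- simulate_sequence(sc, mc, frame_size = c(120, 120))
  s2 <- simulate_sequence(sc, mc, frame_size = c(120, 120))
  expect_identical(s1$frames, s2$frames)
  for (k in 2:4) expect_identical(s1$frames[[k]], s1$frames[[1]])
})

test_that("translation-only motion yields uniform ground-truth flow", {
  sc <- scene_config(texture_size = 300, seed = 66)
  mc <- motion_config(n_frames = 3, max_translation_step = 4,
                      max_rotation_step = 0, max_scale_step = 0, seed = 66)
  seq <- simulate_sequence(sc, mc, frame_size = c(120, 120))
  for (k in 1:2) {
    A <- seq$gt_pairwise[[k]]
    expect_equal(unclass(A)[, 1:2], diag(2), tolerance = 1e-12)
    fl <- seq$gt_flow[[k]]
    # flow from frame k to k+1 is the inverse step translation, constant
    expect_lt(diff(range(fl$u)), 1e-9)
    expect_lt(diff(range(fl$v)), 1e-9)
    expect_equal(fl$u[1, 1], -unclass(A)[1, 3], tolerance = 1e-9)
    expect_equal(fl$v[1, 1], -unclass(A)[2, 3], tolerance = 1e-9)
  }
})

test_that("ground-truth flow and transforms are mutually consistent", {
  seq <- tiny_clean_seq()
  h <- seq$frame_size[1]; w <- seq$frame_size[2]
  g <- fetomosaic:::pixel_grid(h, w)
  for (k in c(1, 3)) {
    q <- affine_apply(affine_invert(seq$gt_pairwise[[k]]),
                      cbind(as.numeric(g$x), as.numeric(g$y)))
    expect_lt(max(abs(matrix(q[, 1], h, w) - g$x - seq$gt_flow[[k]]$u)), 1e-6)
    expect_lt(max(abs(matrix(q[, 2], h, w) - g$y - seq$gt_flow[[k]]$v)), 1e-6)
  }
})

test_that("particle labels cover roughly the configured density", {
  # speculars off so the labelled fraction isolates the particle contract
  sc <- scene_config(texture_size = 400, seed = 67)
  mc <- motion_config(n_frames = 3, seed = 67)
  s <- simulate_sequence(sc, mc,
                         artifact_config(particle_density = 0.1,
                                         specular_count = 0, seed = 67),
                         frame_size = c(160, 160))
  frac <- mean(vapply(s$artifact_labels,
                      function(l) mean(l[s$mask$raster]), numeric(1)))
  expect_gt(frac, 0.08)
  expect_lt(frac, 0.12)
  # density sweep is monotone
  fr <- vapply(c(0.02, 0.1, 0.25), function(d) {
    s <- simulate_sequence(sc, mc,
                           artifact_config(particle_density = d, seed = 67),
                           frame_size = c(160, 160))
    mean(s$artifact_labels[[1]][s$mask$raster])
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("corrupted flow deviates from truth only at artifact pixels", {
  seq <- tiny_artifact_seq()
  k <- 1
  cf <- corrupted_flow(seq, k)
  gt <- seq$gt_flow[[k]]
  lab <- seq$artifact_labels[[k]]
  d <- sqrt((cf$u - gt$u)^2 + (cf$v - gt$v)^2)
  expect_identical(d[!lab & seq$mask$raster],
                   rep(0, sum(!lab & seq$mask$raster)))
  expect_gt(median(d[lab]), 6)
})

test_that("recovery from clean ground-truth flow is near exact", {
  seq <- tiny_clean_seq()
  rec <- recovery_experiment(seq, "gt", cfg = ransac_config(seed = 68))
  expect_lt(max(rec$per_pair$corner_error), 1e-3)
  expect_lt(rec$endpoint_drift, 1e-2)
})
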