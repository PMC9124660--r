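# Independent oracles and shared fixtures for the test suite.
# Oracles deliberately avoid the package's own code paths: homogeneous 3x3
# matrix products for the affine algebra, explicit normal equations for the
# least-squares fits.

# --- oracles ---------------------------------------------------------------

oracle_h3 <- function(A) rbind(unclass(A), c(0, 0, 1))

oracle_apply <- function(A, pts) {
  out <- cbind(pts, 1) %*% t(oracle_h3(A))
  out[, 1:2, drop = FALSE]
}

oracle_compose <- function(A, B) {
  M <- oracle_h3(A) %*% oracle_h3(B)
  M[1:2, , drop = FALSE]
}

# Normal-equations affine fit: two decoupled 3-parameter problems.
oracle_affine_normal_eq <- function(src, dst) {
  X <- cbind(src, 1)
  G <- t(X) %*% X
  cx <- solve(G, t(X) %*% dst[, 1])
  cy <- solve(G, t(X) %*% dst[, 2])
  affine(cx[1], cx[2], cy[1], cy[2], cx[3], cy[3])
}

# A moderately conditioned random affine drawn from the current RNG.
random_affine <- function(max_angle = 10, scale_range = c(0.9, 1.1),
                          max_shear = 0.05, max_t = 20,
                          center = c(200, 200)) {
  A <- affine_similarity(angle = runif(1, -max_angle, max_angle),
                         scale = runif(1, scale_range[1], scale_range[2]),
                         tx = runif(1, -max_t, max_t),
                         ty = runif(1, -max_t, max_t),
                         center = center)
  shear <- affine(1, runif(1, -max_shear, max_shear),
                  runif(1, -max_shear, max_shear), 1, 0, 0)
  affine_compose(A, shear)
}

max_corner_error <- function(A, B, w = 400, h = 400) {
  corners <- cbind(c(0, w - 1, 0, w - 1), c(0, 0, h - 1, h - 1))
  max(sqrt(rowSums((affine_apply(A, corners) - affine_apply(B, corners))^2)))
}

# --- shared fixtures (memoized across test files) --------------------------

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small clean synthetic sequence shared by mosaic/evaluation/flow tests.
tiny_clean_seq <- function() {
  fixture("tiny_clean", function() {
    simulate_sequence(scene_config(texture_size = 400, seed = 101),
                      motion_config(n_frames = 6, seed = 101),
                      artifacts = NULL, frame_size = c(160, 160))
  })
}

# Small artifact-bearing sequence for outlier tests.
tiny_artifact_seq <- function() {
  fixture("tiny_artifact", function() {
    simulate_sequence(scene_config(texture_size = 400, seed = 102),
                      motion_config(n_frames = 6, seed = 102),
                      artifacts = artifact_config(seed = 102),
                      frame_size = c(160, 160))
  })
}
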