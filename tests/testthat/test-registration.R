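make_pairs <- function(A, n, xy_range = c(0, 400)) {
  src <- matrix(runif(2 * n, xy_range[1], xy_range[2]), ncol = 2)
  correspondence_set(src, affine_apply(A, src))
}

test_that("minimal 3-point solver interpolates and rejects collinearity", {
  ident3 <- correspondence_set(cbind(c(0, 1, 0), c(0, 0, 1)),
                               cbind(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(unclass(solve_affine_minimal(ident3)),
               unclass(affine_identity()))
  with_seed(31, {
    for (rep in 1:10) {
      A <- random_affine()
      cs <- make_pairs(A, 3)
      Ah <- solve_affine_minimal(cs)
      expect_lt(max(abs(unclass(Ah) - unclass(A))), 1e-9)
      expect_lt(max(reprojection_errors(Ah, cs)), 1e-9)
    }
  })
  col <- correspondence_set(cbind(c(0, 1, 2), c(0, 1, 2)),
                            cbind(c(0, 1, 2), c(0, 1, 2)))
  expect_error(solve_affine_minimal(col), "degenerate")
})

test_that("least-squares fit recovers exact data and is optimal under noise", {
  with_seed(32, {
    A <- random_affine()
    cs <- make_pairs(A, 50)
    expect_lt(max(abs(unclass(solve_affine_lsq(cs)) - unclass(A))), 1e-9)
    # n = 3 reduces to the minimal solver
    tri <- make_pairs(A, 3)
    expect_equal(unclass(solve_affine_lsq(tri)),
                 unclass(solve_affine_minimal(tri)), tolerance = 1e-9)
    # with noise, the fit beats the generator at its own objective
    noisy <- correspondence_set(cs$src,
                                cs$dst + matrix(rnorm(100, 0, 1), ncol = 2))
    Ah <- solve_affine_lsq(noisy)
    expect_lte(fetomosaic:::reprojection_cost(Ah, noisy),
               fetomosaic:::reprojection_cost(A, noisy))
  })
})

test_that("RANSAC keeps consistent sets intact and excludes gross outliers", {
  with_seed(33, {
    A <- random_affine()
    cs <- make_pairs(A, 200)
    reg <- ransac_affine(cs, ransac_config(seed = 5))
    expect_true(all(reg$inlier_mask))
    expect_lt(max(abs(unclass(reg$transform) - unclass(solve_affine_lsq(cs)))),
              1e-6)
    # 30% outliers displaced by 15-40 px
    n <- 500
    cs <- make_pairs(A, n)
    out_idx <- sample(n, 150)
    ang <- runif(150, 0, 2 * pi); mag <- runif(150, 15, 40)
    dst <- cs$dst
    dst[out_idx, ] <- dst[out_idx, ] + cbind(mag * cos(ang), mag * sin(ang))
    cs2 <- correspondence_set(cs$src, dst)
    reg2 <- ransac_affine(cs2, ransac_config(seed = 6))
    expect_gte(mean(!reg2$inlier_mask[out_idx]), 0.95)
    expect_lt(max_corner_error(reg2$transform, A), 0.1)
  })
})

test_that("a residual exactly at the threshold counts as an inlier", {
  # the inlier rule itself: <= 6, so exactly 6.0 is kept, just beyond is not
  with_seed(34, {
    src <- matrix(runif(200, 0, 400), ncol = 2)
    dst <- src
    dst[1, ] <- src[1, ] + c(6, 0)      # residual exactly 6.0
    dst[2, ] <- src[2, ] + c(6.001, 0)  # just beyond
    cs <- correspondence_set(src, dst)
    keep <- inlier_rule(affine_identity(), cs, 6)
    expect_true(keep[1])
    expect_false(keep[2])
    expect_true(all(keep[-(1:2)]))
    # end to end, a clearly-inside and clearly-outside pair separate cleanly
    dst[1, ] <- src[1, ] + c(5.9, 0)
    dst[2, ] <- src[2, ] + c(8, 0)
    reg <- ransac_affine(correspondence_set(src, dst),
                         ransac_config(threshold = 6, seed = 2))
    expect_true(reg$inlier_mask[1])
    expect_false(reg$inlier_mask[2])
  })
})

test_that("RANSAC inlier sets are invariant to input permutation", {
  with_seed(35, {
    A <- random_affine()
    cs <- make_pairs(A, 300)
    dst <- cs$dst
    idx <- sample(300, 90)
    dst[idx, ] <- dst[idx, ] + matrix(runif(180, 15, 40), ncol = 2)
    cs <- correspondence_set(cs$src, dst)
    reg <- ransac_affine(cs, ransac_config(seed = 9))
    perm <- sample(300)
    csp <- correspondence_set(cs$src[perm, ], cs$dst[perm, ])
    regp <- ransac_affine(csp, ransac_config(seed = 9))
    expect_identical(regp$inlier_mask, reg$inlier_mask[perm])
    expect_equal(unclass(regp$transform), unclass(reg$transform),
                 tolerance = 1e-12)
  })
})

test_that("LM refinement reaches the closed-form minimizer monotonically", {
  with_seed(36, {
    A <- random_affine()
    cs <- make_pairs(A, 80)
    noisy <- correspondence_set(cs$src,
                                cs$dst + matrix(rnorm(160, 0, 0.5), ncol = 2))
    A_star <- solve_affine_lsq(noisy)
    # already-optimal start stays put
    A_same <- refine_lm(A_star, noisy)
    expect_lt(max(abs(affine_to_vec(A_same) - affine_to_vec(A_star))), 1e-8)
    # perturbed starts converge to the closed form with non-increasing cost
    for (rep in 1:10) {
      A0 <- affine_from_vec(affine_to_vec(A_star) + runif(6, -0.1, 0.1))
      Ar <- refine_lm(A0, noisy)
      expect_lt(max(abs(affine_to_vec(Ar) - affine_to_vec(A_star))), 1e-6)
      expect_true(all(diff(attr(Ar, "cost_trace")) <= 0))
    }
  })
})

test_that("soft-L1 regression matches lsq when clean and beats it with outliers", {
  with_seed(37, {
    A <- random_affine()
    cs <- make_pairs(A, 200)
    rr <- robust_regression_affine(cs)
    expect_lt(max_corner_error(rr$transform, solve_affine_lsq(cs)), 1e-4)
    # large f_scale limit reduces to least squares even with outliers
    dst <- cs$dst
    idx <- sample(200, 40)
    dst[idx, ] <- dst[idx, ] + matrix(runif(80, 20, 40), ncol = 2)
    cs2 <- correspondence_set(cs$src, dst)
    lsq2 <- solve_affine_lsq(cs2)
    rr_inf <- robust_regression_affine(cs2, f_scale = 1e8)
    expect_lt(max_corner_error(rr_inf$transform, lsq2), 1e-4)
    # at the working scale the robust fit is strictly closer to truth
    rr2 <- robust_regression_affine(cs2, f_scale = 6)
    expect_lt(max_corner_error(rr2$transform, A),
              max_corner_error(lsq2, A))
  })
})

test_that("registering identical frames returns the identity", {
  seq <- tiny_clean_seq()
  f <- seq$frames[[1]]
  reg <- register_pair(f, f, mask = seq$mask, cfg = ransac_config(seed = 3))
  expect_lt(max_corner_error(reg$transform, affine_identity(), 160, 160), 0.05)
  expect_gte(reg$n_inliers / reg$n, 0.99)
})

test_that("pairs with injected particles flag the particle pixels as outliers", {
  seq <- tiny_artifact_seq()
  k <- 2
  reg <- register_pair(seq$frames[[k]], seq$frames[[k + 1]],
                       flow = corrupted_flow(seq, k), mask = seq$mask,
                       cfg = ransac_config(seed = 4))
  # particle pixels only: speculars ride with the camera, so with small
  # camera steps their apparent motion is not inconsistent enough to reject
  g <- fetomosaic:::pixel_grid(160, 160)
  plab <- matrix(FALSE, 160, 160)
  parts <- seq$particles[[k]]
  for (p in seq_len(nrow(parts))) {
    plab <- plab | ((g$x - parts[p, 1])^2 + (g$y - parts[p, 2])^2 <=
                      parts[p, 3]^2)
  }
  plab <- plab & seq$mask$raster
  idx <- cbind(reg$src_points[, 2] + 1, reg$src_points[, 1] + 1)
  is_art <- plab[idx]
  expect_gt(sum(is_art), 50)
  expect_gte(mean(!reg$inlier_mask[is_art]), 0.9)
  # ground truth still recovered accurately despite the corruption
  expect_lt(max_corner_error(reg$transform, seq$gt_pairwise[[k]], 160, 160),
            0.5)
})
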