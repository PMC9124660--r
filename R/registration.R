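# Robust pairwise affine estimation from point correspondences.
#
# The estimation pipeline is the gold-standard two-view scheme: a 3-point
# minimal solver generates candidate affines inside RANSAC; points whose
# re-projection error ||P_D - P_R||_2 exceeds the threshold (default 6 px,
# set by inspecting which pixels get removed — floating particles and
# specular highlights) are outliers; the winning model is refined by
# Levenberg-Marquardt on the inlier re-projection error
#   E = sum_i (x_i - a11 x'_i - a12 y'_i - b1)^2
#            + (y_i - a21 x'_i - a22 y'_i - b2)^2 .
# A robust-regression alternative (soft-L1 loss) is provided for
# comparison; it skips RANSAC and downweights outliers smoothly.

#' RANSAC configuration
#'
#' @param threshold inlier re-projection bound in pixels; a pair with
#'   residual exactly equal to the threshold counts as an inlier.
#' @param max_iterations cap on RANSAC iterations.
#' @param confidence target probability of sampling one all-inlier minimal
#'   triple; drives adaptive termination.
#' @param seed integer RNG seed for the sampling stream.
#' @return A list of class `ransac_config`.
#' @export
ransac_config <- function(threshold = 6, max_iterations = 2000L,
                          confidence = 0.99, seed = 1L) {
  stopifnot(threshold > 0, confidence > 0, confidence < 1,
            max_iterations >= 1)
  structure(list(threshold = threshold,
                 max_iterations = as.integer(max_iterations),
                 confidence = confidence, seed = as.integer(seed)),
            class = "ransac_config")
}

new_pairwise_registration <- function(transform, inlier_mask, residuals,
                                      extra = list()) {
  inl <- residuals[inlier_mask]
  out <- c(list(transform = transform,
                inlier_mask = inlier_mask,
                n = length(inlier_mask),
                n_inliers = sum(inlier_mask),
                rmse = if (any(inlier_mask)) sqrt(mean(inl^2)) else NA_real_,
                residuals = residuals),
           extra)
  structure(out, class = "pairwise_registration")
}

#' @export
print.pairwise_registration <- function(x, ...) {
  cat(sprintf("pairwise registration: %d/%d inliers, rmse %.3f px\n",
              x$n_inliers, x$n, x$rmse))
  invisible(x)
}

# Per-point re-projection error ||dst - A src||_2.
reprojection_errors <- function(A, c) {
  d <- c$dst - affine_apply(A, c$src)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Inlier rule for a fitted transform
#'
#' A pair is an inlier when its re-projection error does not exceed the
#' threshold; a residual exactly at the threshold still counts as an inlier.
#'
#' @param A an [affine()].
#' @param c a [correspondence_set()].
#' @param threshold inlier bound in pixels.
#' @return Logical vector aligned with the pairs.
#' @export
inlier_rule <- function(A, c, threshold) {
  reprojection_errors(A, c) <= threshold
}

# Sum of squared re-projection errors (the LM objective).
reprojection_cost <- function(A, c) {
  d <- c$dst - affine_apply(A, c$src)
  sum(d * d)
}

# Twice the signed triangle area of three source points.
triangle_area2 <- function(p) {
  (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
}

#' Minimal 3-point affine solver
#'
#' Solves exactly for the affine transform interpolating three point pairs
#' (the minimal sample for the 6-dof model).
#'
#' @param c a [correspondence_set()] with exactly 3 pairs.
#' @return An [affine()] with zero residual at the three pairs.
#' @export
solve_affine_minimal <- function(c) {
  stopifnot(c$n == 3)
  if (abs(triangle_area2(c$src)) < 2e-8) {
    stop("degenerate sample: collinear source points")
  }
  X <- cbind(c$src, 1)
  sol <- solve(X, c$dst)          # 3 x 2: columns (a11, a12, b1), (a21, a22, b2)
  affine(sol[1, 1], sol[2, 1], sol[1, 2], sol[2, 2], sol[3, 1], sol[3, 2])
}

#' Least-squares affine fit
#'
#' Minimizes the summed squared re-projection error over all pairs. The two
#' coordinate equations decouple into two independent 3-parameter linear
#' problems, solved by QR.
#'
#' @param c a [correspondence_set()] with n >= 3 non-degenerate pairs.
#' @param weights optional non-negative per-pair weights.
#' @return An [affine()].
#' @export
solve_affine_lsq <- function(c, weights = NULL) {
  stopifnot(c$n >= 3)
  X <- cbind(c$src, 1)
  Y <- c$dst
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    X <- X * sw
    Y <- Y * sw
  }
  qrx <- qr(X)
  if (qrx$rank < 3) stop("degenerate correspondence set: rank-deficient design")
  sol <- qr.coef(qrx, Y)
  affine(sol[1, 1], sol[2, 1], sol[1, 2], sol[2, 2], sol[3, 1], sol[3, 2])
}

#' Robust affine estimation by 3-point RANSAC
#'
#' Repeatedly fits the minimal solver to random non-collinear triples,
#' counts pairs with re-projection error `<= cfg$threshold` as inliers, and
#' keeps the model with the largest consensus. The iteration count adapts to
#' the best inlier ratio seen so far (`log(1 - confidence) / log(1 - w^3)`),
#' capped at `max_iterations`. The winner is re-fitted by least squares on
#' its consensus set and the inlier mask re-derived (twice, which is enough
#' for the linear model to stabilize).
#'
#' Sampling is performed in a canonical ordering of the pairs (lexicographic
#' on coordinates), so the returned inlier set is invariant to permutations
#' of the input list under the same seed.
#'
#' @param c a [correspondence_set()] with n >= 3.
#' @param cfg a [ransac_config()].
#' @return A `pairwise_registration`: fields `transform`, `inlier_mask`
#'   (aligned with `c`), `n_inliers`, `rmse` (inlier RMS re-projection
#'   error), `residuals`.
#' @export
ransac_affine <- function(c, cfg = ransac_config()) {
  stopifnot(c$n >= 3)
  ord <- order(c$src[, 1], c$src[, 2], c$dst[, 1], c$dst[, 2])
  cs <- subset_correspondences(c, ord)
  n <- cs$n
  best_mask <- NULL
  best_count <- -1L
  needed <- cfg$max_iterations
  with_seed(cfg$seed, {
    i <- 0L
    while (i < min(needed, cfg$max_iterations)) {
      i <- i + 1L
      idx <- sample.int(n, 3L)
      tri <- subset_correspondences(cs, idx)
      if (abs(triangle_area2(tri$src)) < 2e-8) next
      A <- solve_affine_minimal(tri)
      mask <- inlier_rule(A, cs, cfg$threshold)
      cnt <- sum(mask)
      if (cnt > best_count) {
        best_count <- cnt
        best_mask <- mask
        w <- cnt / n
        if (w > 0) {
          needed <- if (w >= 1) i else
            ceiling(log(1 - cfg$confidence) / log(1 - w^3))
        }
      }
    }
  })
  if (is.null(best_mask) || best_count < 3L) {
    stop("registration failure: no affine model with >= 3 inliers")
  }
  # consensus re-fit, then re-derive the inlier set (stabilizes quickly)
  mask <- best_mask
  A <- NULL
  for (k in 1:2) {
    A <- solve_affine_lsq(subset_correspondences(cs, mask))
    mask <- inlier_rule(A, cs, cfg$threshold)
    if (sum(mask) < 3L) {
      stop("registration failure: consensus collapsed below 3 inliers")
    }
  }
  errs_orig <- reprojection_errors(A, c)
  new_pairwise_registration(A, errs_orig <= cfg$threshold, errs_orig)
}

#' Levenberg-Marquardt refinement of an affine transform
#'
#' Minimizes the summed squared re-projection error over the given pairs,
#' starting from `A0`. Damped normal-equation steps are accepted only when
#' they reduce the cost, so the cost trace is non-increasing. For this
#' linear-in-parameters model the minimizer coincides with the closed-form
#' least-squares solution; LM is retained as the refinement engine because
#' it is initialization-robust and its accepted-step trace is a useful
#' diagnostic.
#'
#' @param A0 initial [affine()].
#' @param inliers a [correspondence_set()] (n >= 3), typically the RANSAC
#'   consensus set.
#' @param tol termination threshold on the parameter step norm.
#' @param max_steps iteration cap.
#' @return The refined [affine()], with attribute `"cost_trace"` holding the
#'   cost after each accepted step (element 1 = cost at `A0`).
#' @export
refine_lm <- function(A0, inliers, tol = 1e-10, max_steps = 100L) {
  stopifnot(inliers$n >= 3)
  X <- cbind(inliers$src, 1)
  theta <- affine_to_vec(A0)          # (a11, a12, b1, a21, a22, b2)
  resid_fun <- function(th) {
    px <- X %*% th[1:3]
    py <- X %*% th[4:6]
    c(inliers$dst[, 1] - px, inliers$dst[, 2] - py)
  }
  r <- resid_fun(theta)
  cost <- sum(r * r)
  trace <- cost
  # Jacobian of the residual is constant: block-diagonal [-X, -X]
  JtJ_blk <- crossprod(X)
  lambda <- 1e-3
  nx <- nrow(X)
  for (step in seq_len(max_steps)) {
    g1 <- crossprod(X, r[1:nx])       # -J^T r, per block
    g2 <- crossprod(X, r[(nx + 1):(2 * nx)])
    D <- diag(pmax(diag(JtJ_blk), 1e-12))
    M <- JtJ_blk + lambda * D
    d1 <- tryCatch(solve(M, g1), error = function(e) NULL)
    d2 <- tryCatch(solve(M, g2), error = function(e) NULL)
    if (is.null(d1) || is.null(d2)) break
    cand <- theta + c(d1, d2)
    rc <- resid_fun(cand)
    cc <- sum(rc * rc)
    if (cc < cost) {
      accepted_step <- sqrt(sum((cand - theta)^2))
      theta <- cand
      r <- rc
      cost <- cc
      trace <- c(trace, cost)
      lambda <- max(lambda / 10, 1e-12)
      if (accepted_step < tol) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }
  out <- affine_from_vec(theta)
  attr(out, "cost_trace") <- trace
  out
}

# Soft-L1 robust loss rho(z) = 2 (sqrt(1 + z) - 1), z = (r / f_scale)^2.
soft_l1_cost <- function(A, c, f_scale) {
  r <- reprojection_errors(A, c)
  z <- (r / f_scale)^2
  f_scale^2 * sum(2 * (sqrt(1 + z) - 1))
}

#' Robust affine regression with a soft-L1 loss
#'
#' Alternative to RANSAC+LM: minimizes the smooth absolute-loss surrogate
#' `f_scale^2 * sum_i 2 (sqrt(1 + (r_i / f_scale)^2) - 1)` over the full
#' correspondence set via iteratively reweighted least squares (weight
#' `1 / sqrt(1 + z_i)`), initialized from the plain least-squares fit. An
#' inlier mask is re-derived post hoc with `threshold` for reporting, so the
#' result is comparable with [ransac_affine()] output.
#'
#' @param c a [correspondence_set()] with n >= 3.
#' @param f_scale soft-L1 scale in pixels; residuals well below it are
#'   treated quadratically, residuals above it approximately linearly.
#'   Defaults to the RANSAC threshold so the two robust schemes share an
#'   influence scale.
#' @param threshold inlier bound (pixels) for the reported mask.
#' @param max_iter,tol IRLS termination controls.
#' @return A `pairwise_registration`.
#' @export
robust_regression_affine <- function(c, f_scale = 6, threshold = f_scale,
                                     max_iter = 100L, tol = 1e-12) {
  stopifnot(c$n >= 3, f_scale > 0)
  A <- solve_affine_lsq(c)
  theta <- affine_to_vec(A)
  for (it in seq_len(max_iter)) {
    r <- reprojection_errors(A, c)
    wgt <- 1 / sqrt(1 + (r / f_scale)^2)
    A_new <- solve_affine_lsq(c, weights = wgt)
    theta_new <- affine_to_vec(A_new)
    delta <- sqrt(sum((theta_new - theta)^2))
    A <- A_new
    theta <- theta_new
    if (delta < tol) break
  }
  errs <- reprojection_errors(A, c)
  new_pairwise_registration(A, errs <= threshold, errs)
}

#' Register one frame pair end to end
#'
#' Runs the full per-pair pipeline: dense flow (built-in pyramidal LK or a
#' precomputed field), correspondence extraction under the circular mask,
#' robust estimation (RANSAC + LM refinement on the consensus set, or the
#' soft-L1 robust-regression variant), and diagnostics. The returned
#' transform maps target-frame (i+1) coordinates into source-frame (i)
#' coordinates, so chaining toward an earlier reference frame is a plain
#' left multiplication.
#'
#' @param src,tgt consecutive frames (i and i+1).
#' @param flow optional precomputed [flow_field()] from `src` to `tgt`;
#'   when `NULL`, [lk_pyramidal()] is run.
#' @param mask optional [circular_mask()]; estimated from `src` when `NULL`.
#' @param stride correspondence subsampling step.
#' @param cfg a [ransac_config()].
#' @param method `"ransac_lm"` or `"rr"` (soft-L1 robust regression).
#' @param lk_args list of arguments forwarded to [lk_pyramidal()].
#' @param passes model-refinement passes. With `passes > 1` (only
#'   meaningful for the built-in flow backend) the target frame is warped by
#'   the current affine estimate, residual flow is re-estimated on the
#'   warped pair and the correction is composed in — the classic
#'   coarse-to-fine model-based alignment loop, which suppresses the
#'   spatially structured part of the flow error.
#' @return A `pairwise_registration` with additional fields `src_points`
#'   (sampled frame-i pixels, n x 2), `outlier_points` (the frame-i pixels
#'   rejected as outliers — particles/specularities in fetoscopic video)
#'   and `mask`.
#' @export
register_pair <- function(src, tgt, flow = NULL, mask = NULL, stride = 2L,
                          cfg = ransac_config(),
                          method = c("ransac_lm", "rr"),
                          lk_args = list(), passes = 1L) {
  method <- match.arg(method)
  if (is.null(mask)) mask <- estimate_mask(src)
  builtin <- is.null(flow)
  if (builtin) {
    if (is.null(lk_args$roi)) lk_args$roi <- mask$raster
    flow <- do.call(lk_pyramidal, c(list(src = src, tgt = tgt), lk_args))
  }
  fit_one <- function(corr) {
    # fit A : frame i+1 -> frame i, i.e. src coordinates predicted from dst
    fit_set <- swap_correspondences(corr)
    if (method == "ransac_lm") {
      reg <- ransac_affine(fit_set, cfg)
      A <- refine_lm(reg$transform,
                     subset_correspondences(fit_set, reg$inlier_mask))
      errs <- reprojection_errors(A, fit_set)
      new_pairwise_registration(A, errs <= cfg$threshold, errs)
    } else {
      robust_regression_affine(fit_set, f_scale = cfg$threshold,
                               threshold = cfg$threshold)
    }
  }
  corr <- flow_to_correspondences(flow, mask, stride)
  if (corr$n < 3) stop("registration failure: fewer than 3 correspondences")
  reg <- fit_one(corr)
  if (builtin && passes > 1L) {
    fd <- frame_dim(src)
    canvas <- list(height = fd[1], width = fd[2],
                   origin_offset = affine_translation(0, 0))
    r_args <- lk_args
    r_args$levels <- min(c(r_args$levels, 2L))   # residual motion is small
    win <- if (is.null(lk_args$window)) formals(lk_pyramidal)$window else
      lk_args$window
    rmask <- circular_mask(mask$cx, mask$cy,
                           max(mask$radius - win / 2, mask$radius * 0.5),
                           dim(mask$raster))
    r_args$roi <- rmask$raster
    for (p in seq_len(passes - 1L)) {
      # warp tgt into src coordinates with the current estimate, measure the
      # residual motion and fold the correction into the transform
      wp <- warp_frame(tgt, reg$transform, NULL, canvas)
      rflow <- do.call(lk_pyramidal,
                       c(list(src = src, tgt = wp$image), r_args))
      rflow$valid <- rflow$valid & wp$valid
      rcorr <- flow_to_correspondences(rflow, rmask, stride)
      if (rcorr$n < 3) break
      corr_reg <- fit_one(rcorr)
      A <- affine_compose(corr_reg$transform, reg$transform)
      reg <- new_pairwise_registration(A, corr_reg$inlier_mask,
                                       corr_reg$residuals)
      corr <- rcorr
    }
  }
  reg$src_points <- corr$src
  reg$outlier_points <- corr$src[!reg$inlier_mask, , drop = FALSE]
  reg$mask <- mask
  reg
}
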