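# Low-level raster primitives shared by every module.
#
# Conventions used throughout the package:
#   * images are numeric matrices [h x w] (grayscale, intensities in [0, 1])
#     or arrays [h x w x 3] (RGB);
#   * pixel coordinates are 0-based, x = column index increasing rightward,
#     y = row index increasing downward, pixel centers at integers, so the
#     matrix entry img[r, c] sits at (x, y) = (c - 1, r - 1).

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so library code never perturbs user randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-item substream seed derived from a master seed.
# Kept strictly below 2^31 (R integers).
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 7919 + 12345) %%
               2147483629)
}

#' Convert a color frame to grayscale
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114). Grayscale input is returned
#' unchanged.
#'
#' @param img matrix or `[h x w x 3]` array in `[0, 1]`.
#' @return numeric matrix `[h x w]`.
#' @export
as_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

frame_dim <- function(img) dim(img)[1:2]

n_channels <- function(img) if (is.matrix(img)) 1L else dim(img)[3]

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Normalized 1-D Gaussian kernel, odd length 2*radius + 1.
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of every column of m with odd-length kernel k.
conv_cols <- function(m, k, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  if (r == 0L) return(m * k)
  top <- if (pad == "replicate") m[rep(1L, r), , drop = FALSE] else
    matrix(0, r, ncol(m))
  bot <- if (pad == "replicate") m[rep(n, r), , drop = FALSE] else
    matrix(0, r, ncol(m))
  mp <- rbind(top, m, bot)
  out <- stats::filter(mp, k, method = "convolution", sides = 2)
  out <- matrix(as.numeric(out), nrow = nrow(mp))
  out[(r + 1L):(r + n), , drop = FALSE]
}

# Separable 2-D convolution: column kernel ky then row kernel kx.
conv_sep <- function(img, kx, ky = kx, pad = "replicate") {
  t(conv_cols(t(conv_cols(img, ky, pad)), kx, pad))
}

# Gaussian smoothing of a matrix.
gauss_smooth <- function(img, sigma) {
  conv_sep(img, gauss_kernel(sigma))
}

# Windowed box sum (kernel of ones, odd size), zero padded.
box_sum <- function(img, size) {
  conv_sep(img, rep(1, size), pad = "zero")
}

#' Bilinear sampling at fractional 0-based coordinates
#'
#' @param img numeric matrix `[h x w]`.
#' @param x,y numeric vectors of 0-based column/row coordinates.
#' @param outside value returned for samples outside the image.
#' @return numeric vector of sampled values, shaped like `x`.
#' @keywords internal
bilinear_sample <- function(img, x, y, outside = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  out_dim <- dim(x)
  x <- as.numeric(x)
  y <- as.numeric(y)
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1) &
    is.finite(x) & is.finite(y)
  x0 <- pmin(pmax(floor(x), 0), w - 2)
  y0 <- pmin(pmax(floor(y), 0), h - 2)
  fx <- x - x0
  fy <- y - y0
  x0[!inside] <- 0; y0[!inside] <- 0; fx[!inside] <- 0; fy[!inside] <- 0
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[cbind(y0 + 1, x0 + 2)] +
    (1 - fx) * fy * img[cbind(y0 + 2, x0 + 1)] +
    fx * fy * img[cbind(y0 + 2, x0 + 2)]
  v[!inside] <- outside
  dim(v) <- out_dim
  v
}

#' Bicubic (Catmull-Rom) sampling at fractional 0-based coordinates
#'
#' Higher-order companion to [bilinear_sample()]. Bilinear interpolation
#' attenuates high frequencies by an amount that varies with the fractional
#' part of the sample position; in iterative warp-and-compare loops that
#' attenuation acts like a spatially periodic blur field and biases
#' gradient-based estimates. The cubic kernel keeps that attenuation an
#' order of magnitude smaller. Border pixels fall back to clamped indexing.
#'
#' @inheritParams bilinear_sample
#' @keywords internal
bicubic_sample <- function(img, x, y, outside = NA_real_) {
  h <- nrow(img); w <- ncol(img)
  out_dim <- dim(x)
  x <- as.numeric(x)
  y <- as.numeric(y)
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1) &
    is.finite(x) & is.finite(y)
  x0 <- pmin(pmax(floor(x), 0), w - 1)
  y0 <- pmin(pmax(floor(y), 0), h - 1)
  tx <- x - x0
  ty <- y - y0
  tx[!inside] <- 0; ty[!inside] <- 0
  cr <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(-0.5 * t3 + t2 - 0.5 * t,
         1.5 * t3 - 2.5 * t2 + 1,
         -1.5 * t3 + 2 * t2 + 0.5 * t,
         0.5 * t3 - 0.5 * t2)
  }
  wx <- cr(tx)
  wy <- cr(ty)
  cl_r <- function(r) pmin(pmax(r, 0), h - 1)
  cl_c <- function(c) pmin(pmax(c, 0), w - 1)
  v <- 0
  for (j in 1:4) {
    row_acc <- 0
    rr <- cl_r(y0 + j - 2)
    for (i in 1:4) {
      row_acc <- row_acc + wx[[i]] * img[cbind(rr + 1, cl_c(x0 + i - 2) + 1)]
    }
    v <- v + wy[[j]] * row_acc
  }
  v[!inside] <- outside
  dim(v) <- out_dim
  v
}

# 0-based coordinate grids for an h x w raster: list(x, y) of h x w matrices.
pixel_grid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

# Downsample a matrix by 2 after Gaussian pre-smoothing (sigma = 1).
pyr_down <- function(img, sigma = 1) {
  s <- gauss_smooth(img, sigma)
  s[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}

# Resize a matrix to (h, w) by bilinear interpolation.
resize_bilinear <- function(img, h, w) {
  sy <- nrow(img) / h
  sx <- ncol(img) / w
  g <- pixel_grid(h, w)
  # map output pixel centers into input coordinates, clamped to the frame
  xs <- pmin(pmax((g$x + 0.5) * sx - 0.5, 0), ncol(img) - 1)
  ys <- pmin(pmax((g$y + 0.5) * sy - 0.5, 0), nrow(img) - 1)
  bilinear_sample(img, xs, ys, outside = 0)
}
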