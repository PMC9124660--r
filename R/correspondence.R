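# From flow fields to explicit point correspondences inside the circular
# fetoscope field of view. The fetoscope produces a bright circular image
# surrounded by black; pixels outside that circle carry no scene content
# and are excluded from registration entirely.

#' Construct a circular field-of-view mask
#'
#' @param cx,cy circle center (0-based pixel coordinates).
#' @param radius circle radius (pixels, > 0).
#' @param dim `c(h, w)` raster size.
#' @return An object of class `circular_mask` with fields `cx`, `cy`,
#'   `radius` and a logical `raster` that is `TRUE` exactly where
#'   `(x - cx)^2 + (y - cy)^2 <= radius^2`.
#' @export
circular_mask <- function(cx, cy, radius, dim) {
  stopifnot(radius > 0, length(dim) == 2)
  g <- pixel_grid(dim[1], dim[2])
  raster <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
  structure(list(cx = cx, cy = cy, radius = radius, raster = raster),
            class = "circular_mask")
}

#' @export
print.circular_mask <- function(x, ...) {
  cat(sprintf("circular mask: center (%.1f, %.1f), radius %.1f px\n",
              x$cx, x$cy, x$radius))
  invisible(x)
}

#' Construct a correspondence set
#'
#' Paired point lists between a source frame i and target frame i+1.
#'
#' @param src,dst n x 2 matrices of (x, y) coordinates (equal n).
#' @return An object of class `correspondence_set`.
#' @export
correspondence_set <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  stopifnot(nrow(src) == nrow(dst))
  structure(list(src = src, dst = dst, n = nrow(src)),
            class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat("correspondence set with", x$n, "pairs\n")
  invisible(x)
}

# Swap source/target roles (used to estimate the frame i+1 -> i transform).
swap_correspondences <- function(c) correspondence_set(c$dst, c$src)

subset_correspondences <- function(c, keep) {
  correspondence_set(c$src[keep, , drop = FALSE], c$dst[keep, , drop = FALSE])
}

#' Convert a flow field to point correspondences under a circular mask
#'
#' Every valid flow pixel (x, y) inside the mask, sampled on a regular
#' stride grid, contributes the pair src = (x, y), dst = (x + u, y + v).
#' Masked-out or invalid pixels are excluded entirely; destination points
#' are allowed to leave the field of view (the robust estimator deals with
#' any resulting inconsistency).
#'
#' @param flow a [flow_field()].
#' @param mask a [circular_mask()] with raster of the same size.
#' @param stride positive integer subsampling step (1 = every pixel).
#' @return A [correspondence_set()].
#' @export
flow_to_correspondences <- function(flow, mask, stride = 2L) {
  if (!all(dim(flow$u) == dim(mask$raster))) {
    stop("size mismatch between flow (", paste(dim(flow$u), collapse = "x"),
         ") and mask (", paste(dim(mask$raster), collapse = "x"), ")")
  }
  stopifnot(stride >= 1)
  h <- nrow(flow$u); w <- ncol(flow$u)
  rows <- seq(1, h, by = stride)
  cols <- seq(1, w, by = stride)
  keep <- matrix(FALSE, h, w)
  keep[rows, cols] <- TRUE
  sel <- which(keep & mask$raster & flow$valid)
  y <- (sel - 1) %% h          # 0-based row
  x <- (sel - 1) %/% h         # 0-based col
  u <- flow$u[sel]
  v <- flow$v[sel]
  correspondence_set(cbind(x, y), cbind(x + u, y + v))
}

#' Estimate the circular field-of-view mask from a frame
#'
#' The fetoscopic field of view appears as a bright disc on a black
#' surround. The frame is thresholded, the largest connected component is
#' taken, and a circle is fitted from its centroid and equivalent radius
#' (`sqrt(area / pi)`). When the fit is implausible (component not
#' disc-shaped, radius outside a sane range) a fallback circle is returned:
#' the largest circle inscribed in the frame, or a user-supplied one.
#'
#' @param frame a frame (matrix or RGB array in `[0, 1]`).
#' @param threshold intensity separating the field of view from the black
#'   surround.
#' @param fallback optional [circular_mask()] used when detection fails.
#' @return A [circular_mask()] (never `NULL`).
#' @export
estimate_mask <- function(frame, threshold = 0.08, fallback = NULL) {
  gray <- as_gray(frame)
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(fallback)) {
    fallback <- circular_mask((w - 1) / 2, (h - 1) / 2, min(h, w) / 2,
                              c(h, w))
  }
  bw <- gray > threshold
  if (!any(bw)) return(fallback)
  # EBImage works on [x, y] = transposed rasters
  lab <- EBImage::bwlabel(EBImage::Image(t(bw)))
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0) return(fallback)
  big <- which.max(tab)
  comp <- t(EBImage::imageData(lab) == big)
  area <- sum(comp)
  g <- pixel_grid(h, w)
  cx <- sum(g$x[comp]) / area
  cy <- sum(g$y[comp]) / area
  r <- sqrt(area / pi)
  if (r < 0.15 * min(h, w) || r > 0.6 * min(h, w)) return(fallback)
  circle <- (g$x - cx)^2 + (g$y - cy)^2 <= r^2
  containment <- sum(comp & circle) / area          # component inside circle
  coverage <- sum(comp & circle) / sum(circle)      # circle filled by comp.
  if (containment < 0.96 || coverage < 0.9) return(fallback)
  circular_mask(cx, cy, r, c(h, w))
}

#' Read a mask supplied by the user
#'
#' Either a binary PNG (non-zero = inside; a circle is fitted to it by
#' centroid/equivalent radius) or a string `"cx,cy,r"`.
#'
#' @param spec file path or `"cx,cy,r"` string.
#' @param dim `c(h, w)` raster size.
#' @return A [circular_mask()].
#' @export
read_mask <- function(spec, dim) {
  if (file.exists(spec)) {
    img <- png::readPNG(spec)
    bw <- as_gray(img) > 0.5
    area <- sum(bw)
    if (area == 0) stop("mask image is empty: ", spec)
    g <- pixel_grid(nrow(bw), ncol(bw))
    return(circular_mask(sum(g$x[bw]) / area, sum(g$y[bw]) / area,
                         sqrt(area / pi), dim))
  }
  v <- suppressWarnings(as.numeric(strsplit(spec, ",")[[1]]))
  if (length(v) != 3 || anyNA(v)) {
    stop("mask spec must be a PNG path or 'cx,cy,r': ", spec)
  }
  circular_mask(v[1], v[2], v[3], dim)
}
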