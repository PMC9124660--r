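# Mosaic construction: chain pairwise transforms to a reference frame, warp
# every frame onto a common canvas and blend. The reference frame (the
# mosaic plane) defaults to the middle of the sequence so accumulated error
# spreads both ways; frames before/after it are warped forward/backward by
# left-hand multiplication of the pairwise affines.

#' Chain pairwise transforms to a reference frame
#'
#' Pairwise element k maps frame k+1 coordinates into frame k coordinates.
#' The absolute transform of frame f maps frame f into the reference frame:
#' identity at the reference, cumulative left-multiplied products of the
#' pairwise transforms after it, and of their inverses before it.
#'
#' @param pairwise list of length n_frames - 1; each element an [affine()]
#'   or a `pairwise_registration`. A `NULL` element marks a failed pair and
#'   breaks the chain.
#' @param reference_index 1-based reference frame; defaults to the middle
#'   frame `n %/% 2 + 1`.
#' @return A `trajectory` object: list with `reference_index` and
#'   `absolute`, a list of n_frames [affine()] transforms.
#' @export
chain_to_reference <- function(pairwise, reference_index = NULL) {
  n <- length(pairwise) + 1L
  if (is.null(reference_index)) reference_index <- n %/% 2L + 1L
  stopifnot(reference_index >= 1, reference_index <= n)
  pw <- lapply(pairwise, function(p) {
    if (is.null(p)) return(NULL)
    if (inherits(p, "pairwise_registration")) p$transform else p
  })
  broken <- which(vapply(pw, is.null, logical(1)))
  absolute <- vector("list", n)
  absolute[[reference_index]] <- affine_identity()
  if (reference_index < n) {
    acc <- affine_identity()
    for (k in reference_index:(n - 1L)) {
      if (k %in% broken) {
        stop("broken chain: registration failed at pair ", k,
             " (frames ", k, "-", k + 1L, ")")
      }
      acc <- affine_compose(acc, pw[[k]])
      absolute[[k + 1L]] <- acc
    }
  }
  if (reference_index > 1) {
    acc <- affine_identity()
    for (k in (reference_index - 1L):1L) {
      if (k %in% broken) {
        stop("broken chain: registration failed at pair ", k,
             " (frames ", k, "-", k + 1L, ")")
      }
      acc <- affine_compose(acc, affine_invert(pw[[k]]))
      absolute[[k]] <- acc
    }
  }
  structure(list(reference_index = reference_index, absolute = absolute),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, reference %d\n",
              length(x$absolute), x$reference_index))
  invisible(x)
}

#' Canvas bounds covering a whole trajectory
#'
#' Transforms the bounding box of the field-of-view mask (or the full frame)
#' of every frame into reference coordinates and takes the union, plus a
#' margin.
#'
#' @param traj a trajectory from [chain_to_reference()].
#' @param frame_size `c(h, w)`.
#' @param mask optional [circular_mask()] restricting each frame's extent.
#' @param margin extra border in pixels.
#' @return List with `xmin`, `ymin`, `width`, `height`, `origin_offset`
#'   (an [affine_translation()] mapping canvas to reference coordinates).
#' @export
compute_canvas <- function(traj, frame_size, mask = NULL, margin = 2) {
  h <- frame_size[1]; w <- frame_size[2]
  if (is.null(mask)) {
    x0 <- 0; x1 <- w - 1; y0 <- 0; y1 <- h - 1
  } else {
    x0 <- max(0, mask$cx - mask$radius); x1 <- min(w - 1, mask$cx + mask$radius)
    y0 <- max(0, mask$cy - mask$radius); y1 <- min(h - 1, mask$cy + mask$radius)
  }
  corners <- cbind(c(x0, x1, x0, x1), c(y0, y0, y1, y1))
  pts <- do.call(rbind, lapply(traj$absolute, affine_apply, pts = corners))
  xmin <- floor(min(pts[, 1])) - margin
  ymin <- floor(min(pts[, 2])) - margin
  xmax <- ceiling(max(pts[, 1])) + margin
  ymax <- ceiling(max(pts[, 2])) + margin
  list(xmin = xmin, ymin = ymin,
       width = as.integer(xmax - xmin + 1),
       height = as.integer(ymax - ymin + 1),
       origin_offset = affine_translation(xmin, ymin))
}

#' Warp one frame onto the mosaic canvas
#'
#' Inverse warping with bilinear interpolation: every canvas pixel is mapped
#' back through the inverse transform into source-frame coordinates and
#' sampled there. Pixels falling outside the source frame or outside its
#' field-of-view mask contribute nothing.
#'
#' @param frame matrix or RGB array.
#' @param A_to_reference [affine()] mapping frame to reference coordinates.
#' @param mask optional [circular_mask()] for the frame.
#' @param canvas canvas description from [compute_canvas()].
#' @return List with `image` (canvas-sized raster) and `valid` (logical).
#' @export
warp_frame <- function(frame, A_to_reference, mask = NULL, canvas) {
  h <- canvas$height; w <- canvas$width
  fh <- frame_dim(frame)[1]; fw <- frame_dim(frame)[2]
  back <- affine_compose(affine_invert(A_to_reference), canvas$origin_offset)
  g <- pixel_grid(h, w)
  src <- affine_apply(back, cbind(as.numeric(g$x), as.numeric(g$y)))
  sx <- matrix(src[, 1], h, w)
  sy <- matrix(src[, 2], h, w)
  valid <- sx >= 0 & sx <= (fw - 1) & sy >= 0 & sy <= (fh - 1)
  if (!is.null(mask)) {
    valid <- valid & ((sx - mask$cx)^2 + (sy - mask$cy)^2 <= mask$radius^2)
  }
  sample_ch <- function(m) {
    out <- bicubic_sample(m, sx, sy, outside = 0)
    out[!valid] <- 0
    out
  }
  img <- if (is.matrix(frame)) {
    sample_ch(frame)
  } else {
    array(c(sample_ch(frame[, , 1]), sample_ch(frame[, , 2]),
            sample_ch(frame[, , 3])), dim = c(h, w, 3))
  }
  list(image = img, valid = valid)
}

# Feathering weight: Euclidean distance to the nearest invalid pixel,
# computed on a zero-padded raster so frame borders count as invalid.
feather_weight <- function(valid) {
  h <- nrow(valid); w <- ncol(valid)
  padded <- matrix(0, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- valid
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(t(padded))))
  t(d)[2:(h + 1), 2:(w + 1)]
}

gauss_pyramid <- function(img, levels, sigma = 1) {
  pyr <- list(img)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr[[l]])) < 8) break
    pyr[[l + 1]] <- pyr_down(pyr[[l]], sigma)
  }
  pyr
}

laplacian_pyramid <- function(img, levels, sigma = 1) {
  gp <- gauss_pyramid(img, levels, sigma)
  nl <- length(gp)
  lp <- vector("list", nl)
  for (l in seq_len(nl - 1)) {
    up <- resize_bilinear(gp[[l + 1]], nrow(gp[[l]]), ncol(gp[[l]]))
    lp[[l]] <- gp[[l]] - up
  }
  lp[[nl]] <- gp[[nl]]
  lp
}

collapse_pyramid <- function(lp) {
  acc <- lp[[length(lp)]]
  if (length(lp) == 1) return(acc)
  for (l in (length(lp) - 1):1) {
    acc <- resize_bilinear(acc, nrow(lp[[l]]), ncol(lp[[l]])) + lp[[l]]
  }
  acc
}

# Multi-resolution spline blending: frames are combined level-by-level in a
# Laplacian pyramid with weights blurred at each level, so low frequencies
# blend over wide transition zones and high frequencies over narrow ones.
# Each frame's invalid area is pre-filled with the feathered composite
# (`base`) so pyramid smoothing never drags in out-of-footprint zeros.
blend_multiband <- function(images, weights, base, levels = 4) {
  nch <- n_channels(images[[1]])
  norm_w <- weights
  wp <- lapply(norm_w, gauss_pyramid, levels = levels)
  nl <- length(wp[[1]])
  blend_ch <- function(chs, base_ch) {
    filled <- Map(function(im, w) ifelse(w > 0, im, base_ch), chs, weights)
    lps <- lapply(filled, laplacian_pyramid, levels = levels)
    out_lv <- vector("list", nl)
    for (l in seq_len(nl)) {
      wsum <- Reduce(`+`, lapply(wp, `[[`, l))
      acc <- Reduce(`+`, Map(function(lpf, wpf) lpf[[l]] * wpf[[l]], lps, wp))
      out_lv[[l]] <- acc / pmax(wsum, 1e-12)
    }
    collapse_pyramid(out_lv)
  }
  if (nch == 1) {
    img <- blend_ch(images, base)
  } else {
    img <- array(0, dim = c(dim(images[[1]])[1:2], 3))
    for (ch in 1:3) {
      img[, , ch] <- blend_ch(lapply(images, function(im) im[, , ch]),
                              base[, , ch])
    }
  }
  img
}

#' Blend warped frames into a mosaic
#'
#' `"feather"` (default) is a distance-transform-weighted average: each
#' frame's weight at a pixel is its distance to the frame's field-of-view
#' boundary, so seams fade smoothly. `"multiband"` is multi-resolution
#' spline blending: validity-weighted combination of Laplacian-pyramid
#' levels, collapsing to a seam-free composite.
#'
#' @param warped list of `list(image, valid)` as produced by [warp_frame()],
#'   all on the same canvas.
#' @param mode `"feather"` or `"multiband"`.
#' @param levels pyramid depth for multiband blending.
#' @return A `mosaic_canvas`: list with `image`, `weight` (accumulated
#'   feather weight; 0 where uncovered) and `covered` (logical raster).
#' @export
blend <- function(warped, mode = c("feather", "multiband"), levels = 4) {
  mode <- match.arg(mode)
  stopifnot(length(warped) >= 1)
  weights <- lapply(warped, function(wf) feather_weight(wf$valid))
  total <- Reduce(`+`, weights)
  covered <- total > 0
  images <- lapply(warped, `[[`, "image")
  nch <- n_channels(images[[1]])
  denom <- pmax(total, 1e-12)
  if (nch == 1) {
    img <- Reduce(`+`, Map(`*`, images, weights)) / denom
  } else {
    img <- array(0, dim = dim(images[[1]]))
    for (ch in 1:3) {
      img[, , ch] <- Reduce(`+`, Map(function(im, w) im[, , ch] * w,
                                     images, weights)) / denom
    }
  }
  if (mode == "multiband") {
    img <- blend_multiband(images, weights, img, levels)
  }
  if (nch == 1) {
    img[!covered] <- 0
    img <- clamp01(img)
  } else {
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[!covered] <- 0
      img[, , ch] <- clamp01(pl)
    }
  }
  structure(list(image = img, weight = total, covered = covered),
            class = "mosaic_canvas")
}

#' @export
print.mosaic_canvas <- function(x, ...) {
  cat(sprintf("mosaic canvas %d x %d, %.1f%% covered\n",
              nrow(x$weight), ncol(x$weight), 100 * mean(x$covered)))
  invisible(x)
}

#' Build a mosaic from frames and a trajectory
#'
#' @param frames list of frames.
#' @param traj trajectory from [chain_to_reference()].
#' @param mask optional shared [circular_mask()].
#' @param mode blending mode, see [blend()].
#' @param levels multiband pyramid depth.
#' @return A `mosaic_canvas`.
#' @export
render_mosaic <- function(frames, traj, mask = NULL,
                          mode = c("feather", "multiband"), levels = 4) {
  mode <- match.arg(mode)
  canvas <- compute_canvas(traj, frame_dim(frames[[1]]), mask)
  warped <- Map(function(f, A) warp_frame(f, A, mask, canvas),
                frames, traj$absolute)
  out <- blend(warped, mode, levels)
  out$canvas <- canvas
  out
}

#' Incremental mosaic previews
#'
#' Blends the first k, 2k, ... frames, ending with the full mosaic — the
#' supplementary-video style growing view.
#'
#' @param frames list of frames.
#' @param traj trajectory covering the frames.
#' @param every_k spacing between previews.
#' @param mask optional [circular_mask()].
#' @param mode blending mode.
#' @return List of `mosaic_canvas` objects (last one uses all frames).
#' @export
incremental_preview <- function(frames, traj, every_k = 10L, mask = NULL,
                                mode = "feather") {
  n <- length(frames)
  canvas <- compute_canvas(traj, frame_dim(frames[[1]]), mask)
  warped <- Map(function(f, A) warp_frame(f, A, mask, canvas),
                frames, traj$absolute)
  stops <- unique(c(seq(min(every_k, n), n, by = every_k), n))
  lapply(stops, function(k) {
    out <- blend(warped[seq_len(k)], mode)
    out$canvas <- canvas
    out
  })
}
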