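# Dense optical flow between consecutive frames.
#
# The built-in backbone is classic pyramidal Lucas-Kanade: a coarse-to-fine
# Gaussian pyramid, and at each level an iterative solve of the local
# brightness-constancy normal equations over a Gaussian-weighted window,
# warping the target by the current flow estimate between iterations.
# Externally computed flow (e.g. from a deep network) enters through
# load_flow(); the package never runs a network itself.

#' Construct a flow field
#'
#' A flow field stores, for every pixel (x, y) of the source frame, the
#' displacement (u, v) such that the matching location in the target frame
#' is (x + u, y + v), plus a validity raster marking pixels where flow was
#' estimable.
#'
#' @param u,v numeric matrices of horizontal/vertical displacements (pixels).
#' @param valid logical matrix, same size; defaults to all-valid.
#' @return An object of class `flow_field`.
#' @export
flow_field <- function(u, v, valid = NULL) {
  stopifnot(is.matrix(u), is.matrix(v), all(dim(u) == dim(v)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  stopifnot(all(dim(valid) == dim(u)))
  structure(list(u = u, v = v, valid = valid), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow field %d x %d, %.1f%% valid\n", nrow(x$u), ncol(x$u),
              100 * mean(x$valid)))
  invisible(x)
}

#' Pyramidal Lucas-Kanade dense optical flow
#'
#' Estimates the dense displacement field from `src` to `tgt`. Pixels whose
#' local gradient structure tensor is near-singular (smallest eigenvalue of
#' the window-averaged tensor below `eig_floor`) are marked invalid: the
#' aperture problem makes their flow unobservable.
#'
#' @param src,tgt frames of identical size (matrix or RGB array, `[0, 1]`).
#' @param levels number of pyramid levels (>= 1).
#' @param window odd window size (pixels) for the local least-squares fit.
#' @param iterations warp-and-refine iterations per level.
#' @param eig_floor validity floor on the smallest eigenvalue of the
#'   window-averaged structure tensor (intensity units squared).
#' @param presmooth_sigma Gaussian smoothing applied to both frames before
#'   differentiation (every pyramid level, including the finest). The
#'   brightness-constancy linearization needs a band-limited signal;
#'   without it, pixel noise and the high-frequency attenuation of the
#'   bilinear warp bias the estimate. Set to 0 to disable.
#' @param roi optional logical matrix naming the pixels that matter (the
#'   fetoscope field of view). Validity statistics — in particular the
#'   texture-poor fallback of the eigenvalue floor — are computed inside
#'   it, so the bright rim of the field of view cannot mask a collapse of
#'   usable texture in the scene itself.
#' @return A [flow_field()].
#' @export
lk_pyramidal <- function(src, tgt, levels = 3, window = 21, iterations = 8,
                         eig_floor = 1e-5, presmooth_sigma = 0.8,
                         roi = NULL) {
  if (!all(frame_dim(src) == frame_dim(tgt))) {
    stop("frame-size mismatch: ", paste(frame_dim(src), collapse = "x"),
         " vs ", paste(frame_dim(tgt), collapse = "x"))
  }
  stopifnot(levels >= 1, window >= 3, window %% 2 == 1, iterations >= 1)
  a <- as_gray(src)
  b <- as_gray(tgt)
  if (presmooth_sigma > 0) {
    a <- gauss_smooth(a, presmooth_sigma)
    b <- gauss_smooth(b, presmooth_sigma)
  }

  if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
  pyr_a <- list(a); pyr_b <- list(b); pyr_r <- list(roi)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr_a[[l]])) < 2 * window) break
    pyr_a[[l + 1]] <- pyr_down(pyr_a[[l]])
    pyr_b[[l + 1]] <- pyr_down(pyr_b[[l]])
    pyr_r[[l + 1]] <- pyr_r[[l]][seq(1, nrow(pyr_r[[l]]), by = 2),
                                 seq(1, ncol(pyr_r[[l]]), by = 2),
                                 drop = FALSE]
  }
  nl <- length(pyr_a)

  wk <- gauss_kernel(window / 6, radius = (window - 1) %/% 2)
  u <- matrix(0, nrow(pyr_a[[nl]]), ncol(pyr_a[[nl]]))
  v <- u
  lam <- NULL
  for (l in nl:1) {
    al <- pyr_a[[l]]; bl <- pyr_b[[l]]
    h <- nrow(al); w <- ncol(al)
    if (l < nl) {
      u <- 2 * resize_bilinear(u, h, w)
      v <- 2 * resize_bilinear(v, h, w)
    }
    g <- pixel_grid(h, w)
    # spatial gradients of the source (central differences)
    Ix <- (cbind(al[, -1], al[, w]) - cbind(al[, 1], al[, -w])) / 2
    Iy <- (rbind(al[-1, ], al[h, ]) - rbind(al[1, ], al[-h, ])) / 2
    Sxx <- conv_sep(Ix * Ix, wk)
    Sxy <- conv_sep(Ix * Iy, wk)
    Syy <- conv_sep(Iy * Iy, wk)
    tr <- Sxx + Syy
    lam <- (tr - sqrt(pmax((Sxx - Syy)^2 + 4 * Sxy^2, 0))) / 2
    det <- Sxx * Syy - Sxy^2
    solvable <- lam > adaptive_floor(lam[pyr_r[[l]]], eig_floor) & det > 0
    for (it in seq_len(iterations)) {
      bw <- bicubic_sample(bl, g$x + u, g$y + v, outside = NA_real_)
      It <- bw - al
      off <- !is.finite(It)
      It[off] <- 0
      Sxt <- conv_sep(Ix * It, wk)
      Syt <- conv_sep(Iy * It, wk)
      du <- -(Syy * Sxt - Sxy * Syt) / det
      dv <- -(Sxx * Syt - Sxy * Sxt) / det
      du[!solvable] <- 0
      dv[!solvable] <- 0
      # damp implausible single-step jumps (occlusions, border effects)
      step <- sqrt(du^2 + dv^2)
      big <- step > window
      du[big] <- du[big] * window / step[big]
      dv[big] <- dv[big] * window / step[big]
      u <- u + du
      v <- v + dv
    }
  }
  h <- nrow(a); w <- ncol(a)
  g <- pixel_grid(h, w)
  tx <- g$x + u; ty <- g$y + v
  inb <- tx >= 0 & tx <= (w - 1) & ty >= 0 & ty <= (h - 1)
  valid <- (lam > adaptive_floor(lam[roi], eig_floor)) & inb
  u[!valid] <- 0
  v[!valid] <- 0
  flow_field(u, v, valid)
}

# Structure-tensor validity floor with a texture-poor fallback. The
# absolute floor applies whenever it leaves enough support (`trigger`
# fraction of the region of interest); on frames where usable texture
# collapses below that (smooth tissue, defocus), the relatively best
# `rescue` fraction of pixels is kept instead. The rescue set is made
# deliberately broad: with few strong pixels the affine fit needs spatial
# spread more than per-pixel quality, since its corner error is dominated
# by the lever arm of the support. Frames with no gradient signal at all
# (flat images) keep zero support.
adaptive_floor <- function(lam, eig_floor, trigger = 0.05, rescue = 0.3) {
  if (length(lam) == 0 || mean(lam > eig_floor) >= trigger) return(eig_floor)
  q <- stats::quantile(lam, 1 - rescue, names = FALSE)
  max(min(eig_floor, q), eig_floor * 1e-4)
}

FLO_MAGIC <- 202021.25

#' Write a flow field to disk
#'
#' Two layouts are supported. `"planes"` (default) writes row-major float64
#' planes (u, then v, then validity as 0/1) to `<path>` with a JSON sidecar
#' `<path>.json` recording height, width and plane names; it round-trips
#' doubles exactly. `"flo"` writes the common two-channel binary layout
#' (float32 magic tag, int32 width/height, interleaved row-major float32
#' u,v), which quantizes to single precision and drops the validity raster.
#'
#' @param flow a [flow_field()].
#' @param path output file path.
#' @param format `"planes"` or `"flo"`.
#' @return `path`, invisibly.
#' @export
save_flow <- function(flow, path, format = c("planes", "flo")) {
  format <- match.arg(format)
  h <- nrow(flow$u); w <- ncol(flow$u)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "flo") {
    writeBin(FLO_MAGIC, con, size = 4, endian = "little")
    writeBin(as.integer(c(w, h)), con, size = 4, endian = "little")
    inter <- rbind(as.numeric(t(flow$u)), as.numeric(t(flow$v)))
    writeBin(as.numeric(inter), con, size = 4, endian = "little")
  } else {
    planes <- c("u", "v", "valid")
    writeBin(c(as.numeric(t(flow$u)), as.numeric(t(flow$v)),
               as.numeric(t(flow$valid))), con, size = 8, endian = "little")
    jsonlite::write_json(
      list(height = h, width = w, planes = planes, dtype = "float64",
           order = "row-major"),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a flow field from disk
#'
#' Accepts both layouts written by [save_flow()]; the layout is detected
#' from the presence of a JSON sidecar, falling back to the `.flo` magic tag.
#'
#' @param path file path.
#' @param expect_dim optional `c(h, w)` to validate against.
#' @return A [flow_field()].
#' @export
load_flow <- function(path, expect_dim = NULL) {
  if (!file.exists(path)) stop("flow file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    h <- as.integer(meta$height); w <- as.integer(meta$width)
    planes <- meta$planes
    if (is.null(h) || is.null(w) || is.null(planes) ||
        !all(planes[1:2] == c("u", "v")) ||
        !(length(planes) %in% c(2L, 3L))) {
      stop("malformed flow sidecar: ", sidecar)
    }
    npix <- as.double(h) * w
    raw <- readBin(path, "double", n = npix * length(planes) + 1, size = 8,
                   endian = "little")
    if (length(raw) != npix * length(planes)) {
      stop("malformed flow file: expected ", npix * length(planes),
           " float64 values, found ", length(raw))
    }
    take <- function(i) matrix(raw[((i - 1) * npix + 1):(i * npix)],
                               h, w, byrow = TRUE)
    u <- take(1); v <- take(2)
    valid <- if (length(planes) == 3L) take(3) > 0.5 else NULL
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readBin(con, "numeric", 1, size = 4, endian = "little")
    if (length(magic) != 1 || abs(magic - FLO_MAGIC) > 1e-3) {
      stop("malformed flow file (bad magic tag): ", path)
    }
    wh <- readBin(con, "integer", 2, size = 4, endian = "little")
    w <- wh[1]; h <- wh[2]
    npix <- as.double(h) * w
    raw <- readBin(con, "numeric", 2 * npix + 1, size = 4, endian = "little")
    if (length(raw) != 2 * npix) stop("malformed flow file (truncated): ", path)
    u <- matrix(raw[seq(1, 2 * npix, 2)], h, w, byrow = TRUE)
    v <- matrix(raw[seq(2, 2 * npix, 2)], h, w, byrow = TRUE)
    valid <- NULL
  }
  if (!is.null(expect_dim) && !all(c(h, w) == expect_dim)) {
    stop("flow dimension mismatch: file is ", h, "x", w, ", frames are ",
         expect_dim[1], "x", expect_dim[2])
  }
  flow_field(u, v, valid)
}
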