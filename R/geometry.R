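# 2-D affine algebra. An affine transform is the 6-parameter planar motion
# model
#     [x']   [a11 a12 b1] [x]
#     [y'] = [a21 a22 b2] [y]
#                         [1]
# stored as a 2 x 3 numeric matrix of class "affine". The linear part
# carries scale, shear and rotation; (b1, b2) is the translation in pixels.

#' Construct an affine transform
#'
#' @param a11,a12,a21,a22 linear part (dimensionless).
#' @param b1,b2 translation (pixels).
#' @return An object of class `affine`: a 2 x 3 numeric matrix.
#' @examples
#' A <- affine(1, 0, 0, 1, 5, -2)   # pure translation by (5, -2)
#' affine_apply(A, cbind(0, 0))
#' @export
affine <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1, b1 = 0, b2 = 0) {
  m <- matrix(c(a11, a21, a12, a22, b1, b2), 2, 3)
  stopifnot(all(is.finite(m)))
  structure(m, class = "affine")
}

#' @rdname affine
#' @export
affine_identity <- function() affine()

#' @rdname affine
#' @param tx,ty translation components (pixels).
#' @export
affine_translation <- function(tx, ty) affine(b1 = tx, b2 = ty)

#' Similarity transform about a center point
#'
#' Rotation by `angle` degrees (clockwise in image coordinates, y down),
#' isotropic scaling and translation, applied about `center`.
#'
#' @param angle rotation in degrees.
#' @param scale isotropic scale factor.
#' @param tx,ty translation (pixels).
#' @param center length-2 point the rotation/scaling pivots about.
#' @return An `affine` object.
#' @export
affine_similarity <- function(angle = 0, scale = 1, tx = 0, ty = 0,
                              center = c(0, 0)) {
  th <- angle * pi / 180
  R <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  b <- c(center[1], center[2]) - R %*% c(center[1], center[2]) + c(tx, ty)
  affine(R[1, 1], R[1, 2], R[2, 1], R[2, 2], b[1], b[2])
}

is_affine <- function(x) inherits(x, "affine")

as_affine <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(2, 3)))
  structure(m, class = "affine")
}

# Homogeneous 3x3 form (used internally for composition).
affine_h3 <- function(A) rbind(unclass(A), c(0, 0, 1))

#' Apply an affine transform to points
#'
#' @param A an `affine` transform.
#' @param pts n x 2 matrix of (x, y) coordinates (0-based pixels).
#' @return n x 2 matrix of transformed points.
#' @export
affine_apply <- function(A, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  m <- unclass(A)
  out <- pts %*% t(m[, 1:2])
  out[, 1] <- out[, 1] + m[1, 3]
  out[, 2] <- out[, 2] + m[2, 3]
  out
}

#' Compose two affine transforms
#'
#' `affine_compose(A, B)` applies `B` first, then `A`:
#' `affine_apply(affine_compose(A, B), p) == affine_apply(A, affine_apply(B, p))`.
#'
#' @param A,B `affine` transforms.
#' @return The composed `affine` transform.
#' @export
affine_compose <- function(A, B) {
  M <- affine_h3(A) %*% affine_h3(B)
  as_affine(M[1:2, , drop = FALSE])
}

#' Invert an affine transform
#'
#' @param A an `affine` transform with non-singular linear part.
#' @return The inverse `affine` transform.
#' @export
affine_invert <- function(A) {
  L <- unclass(A)[, 1:2]
  d <- L[1, 1] * L[2, 2] - L[1, 2] * L[2, 1]
  if (!is.finite(d) || abs(d) < 1e-12) {
    stop("degenerate transform: linear part is singular (det = ", d, ")")
  }
  Li <- matrix(c(L[2, 2], -L[2, 1], -L[1, 2], L[1, 1]), 2, 2) / d
  b <- -Li %*% unclass(A)[, 3]
  affine(Li[1, 1], Li[1, 2], Li[2, 1], Li[2, 2], b[1], b[2])
}

#' Serialize / deserialize an affine transform
#'
#' The flat layout is row-major: `c(a11, a12, b1, a21, a22, b2)`, the order
#' used in the transform JSON schema.
#'
#' @param A an `affine` transform.
#' @return `affine_to_vec`: numeric vector of length 6.
#' @export
affine_to_vec <- function(A) {
  m <- unclass(A)
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3])
}

#' @rdname affine_to_vec
#' @param v numeric vector of length 6 in row-major order.
#' @export
affine_from_vec <- function(v) {
  stopifnot(length(v) == 6)
  affine(v[1], v[2], v[4], v[5], v[3], v[6])
}

#' @export
print.affine <- function(x, ...) {
  cat("affine transform [a | b]:\n")
  print(unclass(x))
  invisible(x)
}
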