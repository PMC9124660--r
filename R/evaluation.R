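# Drift evaluation. Ground-truth camera motion is unavailable for in vivo
# fetoscopy, so registration quality is quantified by the structural
# similarity (SSIM) between a frame i and the warped source frame i+t for
# t = 1..N (default N = 5): the warp is built by composing the t pairwise
# transforms, so accumulated drift lowers SSIM as t grows. Distributions
# are summarized as boxplots (median, Q1, Q3, whiskers at 1.5 IQR); low-side
# outliers indicate registration failures.

#' SSIM configuration
#'
#' Standard parameterization: Gaussian-weighted 11 x 11 windows
#' (sigma = 1.5), stabilization constants k1 = 0.01, k2 = 0.03, dynamic
#' range 1 (intensities in `[0, 1]`).
#'
#' @param window odd window size.
#' @param k1,k2 stabilization constants.
#' @param gaussian_sigma window weighting sigma.
#' @param use_overlap_mask restrict scoring to the overlap of the two
#'   frames' valid regions (recommended: the black canvas outside the
#'   fetoscopic circle would otherwise inflate similarity).
#' @return A list of class `ssim_config`.
#' @export
ssim_config <- function(window = 11L, k1 = 0.01, k2 = 0.03,
                        gaussian_sigma = 1.5, use_overlap_mask = TRUE) {
  stopifnot(window >= 3, window %% 2 == 1)
  structure(list(window = as.integer(window), k1 = k1, k2 = k2,
                 gaussian_sigma = gaussian_sigma,
                 use_overlap_mask = isTRUE(use_overlap_mask)),
            class = "ssim_config")
}

#' Structural similarity between two frames
#'
#' Gaussian-weighted local means/variances/covariance, combined per window
#' as `((2 mu_a mu_b + C1)(2 cov + C2)) / ((mu_a^2 + mu_b^2 + C1)
#' (var_a + var_b + C2))` with `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, `L = 1`,
#' averaged over windows whose support lies fully inside `valid` and fully
#' inside the image.
#'
#' @param a,b frames of identical size (color is converted to grayscale).
#' @param valid optional logical matrix restricting scoring.
#' @param cfg an [ssim_config()].
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, valid = NULL, cfg = ssim_config()) {
  a <- as_gray(a); b <- as_gray(b)
  stopifnot(all(dim(a) == dim(b)))
  h <- nrow(a); w <- ncol(a)
  win <- cfg$window
  r <- (win - 1L) %/% 2L
  if (is.null(valid)) valid <- matrix(TRUE, h, w)
  stopifnot(all(dim(valid) == c(h, w)))
  # windows fully inside the valid region ...
  full <- box_sum(valid + 0, win) >= (win * win - 0.5)
  # ... and fully inside the image
  inside <- matrix(FALSE, h, w)
  if (h > 2 * r && w > 2 * r) {
    inside[(r + 1):(h - r), (r + 1):(w - r)] <- TRUE
  }
  sel <- full & inside
  if (!any(sel)) stop("empty valid region: no window fits inside it")
  k <- gauss_kernel(cfg$gaussian_sigma, radius = r)
  mu_a <- conv_sep(a, k); mu_b <- conv_sep(b, k)
  s_aa <- conv_sep(a * a, k) - mu_a^2
  s_bb <- conv_sep(b * b, k) - mu_b^2
  s_ab <- conv_sep(a * b, k) - mu_a * mu_b
  c1 <- (cfg$k1)^2  # dynamic range L = 1
  c2 <- (cfg$k2)^2
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  mean((num / den)[sel])
}

#' Five-number boxplot summary
#'
#' Median, Q1, Q3 (linear-interpolation quantiles), whiskers at the most
#' extreme observations within `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, and the
#' points beyond the whiskers listed as outliers.
#'
#' @param values numeric vector (length >= 1).
#' @return List with `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`, `n`.
#' @export
boxplot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("boxplot_stats: empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}

# Warp frame i+t into frame i's grid through A (mapping i+t -> i) and
# return the warped image plus the overlap validity raster.
warp_into_frame <- function(frame_t, A, mask = NULL) {
  fd <- frame_dim(frame_t)
  canvas <- list(height = fd[1], width = fd[2],
                 origin_offset = affine_translation(0, 0))
  warp_frame(frame_t, A, mask, canvas)
}

#' SSIM drift metric over sliding frame windows
#'
#' For every frame i and offset t in 1..N with i+t inside the sequence,
#' composes the t pairwise transforms, warps frame i+t into frame i's
#' coordinates and scores SSIM over the overlap of the two fields of view.
#'
#' @param frames list of frames.
#' @param pairwise list of length `length(frames) - 1` of [affine()] or
#'   `pairwise_registration` (element k maps frame k+1 into frame k).
#' @param N evaluation window (number of offsets), default 5.
#' @param mask optional [circular_mask()] shared by all frames.
#' @param cfg an [ssim_config()].
#' @return A `drift_report`: list with `records` (data.frame `i`, `t`,
#'   `ssim`) and `summaries` (per-t [boxplot_stats()]).
#' @export
drift_metric <- function(frames, pairwise, N = 5L, mask = NULL,
                         cfg = ssim_config()) {
  n <- length(frames)
  stopifnot(length(pairwise) == n - 1)
  if (n < 2) stop("span too short: need at least 2 frames")
  pw <- lapply(pairwise, function(p)
    if (inherits(p, "pairwise_registration")) p$transform else p)
  N <- min(N, n - 1L)
  recs <- vector("list", 0L)
  for (i in seq_len(n - 1L)) {
    A <- affine_identity()
    for (t in seq_len(min(N, n - i))) {
      A <- affine_compose(A, pw[[i + t - 1L]])
      wp <- warp_into_frame(frames[[i + t]], A, mask)
      valid <- wp$valid
      if (cfg$use_overlap_mask && !is.null(mask)) {
        valid <- valid & mask$raster
      }
      s <- ssim(frames[[i]], wp$image, valid = valid, cfg = cfg)
      recs[[length(recs) + 1L]] <- data.frame(i = i, t = t, ssim = s)
    }
  }
  records <- do.call(rbind, recs)
  summaries <- lapply(split(records$ssim, records$t), boxplot_stats)
  structure(list(records = records, summaries = summaries, N = N),
            class = "drift_report")
}

#' @export
print.drift_report <- function(x, ...) {
  cat("SSIM drift report, N =", x$N, "\n")
  med <- vapply(x$summaries, `[[`, numeric(1), "median")
  for (t in names(x$summaries)) {
    cat(sprintf("  t = %s: median SSIM %.4f (%d outliers)\n", t, med[[t]],
                length(x$summaries[[t]]$outliers)))
  }
  invisible(x)
}

#' Consecutive-frame SSIM time series
#'
#' The t = 1 slice of the drift metric as a function of frame index; dips
#' in the series localize registration failures.
#'
#' @param frames list of frames.
#' @param pairwise pairwise transforms as in [drift_metric()].
#' @param mask optional [circular_mask()].
#' @param cfg an [ssim_config()].
#' @param file optional PNG path; when given, a line plot is written.
#' @return data.frame with columns `i` (pair index) and `ssim`.
#' @export
ssim_timeplot <- function(frames, pairwise, mask = NULL, cfg = ssim_config(),
                          file = NULL) {
  rep <- drift_metric(frames, pairwise, N = 1L, mask = mask, cfg = cfg)
  out <- rep$records[rep$records$t == 1L, c("i", "ssim")]
  rownames(out) <- NULL
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 420)
    on.exit(grDevices::dev.off())
    graphics::plot(out$i, out$ssim, type = "l", col = "red3", lwd = 2,
                   xlab = "frame pair", ylab = "SSIM (t = 1)",
                   ylim = c(min(out$ssim, 0.5), 1),
                   main = "Consecutive-frame registration SSIM")
    graphics::grid()
  }
  out
}

#' Boxplot figure for a drift report
#'
#' @param report a `drift_report`.
#' @param file PNG output path.
#' @return `file`, invisibly.
#' @export
drift_boxplot <- function(report, file) {
  grDevices::png(file, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  graphics::boxplot(ssim ~ t, data = report$records, col = "indianred",
                    xlab = "frame offset t", ylab = "SSIM",
                    main = "SSIM drift over frame offsets")
  invisible(file)
}
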