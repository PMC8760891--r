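# Stage 1: frame-to-frame rigid motion correction (translation-only,
# normalized cross-correlation against an iteratively refined reference) and
# surface-coil intensity correction from proton-density frames.

#' Estimate the surface-coil sensitivity (bias) field from PD frames
#'
#' The field is the heavily low-pass-filtered mean proton-density image,
#' normalized to mean 1 over a robust foreground mask (intensity above the
#' 5th percentile), strictly positive. `smoothing_scale -> Inf` yields a
#' field of exactly 1 everywhere.
#'
#' @param pd_frames a PD-role [dynamic_series()] or a 3-D array of frames.
#' @param smoothing_scale Gaussian sigma in pixels; `NULL` for the adaptive
#'   default, 1/16 of the smaller image dimension.
#' @return `list(field = matrix, smoothing_scale =)` of class `BiasField`.
#' @export
estimate_bias_field <- function(pd_frames, smoothing_scale = NULL) {
  frames <- if (inherits(pd_frames, "DynamicSeries")) pd_frames$frames
            else pd_frames
  img <- apply(frames, c(2, 3), mean)
  if (is.null(smoothing_scale)) smoothing_scale <- min(dim(img)) / 16
  if (all(img == 0))
    pq_error("pq_degenerate_input", "all-zero proton-density frames")
  fg <- img >= stats::quantile(img, 0.05)
  if (!any(fg)) fg <- matrix(TRUE, nrow(img), ncol(img))
  sm <- gaussian_smooth(img, smoothing_scale)
  field <- sm / mean(sm[fg])
  field <- pmax(field, 1e-6)
  structure(list(field = field, smoothing_scale = smoothing_scale),
            class = "BiasField")
}

#' Divide a series by a multiplicative bias field
#'
#' @param series a [dynamic_series()].
#' @param field a `BiasField` (or bare matrix) with matching geometry.
#' @return the corrected series; role and metadata unchanged.
#' @export
apply_bias_correction <- function(series, field) {
  f <- if (inherits(field, "BiasField")) field$field else field
  if (!identical(dim(f), as.integer(frame_dim(series))) &&
      !identical(as.integer(dim(f)), as.integer(frame_dim(series))))
    pq_error("pq_geometry_mismatch", "bias field / series geometry mismatch")
  out <- series
  out$frames <- sweep(series$frames, 2:3, f, "/")
  out
}

# NCC of `frame` against `ref` displaced by integer (u, v); frame is
# hypothesized to be ref translated by (+u, +v). An optional logical mask in
# reference coordinates restricts the metric (e.g. to non-enhancing pixels).
ncc_at <- function(frame, ref, u, v, mask = NULL) {
  nr <- nrow(frame); nc <- ncol(frame)
  r1 <- max(1, 1 + u); r2 <- min(nr, nr + u)
  c1 <- max(1, 1 + v); c2 <- min(nc, nc + v)
  a <- frame[r1:r2, c1:c2]
  b <- ref[(r1 - u):(r2 - u), (c1 - v):(c2 - v)]
  if (!is.null(mask)) {
    m <- mask[(r1 - u):(r2 - u), (c1 - v):(c2 - v)]
    if (sum(m) < 16) return(NA_real_)
    a <- a[m]; b <- b[m]
  }
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

parabolic_offset <- function(l, c0, r) {
  den <- l - 2 * c0 + r
  if (!is.finite(den) || den >= 0) return(0)
  d <- 0.5 * (l - r) / den
  max(min(d, 0.5), -0.5)
}

# Estimate the translation (ty, tx) moving ref into frame; returns the
# subpixel-refined shift and a fallback flag for degenerate frames.
estimate_shift <- function(frame, ref, max_shift, mask = NULL) {
  shifts <- -max_shift:max_shift
  cc <- matrix(NA_real_, length(shifts), length(shifts))
  for (i in seq_along(shifts))
    for (j in seq_along(shifts))
      cc[i, j] <- ncc_at(frame, ref, shifts[i], shifts[j], mask)
  if (all(!is.finite(cc)))
    return(list(ty = 0, tx = 0, fallback = TRUE))
  # infinitesimal zero-shift prior: breaks exact ties (e.g. featureless or
  # noise-free regions) toward no motion without disturbing genuine peaks
  cc <- cc - 1e-6 * outer(shifts^2, shifts^2, "+")
  k <- arrayInd(which.max(cc), dim(cc))
  i <- k[1]; j <- k[2]
  dy <- if (i > 1 && i < nrow(cc) && all(is.finite(cc[(i - 1):(i + 1), j])))
    parabolic_offset(cc[i - 1, j], cc[i, j], cc[i + 1, j]) else 0
  dx <- if (j > 1 && j < ncol(cc) && all(is.finite(cc[i, (j - 1):(j + 1)])))
    parabolic_offset(cc[i, j - 1], cc[i, j], cc[i, j + 1]) else 0
  list(ty = shifts[i] + dy, tx = shifts[j] + dx, fallback = FALSE)
}

#' Rigid in-plane motion correction of a dynamic series
#'
#' Per-frame translation is estimated by maximizing normalized
#' cross-correlation against an iteratively refined reference: the initial
#' reference is the temporal median of mid-enhancement frames (middle tertile
#' of the series-mean curve); each refinement pass re-averages the registered
#' frames into a new reference and re-estimates all shifts from the original
#' frames. Translations are applied with edge-clamped bilinear interpolation.
#'
#' @param series a [dynamic_series()] with >= 3 frames.
#' @param config list; keys `max_shift_px` (search radius, default 5),
#'   `n_reference_passes` (default 2), and the band-pass scales
#'   `bp_sigma_low` / `bp_sigma_high` (default 1 / 6 pixels): shifts are
#'   estimated on difference-of-Gaussians images so that the smooth coil
#'   shading and global enhancement changes do not dominate the metric, and
#'   applied to the original frames.
#' @return `list(series = corrected series, trace = data.frame(frame, dy, dx,
#'   fallback))`; `(dy, dx)` is the correction applied to each frame (the
#'   negated estimated motion).
#' @export
motion_correct <- function(series, config = list()) {
  max_shift <- config$max_shift_px %||% 5
  passes <- config$n_reference_passes %||% 2
  s_lo <- config$bp_sigma_low %||% 1
  s_hi <- config$bp_sigma_high %||% 6
  nf <- n_frames(series)
  if (nf < 3) pq_error("pq_bad_params", "motion correction needs >= 3 frames")
  frames <- series$frames
  bp <- function(img) gaussian_smooth(img, s_lo) - gaussian_smooth(img, s_hi)
  filt <- array(0, dim = dim(frames))
  for (f in seq_len(nf)) filt[f, , ] <- bp(frames[f, , ])

  m <- apply(frames, 1, mean)
  qs <- stats::quantile(m, c(1 / 3, 2 / 3))
  mid <- which(m >= qs[1] & m <= qs[2])
  if (length(mid) < 3) mid <- seq_len(nf)
  ref <- apply(filt[mid, , , drop = FALSE], c(2, 3), stats::median)

  trace <- data.frame(frame = seq_len(nf), dy = 0, dx = 0, fallback = FALSE)
  registered <- frames
  reg_filt <- filt
  blank <- vapply(seq_len(nf), function(f) stats::sd(frames[f, , ]) < 1e-12,
                  TRUE)
  for (pass in seq_len(passes + 1)) {
    for (f in seq_len(nf)) {
      est <- if (blank[f]) list(ty = 0, tx = 0, fallback = TRUE)
        else estimate_shift(filt[f, , ], ref, max_shift)
      trace$dy[f] <- -est$ty
      trace$dx[f] <- -est$tx
      trace$fallback[f] <- est$fallback
      if (est$fallback) {
        registered[f, , ] <- frames[f, , ]
        reg_filt[f, , ] <- filt[f, , ]
      } else {
        registered[f, , ] <- translate_image(frames[f, , ], -est$ty, -est$tx)
        reg_filt[f, , ] <- translate_image(filt[f, , ], -est$ty, -est$tx)
      }
    }
    if (pass <= passes)
      ref <- apply(reg_filt, c(2, 3), mean)
  }
  # gauge fixing: the composite reference's absolute position is
  # unobservable, so anchor the series at its median position (zero-median
  # trace); the frame at the median displacement gets correction ~(0, 0)
  ok <- !trace$fallback
  if (any(ok)) {
    trace$dy[ok] <- trace$dy[ok] - stats::median(trace$dy[ok])
    trace$dx[ok] <- trace$dx[ok] - stats::median(trace$dx[ok])
  }
  # deadband: corrections below the estimator's jitter floor are zeroed so a
  # motion-free series is passed through without any resampling loss
  dead <- config$deadband_px %||% 0.25
  small <- ok & abs(trace$dy) < dead & abs(trace$dx) < dead
  trace$dy[small] <- 0
  trace$dx[small] <- 0
  for (f in seq_len(nf)) {
    registered[f, , ] <- if (trace$fallback[f] ||
                             (trace$dy[f] == 0 && trace$dx[f] == 0))
      frames[f, , ]
      else translate_image(frames[f, , ], trace$dy[f], trace$dx[f])
  }
  out <- series
  out$frames <- registered
  list(series = out, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
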