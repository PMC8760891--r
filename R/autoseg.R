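# Stages 2-3: automatic AIF blood-pool detection, myocardial ROI detection,
# first-pass timing-point detection, and angular sectorization.

#' A time-signal intensity curve
#'
#' @param t seconds, strictly increasing.
#' @param y signal units, same length.
#' @param provenance `"AIF"`, `"pixel"` or `"sector"`.
#' @return list of class `SignalCurve`.
#' @export
signal_curve <- function(t, y, provenance = c("AIF", "pixel", "sector")) {
  provenance <- match.arg(provenance)
  if (length(t) != length(y))
    pq_error("pq_bad_params", "t and y lengths differ")
  if (length(t) > 1 && any(diff(t) <= 0))
    pq_error("pq_bad_params", "t must be strictly increasing")
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 provenance = provenance), class = "SignalCurve")
}

# centered 3-point moving average (ends use shorter windows); linear in y
ma3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  out <- y
  out[2:(n - 1)] <- (y[1:(n - 2)] + y[2:(n - 1)] + y[3:n]) / 3
  out[1] <- (y[1] + y[2]) / 2
  out[n] <- (y[n - 1] + y[n]) / 2
  out
}

#' Detect first-pass contrast timing points on a signal curve
#'
#' Baseline statistics come from the first `baseline_n` frames. The foot is
#' the last frame before the signal first exceeds baseline mean + 3 SD
#' sustained for 2 frames; the peak is the maximum after the foot; the
#' first-pass end is the first local minimum after the peak (on a lightly
#' smoothed curve), else the frame where the signal falls below baseline +
#' 50% of (peak - baseline), else the series end. Invariant to affine
#' intensity rescaling `y -> a*y + b`, `a > 0`.
#'
#' @param curve a [signal_curve()] (or list with `t`, `y`).
#' @param baseline_n number of pre-contrast baseline frames.
#' @return list of class `TimingPoints` with 1-based `foot_index`,
#'   `peak_index`, `end_index`, plus baseline mean/SD.
#' @export
detect_timing <- function(curve, baseline_n = 4) {
  y <- curve$y
  n <- length(y)
  if (baseline_n < 1 || baseline_n >= n)
    pq_error("pq_bad_params", "baseline_n out of range")
  base <- mean(y[seq_len(baseline_n)])
  bsd <- stats::sd(y[seq_len(baseline_n)])
  thr <- base + 3 * bsd
  above <- y > thr
  rise <- which(above[-n] & above[-1])     # sustained for 2 frames
  rise <- rise[rise > baseline_n - 1]
  if (!length(rise))
    pq_error("pq_timing_failure", "no suprathreshold contrast enhancement")
  foot <- max(rise[1] - 1L, 1L)
  peak <- foot + which.max(y[(foot + 1):n])
  ys <- ma3(y)
  end <- NA_integer_
  if (peak + 2 <= n - 1) {
    for (i in (peak + 2):(n - 1)) {
      if (ys[i] <= ys[i - 1] && ys[i] < ys[i + 1]) { end <- i; break }
    }
  }
  if (is.na(end)) {
    half <- base + 0.5 * (y[peak] - base)
    below <- which(y < half)
    below <- below[below > peak]
    end <- if (length(below)) below[1] else n
  }
  end <- max(end, peak)
  structure(list(foot_index = foot, peak_index = peak, end_index = end,
                 baseline_mean = base, baseline_sd = bsd),
            class = "TimingPoints")
}

# Per-pixel enhancement features on a lightly smoothed series:
# baseline mean/SD, peak enhancement amplitude, 50%-crossing arrival frame.
pixel_features <- function(frames, baseline_n) {
  nf <- dim(frames)[1]
  Y <- matrix(frames, nrow = nf)          # frames x pixels
  Ys <- apply(Y, 2, ma3)
  base <- colMeans(Y[seq_len(baseline_n), , drop = FALSE])
  bsd <- apply(Y[seq_len(baseline_n), , drop = FALSE], 2, stats::sd)
  amp <- apply(Ys, 2, max) - base
  arrival <- vapply(seq_len(ncol(Ys)), function(j) {
    i <- which(Ys[, j] > base[j] + 0.5 * amp[j])
    if (length(i)) i[1] else nf
  }, 0L)
  upslope <- apply(diff(Ys), 2, max)
  list(base = base, bsd = bsd, amp = amp, arrival = arrival,
       upslope = upslope, noise = stats::median(bsd))
}

#' Detect the LV blood pool on the AIF series and extract its curve
#'
#' Bright-enhancing candidate regions are found from per-pixel features (peak
#' amplitude, upslope, arrival); among the two largest connected components
#' the LV is the one with the LATER arrival (the RV enhances first). The
#' curve is the frame-wise mean over a 1-pixel-eroded mask.
#'
#' @param aif_series motion/bias-corrected AIF-role [dynamic_series()].
#' @param baseline_n pre-contrast frames for baseline statistics.
#' @return `list(mask = logical matrix, curve = SignalCurve)`.
#' @export
detect_aif_roi <- function(aif_series, baseline_n = 4) {
  frames <- aif_series$frames
  d <- dim(frames)[2:3]
  ft <- pixel_features(frames, baseline_n)
  if (max(ft$amp) <= 8 * ft$noise + 1e-9)
    pq_error("pq_detection_failure", "no contrast enhancement in AIF series")
  cand <- matrix(ft$amp > 0.5 * max(ft$amp) & ft$amp > 5 * ft$noise, d[1], d[2])
  lab <- label_components(cand)
  sizes <- tabulate(lab)
  comps <- order(sizes, decreasing = TRUE)
  comps <- comps[sizes[comps] >= 4]
  if (!length(comps))
    pq_error("pq_detection_failure", "no candidate blood-pool component")
  if (length(comps) < 2) {
    warning("single blood-pool candidate; cannot disambiguate LV from RV")
    pick <- comps[1]
  } else {
    two <- comps[1:2]
    arr <- vapply(two, function(k) stats::median(ft$arrival[lab == k]), 0)
    pick <- two[which.max(arr)]
  }
  mask <- lab == pick
  er <- morph(mask, 1, "erode")
  if (!any(er)) er <- mask
  y <- apply(frames, 1, function(f) mean(f[er]))
  list(mask = mask,
       curve = signal_curve(series_times(aif_series), y, "AIF"))
}

#' Detect the myocardial annulus and LV center on a myocardial series
#'
#' The LV cavity is localized as the compact region with the earliest large
#' enhancement; the myocardium is the ring of moderately, later-enhancing
#' pixels around it, after morphological closing, that surrounds the cavity
#' boundary. Detection is invariant to a global intensity scale.
#'
#' @param myo_series corrected MYO-role [dynamic_series()].
#' @param baseline_n pre-contrast frames for baseline statistics.
#' @return `list(mask = logical annulus, lv_center = c(row, col),
#'   cavity_mask = logical)`.
#' @export
detect_myocardium <- function(myo_series, baseline_n = 4) {
  frames <- myo_series$frames
  d <- dim(frames)[2:3]
  ft <- pixel_features(frames, baseline_n)
  if (max(ft$amp) <= 8 * ft$noise + 1e-9)
    pq_error("pq_detection_failure", "no contrast enhancement in series",
             cavity_found = FALSE, candidate_count = 0L)
  amp <- matrix(ft$amp, d[1], d[2])
  arrival <- matrix(ft$arrival, d[1], d[2])

  bright <- amp > 0.5 * max(amp)
  lab <- label_components(bright)
  sizes <- tabulate(lab)
  big <- which(sizes >= 9)
  if (!length(big))
    pq_error("pq_detection_failure", "no compact early-enhancing cavity",
             cavity_found = FALSE, candidate_count = 0L)
  arr <- vapply(big, function(k) stats::median(arrival[lab == k]), 0)
  cavity <- lab == big[which.min(arr)]
  idx <- which(cavity, arr.ind = TRUE)
  center <- c(mean(idx[, 1]), mean(idx[, 2]))
  cav_r <- sqrt(sum(cavity) / pi)
  cav_arrival <- stats::median(arrival[cavity])

  thr <- max(4 * ft$noise, 0.015 * max(amp))
  dd <- sqrt(outer((seq_len(d[1]) - center[1])^2,
                   (seq_len(d[2]) - center[2])^2, "+"))
  cand <- amp > thr & arrival >= cav_arrival + 1 &
    !morph(cavity, 2, "dilate") & dd <= 3.5 * cav_r & dd >= cav_r * 0.8
  cand <- morph_close(cand, 2) & !morph(cavity, 1, "dilate")
  lab2 <- label_components(cand)
  ring_zone <- morph(cavity, 3, "dilate") & !cavity
  ncand <- max(lab2)
  best <- 0L; best_overlap <- 0L
  for (k in seq_len(ncand)) {
    ov <- sum(lab2 == k & ring_zone)
    if (ov > best_overlap) { best <- k; best_overlap <- ov }
  }
  if (best == 0L)
    pq_error("pq_detection_failure",
             "no annular myocardial component around the cavity",
             cavity_found = TRUE, candidate_count = ncand)
  mask <- lab2 == best
  # annularity: angular coverage about the center must be near-complete
  ang <- pixel_angles(d[1], d[2], center)
  bins <- unique(floor((ang[mask] + pi) / (2 * pi / 24)))
  if (length(bins) < 20)
    pq_error("pq_detection_failure",
             sprintf("candidate ring covers only %d/24 angular bins",
                     length(bins)),
             cavity_found = TRUE, candidate_count = ncand)
  list(mask = mask, lv_center = center, cavity_mask = cavity)
}

#' Divide a myocardial mask into transmural angular sectors
#'
#' Pixels are labeled `1..n_sectors` by the angle of `(pixel - lv_center)`
#' measured counterclockwise from `reference_angle` (image angle, radians;
#' the default `pi/2` points straight up, the anterior wall in standard
#' short-axis orientation). Labels partition the mask exactly.
#'
#' @param myocardium_mask logical matrix.
#' @param lv_center `c(row, col)`.
#' @param reference_angle radians; sector 1 starts here.
#' @param n_sectors number of equal angular bins (default 6).
#' @return integer label matrix (0 outside the mask).
#' @export
sectorize <- function(myocardium_mask, lv_center, reference_angle = pi / 2,
                      n_sectors = 6) {
  d <- dim(myocardium_mask)
  if (lv_center[1] < 1 || lv_center[1] > d[1] ||
      lv_center[2] < 1 || lv_center[2] > d[2])
    pq_error("pq_bad_params", "lv_center lies outside the image")
  if (n_sectors < 1) pq_error("pq_bad_params", "n_sectors must be >= 1")
  ang <- pixel_angles(d[1], d[2], lv_center)
  rel <- (ang - reference_angle) %% (2 * pi)
  lab <- matrix(0L, d[1], d[2])
  lab[myocardium_mask] <-
    pmin(floor(rel[myocardium_mask] / (2 * pi / n_sectors)), n_sectors - 1) + 1L
  lab
}
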