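# Stages 4-5: curve normalization, pixel-wise Fermi-constrained deconvolution
# to MBF, MPR maps, 18-segment / 9-territory tables and relative measures.

SLICE_NAMES <- c("basal", "mid", "apical")
SECTOR_NAMES <- c("Anterior", "Anteroseptal", "Inferoseptal",
                  "Inferior", "Inferolateral", "Anterolateral")
# coronary territory of each sector; adjacent sector pairs (1,2), (3,4),
# (5,6) reduce to the LAD / RCA / CX groupings at every slice level
SECTOR_VESSEL <- c("LAD", "LAD", "RCA", "RCA", "CX", "CX")

#' Baseline-subtract and crop curves to the first pass
#'
#' `c = y - mean(y[1:baseline_n])`, applied identically to AIF and tissue;
#' curves are cropped to `[foot - 2 frames, end of first pass]` using the AIF
#' timing points.
#'
#' @param x a [signal_curve()] or a [dynamic_series()] (then all pixel curves
#'   are normalized at once).
#' @param timing AIF [detect_timing()] result.
#' @param baseline_n baseline frames; must be `< foot_index`.
#' @return for a curve: `list(t, c, baseline_value)` of class
#'   `NormalizedCurve`; for a series: `list(t, c = matrix[frames x pixels],
#'   baseline_value = vector, dim)`.
#' @export
normalize_curves <- function(x, timing, baseline_n = 4) {
  if (baseline_n >= timing$foot_index)
    pq_error("pq_bad_params",
             "baseline window reaches past the contrast foot (contaminated)")
  i0 <- max(1L, timing$foot_index - 2L)
  i1 <- timing$end_index
  if (inherits(x, "DynamicSeries")) {
    nf <- dim(x$frames)[1]
    Y <- matrix(x$frames, nrow = nf)
    base <- colMeans(Y[seq_len(baseline_n), , drop = FALSE])
    C <- sweep(Y, 2, base)[i0:i1, , drop = FALSE]
    list(t = series_times(x)[i0:i1], c = C, baseline_value = base,
         dim = dim(x$frames)[2:3])
  } else {
    base <- mean(x$y[seq_len(baseline_n)])
    structure(list(t = x$t[i0:i1], c = (x$y - base)[i0:i1],
                   baseline_value = base),
              class = "NormalizedCurve")
  }
}

# sparse-free linear interpolation operator rows: t_out, cols: t_in
interp_matrix <- function(t_in, t_out) {
  W <- matrix(0, length(t_out), length(t_in))
  for (i in seq_along(t_out)) {
    to <- t_out[i]
    j <- findInterval(to, t_in, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(t_in) - 1L)
    a <- (to - t_in[j]) / (t_in[j + 1] - t_in[j])
    W[i, j] <- 1 - a
    W[i, j + 1] <- a
  }
  W
}

#' Resample a normalized curve onto a uniform grid
#'
#' Linear interpolation; the grid starts at the first sample and uses spacing
#' `dt` across the cropped window.
#'
#' @param curve a `NormalizedCurve` (list with `t`, `c`).
#' @param dt grid spacing, s (> 0).
#' @return a `NormalizedCurve` on the uniform grid.
#' @export
resample_uniform <- function(curve, dt) {
  if (dt <= 0) pq_error("pq_bad_params", "dt must be > 0")
  t_out <- curve$t[1] + dt * seq(0, floor((curve$t[length(curve$t)] -
                                             curve$t[1]) / dt + 1e-9))
  structure(list(t = t_out,
                 c = stats::approx(curve$t, curve$c, xout = t_out)$y,
                 baseline_value = curve$baseline_value),
            class = "NormalizedCurve")
}

default_fermi_bounds <- function() {
  list(F = c(0, 10), k = c(1e-3, 5), w = c(0, 30), tau_d = c(0, 10))
}

# Convolution basis for a unit-amplitude Fermi residue; tissue_hat = F * basis.
# The 60 s/min conversion enters here so the fitted F carries ml/g/min.
fermi_basis <- function(theta, aif, dt) {
  tgrid <- dt * (seq_along(aif) - 1)
  irf <- fermi_irf(fermi_irf_params(1, theta[1], theta[2], theta[3]), tgrid)
  synthesize_tissue_curve(aif, irf / 60, dt)
}

#' Fermi-constrained deconvolution of one tissue curve
#'
#' Minimizes the residual between the tissue curve and
#' `dt * conv(aif, Fermi(F, k, w, tau_d) / 60)` by bounded nonlinear least
#' squares with the amplitude `F` profiled analytically (the model is linear
#' in `F`). The causality cutoff at `tau_d` makes the objective discontinuous
#' where `tau_d` crosses a sample time, so the delay is handled by a
#' deterministic grid scan (initialized from the AIF-to-tissue foot delay):
#' at each candidate delay a `(k, w)` grid is scanned and the best slices are
#' refined by L-BFGS-B; a final joint polish keeps `tau_d` inside its smooth
#' inter-sample interval. MBF is the impulse-response value at the delay,
#' `F / (1 + exp(-k*w))`, in ml/g/min.
#'
#' @param aif,tissue `NormalizedCurve`s on the same uniform grid.
#' @param bounds parameter box, see `default_fermi_bounds()`.
#' @param n_starts `(k, w)` grid initializations scanned per delay candidate
#'   (a 3x3 grid by default).
#' @param tau0 delay initialization, s (AIF-to-tissue foot delay); estimated
#'   from the curves when `NULL`.
#' @param cache optional environment for memoizing scan-stage basis curves
#'   across pixels of one map.
#' @return list of class `FermiFit`: `params`, `mbf`, `residual_rms`,
#'   `converged`.
#' @export
fermi_deconvolve <- function(aif, tissue, bounds = default_fermi_bounds(),
                             n_starts = 9, tau0 = NULL, cache = NULL) {
  a <- aif$c; y <- tissue$c
  if (length(a) != length(y) ||
      max(abs(aif$t - tissue$t)) > 1e-6 * max(1, diff(range(aif$t))))
    pq_error("pq_grid_mismatch", "aif and tissue must share one uniform grid")
  if (!all(is.finite(a)) || !all(is.finite(y)))
    pq_error("pq_bad_params", "non-finite input curves")
  if (max(a) <= 0) pq_error("pq_bad_params", "AIF peak must be > 0")
  dt <- aif$t[2] - aif$t[1]
  n <- length(a)

  if (is.null(tau0)) {
    foot_of <- function(v) {
      i <- which(v > 0.1 * max(v, 0))
      if (length(i)) i[1] else 1L
    }
    tau0 <- max(0, dt * (foot_of(y) - foot_of(a)))
  }
  clamp_tau <- function(x) min(max(x, bounds$tau_d[1]), bounds$tau_d[2])
  tau0 <- clamp_tau(tau0)

  profile_F <- function(b) {
    den <- sum(b * b)
    if (den <= 0) return(0)
    min(max(sum(y * b) / den, bounds$F[1]), bounds$F[2])
  }
  obj3 <- function(theta) {
    b <- fermi_basis(theta, a, dt)
    sum((y - profile_F(b) * b)^2)
  }

  # The objective is smooth in (k, w, tau_d) only while tau_d stays strictly
  # inside one inter-sample interval (m*dt, (m+1)*dt]: optimize per window.
  # Within a window it is exactly flat along (tau_d + d, w - d) — sub-sample
  # delay is unidentifiable from beat-sampled curves — so the fitted delay is
  # snapped to the top of its flat interval (delay in whole samples).
  m_lo <- max(0L, floor(clamp_tau(tau0 - 2 * dt) / dt))
  m_hi <- floor(clamp_tau(tau0 + 2 * dt) / dt)
  windows <- m_lo:m_hi
  kg <- c(0.2, 0.8, 2.0); wg <- c(1, 4, 10)
  grid <- expand.grid(k = kg, w = wg)
  grid <- grid[seq_len(min(n_starts, nrow(grid))), , drop = FALSE]

  scan_basis <- function(k, w, tau) {
    if (!is.null(cache)) {
      key <- sprintf("%g_%g_%g_%d", k, w, tau, n)
      b <- cache[[key]]
      if (is.null(b)) {
        b <- fermi_basis(c(k, w, tau), a, dt)
        cache[[key]] <- b
      }
      b
    } else fermi_basis(c(k, w, tau), a, dt)
  }

  # stage 1: profile-amplitude scan of the (k, w) grid at each window center
  scan <- expand.grid(i = seq_len(nrow(grid)), m = windows)
  scan$tau <- clamp_tau((scan$m + 0.5) * dt)
  scan$rss <- vapply(seq_len(nrow(scan)), function(r) {
    b <- scan_basis(grid$k[scan$i[r]], grid$w[scan$i[r]], scan$tau[r])
    sum((y - profile_F(b) * b)^2)
  }, 0)

  # stage 2: within the best two windows, bounded joint refinement from the
  # best two (k, w) grid starts each
  win_best <- tapply(scan$rss, scan$m, min)
  top <- as.integer(names(sort(win_best)[seq_len(min(2, length(win_best)))]))
  best <- list(value = Inf, par = NULL, conv = FALSE)
  for (m in top) {
    tlo <- max(bounds$tau_d[1], m * dt + 1e-6)
    thi <- min(bounds$tau_d[2], (m + 1) * dt - 1e-6)
    if (thi < tlo) next
    rows <- scan[scan$m == m, ]
    for (i in rows$i[order(rows$rss)][1:2]) {
      th0 <- c(grid$k[i], grid$w[i], min(max(rows$tau[1], tlo), thi))
      fit <- tryCatch(
        stats::optim(th0, obj3, method = "L-BFGS-B",
                     lower = c(bounds$k[1], bounds$w[1], tlo),
                     upper = c(bounds$k[2], bounds$w[2], thi),
                     control = list(maxit = 60)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < best$value) {
        # snap tau_d up the flat ridge to the next sample time, keeping the
        # onset-plus-width sum (the identified quantity) fixed
        s <- fit$par[2] + fit$par[3]
        tau_snap <- min((m + 1) * dt, bounds$tau_d[2], s)
        best <- list(value = fit$value,
                     par = c(fit$par[1], max(s - tau_snap, 0), tau_snap),
                     conv = fit$convergence %in% c(0, 1))
      }
    }
  }
  # tau_d at the lower bound (typically 0) is the top of a window that lies
  # outside the box and is unreachable by the snap: fit it explicitly.
  if (m_lo == 0L && bounds$tau_d[1] < dt) {
    tau_fix <- bounds$tau_d[1]
    rows <- scan[scan$m == windows[1], ]
    for (i in rows$i[order(rows$rss)][1:2]) {
      fit <- tryCatch(
        stats::optim(c(grid$k[i], grid$w[i]),
                     function(p) obj3(c(p, tau_fix)),
                     method = "L-BFGS-B",
                     lower = c(bounds$k[1], bounds$w[1]),
                     upper = c(bounds$k[2], bounds$w[2]),
                     control = list(maxit = 60)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < best$value)
        best <- list(value = fit$value, par = c(fit$par, tau_fix),
                     conv = fit$convergence %in% c(0, 1))
    }
  }
  if (is.null(best$par)) {
    return(structure(list(params = NULL, mbf = NA_real_,
                          residual_rms = NA_real_, converged = FALSE),
                     class = "FermiFit"))
  }

  b <- fermi_basis(best$par, a, dt)
  F <- profile_F(b)
  params <- fermi_irf_params(F, best$par[1], best$par[2], best$par[3])
  structure(list(params = params, mbf = fermi_mbf(params),
                 residual_rms = sqrt(best$value / n),
                 converged = best$conv),
            class = "FermiFit")
}

#' Pixel-wise MBF map of one slice
#'
#' Applies [fermi_deconvolve()] to every masked pixel of a corrected
#' myocardial series against the detected AIF curve. Pixels are independent:
#' the result does not depend on processing order. Failed fits are flagged
#' and carry `NA`.
#'
#' @param myo_series corrected MYO-role [dynamic_series()].
#' @param mask logical myocardium mask.
#' @param aif_curve the detected AIF [signal_curve()].
#' @param timing AIF [detect_timing()] result.
#' @param slice_index,condition map identity.
#' @param config list: `baseline_n`, `dt` (resampling step, default median
#'   frame spacing), `bounds`, `n_starts`.
#' @return an [mbf_map()].
#' @export
compute_slice_mbf <- function(myo_series, mask, aif_curve, timing,
                              slice_index, condition, config = list()) {
  baseline_n <- config$baseline_n %||% 4
  dt <- config$dt %||% stats::median(diff(aif_curve$t))
  bounds <- config$bounds %||% default_fermi_bounds()
  n_starts <- config$n_starts %||% 9

  aif_n <- resample_uniform(normalize_curves(aif_curve, timing, baseline_n), dt)
  ser_n <- normalize_curves(myo_series, timing, baseline_n)
  W <- interp_matrix(ser_n$t, aif_n$t)
  C <- W %*% ser_n$c                       # uniform-grid pixel curves

  d <- frame_dim(myo_series)
  values <- matrix(NA_real_, d[1], d[2])
  failed <- matrix(FALSE, d[1], d[2])
  cache <- new.env(parent = emptyenv())
  px <- which(mask)
  for (p in px) {
    tis <- structure(list(t = aif_n$t, c = C[, p]), class = "NormalizedCurve")
    fit <- tryCatch(
      fermi_deconvolve(aif_n, tis, bounds = bounds, n_starts = n_starts,
                       cache = cache),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$mbf)) {
      failed[p] <- TRUE
    } else {
      values[p] <- fit$mbf
      failed[p] <- !fit$converged
    }
  }
  mbf_map(values, mask, slice_index, condition, failed = failed)
}

#' MBF maps for every slice and condition of a corrected study
#'
#' @param study corrected [perfusion_study()].
#' @param rois per-condition detection results: `rois[[cond]]$aif` from
#'   [detect_aif_roi()], `rois[[cond]]$myo[[slice]]` from
#'   [detect_myocardium()].
#' @param timing per-condition AIF [detect_timing()] results.
#' @param config see [compute_slice_mbf()].
#' @return nested list `maps[[condition]][[slice]]` of [mbf_map()]s.
#' @export
compute_mbf_map <- function(study, rois, timing, config = list()) {
  maps <- list()
  for (cond in names(study$conditions)) {
    maps[[cond]] <- lapply(1:3, function(sl) {
      compute_slice_mbf(study$conditions[[cond]]$myo[[sl]],
                        rois[[cond]]$myo[[sl]]$mask,
                        rois[[cond]]$aif$curve, timing[[cond]],
                        slice_index = sl - 1L, condition = cond,
                        config = config)
    })
  }
  maps
}

#' Myocardial perfusion reserve: stress / rest
#'
#' Elementwise for maps/matrices, scalar for scalars; `NaN` (flagged, no
#' error) where rest <= 0 or either input is invalid.
#'
#' @param stress,rest values, matrices, or [mbf_map()]s of matching shape.
#' @return same shape as the inputs; for maps, a list with `values` and the
#'   intersected `mask`.
#' @export
compute_mpr <- function(stress, rest) {
  if (inherits(stress, "MBFMap") && inherits(rest, "MBFMap")) {
    if (!identical(dim(stress$values), dim(rest$values)))
      pq_error("pq_geometry_mismatch", "stress / rest map shapes differ")
    v <- compute_mpr(stress$values, rest$values)
    return(structure(list(values = v, mask = stress$mask & rest$mask,
                          slice_index = stress$slice_index),
                     class = "MPRMap"))
  }
  if (is.matrix(stress) != is.matrix(rest) ||
      (is.matrix(stress) && !identical(dim(stress), dim(rest))) ||
      (!is.matrix(stress) && length(stress) != length(rest)))
    pq_error("pq_geometry_mismatch", "stress / rest shapes differ")
  out <- stress / rest
  out[!is.finite(rest) | rest <= 0 | !is.finite(stress)] <- NaN
  out
}

segment_mean <- function(map, labels, sector) {
  sel <- map$mask & !map$failed & labels == sector
  if (!sum(sel)) {
    warning(sprintf("empty sector %d on %s slice %d", sector,
                    map$condition, map$slice_index))
    return(NaN)
  }
  mean(map$values[sel], na.rm = TRUE)
}

#' 18-segment and 9-territory summary table
#'
#' Segment value = mean of masked pixels in each of 6 transmural sectors per
#' slice; territory value = mean of its 2 adjacent segments, named by
#' coronary artery (LAD: anterior + anteroseptal; RCA: inferior +
#' inferoseptal; CX: anterolateral + inferolateral, at every slice level),
#' for 9 territories per patient. MPR = stress / rest per segment.
#'
#' @param maps nested list `maps[[condition]][[slice]]` ([compute_mbf_map()]);
#'   `stress` required, `rest` optional.
#' @param sector_labels `sector_labels[[condition]][[slice]]` label matrices
#'   from [sectorize()] (or one shared per-slice list).
#' @param erode_px rim width (pixels) excluded from the measurement mask to
#'   guard segment statistics against partial-volume contamination at the
#'   endo/epicardial borders; 0 disables.
#' @return list of class `SegmentTable`: `segments` (18 rows), `territories`
#'   (9 rows, with `rmbf`/`rmpr` filled by [relative_measures()]).
#' @export
segment_table <- function(maps, sector_labels, erode_px = 1) {
  conds <- names(maps)
  if (erode_px > 0) {
    for (cond in conds) for (sl in seq_along(maps[[cond]])) {
      er <- morph(maps[[cond]][[sl]]$mask, erode_px, "erode")
      if (sum(er) >= 30) maps[[cond]][[sl]]$mask <- er
    }
  }
  labs_for <- function(cond) {
    if (!is.null(names(sector_labels)) && cond %in% names(sector_labels))
      sector_labels[[cond]] else sector_labels
  }
  seg <- expand.grid(sector = 1:6, slice = SLICE_NAMES,
                     stringsAsFactors = FALSE)[, 2:1]
  seg$segment <- SECTOR_NAMES[seg$sector]
  seg$vessel <- SECTOR_VESSEL[seg$sector]
  seg$stress_mbf <- NA_real_; seg$rest_mbf <- NA_real_
  for (i in seq_len(nrow(seg))) {
    sl <- match(seg$slice[i], SLICE_NAMES)
    for (cond in conds) {
      v <- segment_mean(maps[[cond]][[sl]], labs_for(cond)[[sl]],
                        seg$sector[i])
      seg[[paste0(cond, "_mbf")]][i] <- v
    }
  }
  seg$mpr <- ifelse(is.finite(seg$rest_mbf) & seg$rest_mbf > 0,
                    seg$stress_mbf / seg$rest_mbf, NaN)

  terr <- expand.grid(vessel = c("LAD", "RCA", "CX"), slice = SLICE_NAMES,
                      stringsAsFactors = FALSE)[, 2:1]
  pair_mean <- function(v) mean(v)        # both adjacent segments, NaN kept
  for (col in c("stress_mbf", "rest_mbf", "mpr"))
    terr[[col]] <- vapply(seq_len(nrow(terr)), function(i) {
      sel <- seg$slice == terr$slice[i] & seg$vessel == terr$vessel[i]
      pair_mean(seg[[col]][sel])
    }, 0)
  terr$territory <- paste(terr$slice, terr$vessel, sep = "-")
  structure(list(segments = seg, territories = terr), class = "SegmentTable")
}

#' Relative perfusion measures per territory
#'
#' The reference "remote" territory is the one with the most normal (maximal)
#' hyperemic flow, i.e. the argmax of territory stress MBF. `rmbf_i = stress
#' MBF_i / stress MBF_ref`; `rmpr` analogously with MPR (same reference
#' territory). The reference's own values are 1.
#'
#' @param territories the `territories` data.frame of a [segment_table()]
#'   (or a SegmentTable).
#' @return the data.frame with `rmbf`, `rmpr` columns added.
#' @export
relative_measures <- function(territories) {
  terr <- if (inherits(territories, "SegmentTable"))
    territories$territories else territories
  ok <- is.finite(terr$stress_mbf)
  if (sum(ok) < 2)
    pq_error("pq_degenerate_input",
             "need >= 2 valid territories for relative measures")
  ref <- which(ok)[which.max(terr$stress_mbf[ok])]
  terr$rmbf <- terr$stress_mbf / terr$stress_mbf[ref]
  terr$rmpr <- if (is.finite(terr$mpr[ref]) && terr$mpr[ref] > 0)
    terr$mpr / terr$mpr[ref] else NaN
  terr$reference <- seq_len(nrow(terr)) == ref
  terr
}

#' Per-patient and per-vessel minima of the four diagnostic metrics
#'
#' Patient summary = minimum over all 9 territories; vessel summary = minimum
#' over that vessel's 3 territories. `NaN` territories are ignored unless all
#' are `NaN`. Metrics: `mbf` (stress MBF), `mpr`, `rmbf`, `rmpr`.
#'
#' @param territories output of [relative_measures()] (or a SegmentTable with
#'   those columns).
#' @return `list(patient = named numeric, vessel = data.frame)`.
#' @export
patient_vessel_summary <- function(territories) {
  terr <- if (inherits(territories, "SegmentTable"))
    territories$territories else territories
  cols <- c(mbf = "stress_mbf", mpr = "mpr", rmbf = "rmbf", rmpr = "rmpr")
  safe_min <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NaN else min(v)
  }
  patient <- vapply(cols, function(cl) safe_min(terr[[cl]]), 0)
  vessel <- do.call(rbind, lapply(c("LAD", "RCA", "CX"), function(vs) {
    sel <- terr$vessel == vs
    data.frame(vessel = vs, t(vapply(cols, function(cl)
      safe_min(terr[[cl]][sel]), 0)))
  }))
  list(patient = patient, vessel = vessel)
}
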