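# Synthetic dual-sequence perfusion phantom. Emulates the acquisition the
# pipeline targets: a low-resolution AIF series plus 3 myocardial short-axis
# slices per heartbeat for ~60 beats and 2 proton-density frames per slice,
# with gamma-variate first-pass enhancement, sector-wise ground-truth MBF,
# smooth multiplicative coil shading, per-frame rigid motion and additive
# Gaussian noise. Every pipeline stage is testable against the returned
# ground truth without any image download.

#' Gamma-variate bolus parameters
#'
#' The primary bolus is `A * ((t-t0)/(alpha*beta))^alpha *
#' exp(alpha - (t-t0)/beta)` for `t > t0` (peak value `A` at
#' `t0 + alpha*beta`), plus an optional recirculation term of the same shape,
#' delayed and scaled.
#'
#' @param amplitude peak signal amplitude `A`.
#' @param t0 bolus arrival (onset) time, s.
#' @param alpha shape (> 0), dimensionless.
#' @param beta scale (> 0), s.
#' @param recirculation_fraction fraction of `A` recirculating, in `[0, 1)`.
#' @param recirculation_delay delay of the recirculation bolus, s.
#' @return parameter list of class `GammaVariateParams`.
#' @export
gamma_variate_params <- function(amplitude = 1, t0 = 8, alpha = 2.5,
                                 beta = 1.5, recirculation_fraction = 0.15,
                                 recirculation_delay = 12) {
  if (alpha <= 0 || beta <= 0)
    pq_error("pq_bad_params", "gamma-variate alpha and beta must be > 0")
  if (recirculation_fraction < 0 || recirculation_fraction >= 1)
    pq_error("pq_bad_params", "recirculation_fraction must be in [0, 1)")
  structure(list(amplitude = amplitude, t0 = t0, alpha = alpha, beta = beta,
                 recirculation_fraction = recirculation_fraction,
                 recirculation_delay = recirculation_delay),
            class = "GammaVariateParams")
}

#' Evaluate a gamma-variate bolus curve
#'
#' @param params a [gamma_variate_params()].
#' @param tgrid nondecreasing time grid, s.
#' @return signal-unit curve; exactly 0 for `t <= t0`, primary peak equals
#'   `amplitude`.
#' @export
gamma_variate <- function(params, tgrid) {
  if (is.unsorted(tgrid)) pq_error("pq_bad_params", "tgrid must be nondecreasing")
  one <- function(t0) {
    s <- (tgrid - t0) / (params$alpha * params$beta)
    y <- ifelse(tgrid > t0,
                s^params$alpha * exp(params$alpha - (tgrid - t0) / params$beta),
                0)
    y
  }
  y <- one(params$t0)
  if (params$recirculation_fraction > 0)
    y <- y + params$recirculation_fraction *
      one(params$t0 + params$recirculation_delay)
  params$amplitude * y
}

#' Fermi impulse-response parameters
#'
#' Delayed logistic decay `h(t) = F / (1 + exp(k * (t - tau_d - w)))` for
#' `t >= tau_d`, 0 before; `h(tau_d) = F / (1 + exp(-k*w))` is the flow
#' read-out used as MBF.
#'
#' @param F flow amplitude (ml/g/min when used for MBF).
#' @param k decay rate, 1/s (> 0).
#' @param w plateau width, s (>= 0).
#' @param tau_d delay, s (>= 0).
#' @return parameter list of class `FermiIRFParams`.
#' @export
fermi_irf_params <- function(F, k, w, tau_d = 0) {
  if (F < 0 || k <= 0 || w < 0 || tau_d < 0)
    pq_error("pq_bad_params",
             "Fermi parameters require F >= 0, k > 0, w >= 0, tau_d >= 0")
  structure(list(F = F, k = k, w = w, tau_d = tau_d),
            class = "FermiIRFParams")
}

#' Evaluate a Fermi impulse response
#'
#' @param params a [fermi_irf_params()].
#' @param tgrid nondecreasing time grid, s.
#' @return impulse-response array; monotonically nonincreasing for
#'   `t >= tau_d`, 0 before `tau_d`.
#' @export
fermi_irf <- function(params, tgrid) {
  if (is.unsorted(tgrid)) pq_error("pq_bad_params", "tgrid must be nondecreasing")
  ifelse(tgrid >= params$tau_d,
         params$F / (1 + exp(params$k * (tgrid - params$tau_d - params$w))),
         0)
}

fermi_mbf <- function(params) params$F / (1 + exp(-params$k * params$w))

#' Forward model: tissue curve from AIF and impulse response
#'
#' Discrete causal convolution `c_t[n] = dt * sum_{m<=n} aif[m] * irf[n-m]`,
#' linear in both arguments.
#'
#' @param aif,irf curves on the same uniform grid.
#' @param dt grid spacing, s.
#' @return tissue curve, same length.
#' @export
synthesize_tissue_curve <- function(aif, irf, dt) {
  if (length(aif) != length(irf))
    pq_error("pq_grid_mismatch", "aif and irf must share one uniform grid")
  n <- length(aif)
  full <- stats::convolve(aif, rev(irf), type = "open")
  dt * full[seq_len(n)]
}

# ---------------------------------------------------------------------------

#' Phantom specification
#'
#' Defaults mirror the target acquisition: 60 frames at RR = 1 s, 3 slices,
#' 128x128 myocardial matrix, 64x48 AIF matrix; normal stress/rest MBF
#' 3.0/1.0 ml/g/min. An optional ischemic region (default: the two adjacent
#' sectors of one coronary territory) carries reduced stress MBF.
#'
#' @param image_size myocardial matrix size (square), pixels.
#' @param aif_size AIF matrix `c(rows, cols)`.
#' @param n_frames heartbeats (frames per series).
#' @param rr_interval_s seconds per heartbeat.
#' @param epi_radius,endo_radius epicardial/endocardial radii of the basal
#'   slice, pixels; towards the apex the epicardial radius shrinks by
#'   `slice_scale` while the wall thickness stays constant.
#' @param slice_scale per-slice epicardial radius scale (basal, mid, apical).
#' @param stress_mbf,rest_mbf normal-sector MBF, ml/g/min (scalar or 3x6
#'   matrix `[slice, sector]`).
#' @param ischemia `NULL`, or `list(slice =, sectors =, stress_mbf =,
#'   rest_mbf =)` overriding those sectors (`rest_mbf` optional).
#' @param aif_stress,aif_rest [gamma_variate_params()] per condition.
#' @param fermi_k,fermi_w,fermi_tau_d painted tissue residue shape.
#' @param shading_coef polynomial shading coefficients
#'   `c(x, y, xy, x^2, y^2)` on coordinates scaled to `[-1, 1]`.
#' @param motion_max_px peak-to-zero amplitude of per-frame translation.
#' @param noise_snr peak normal stress tissue enhancement / noise SD;
#'   `Inf` for noiseless.
#' @param baseline,gain,pd_value signal-unit offsets/scales; `baseline` is the
#'   myocardial pre-contrast intensity.
#' @param background_value static thorax background intensity (below
#'   `baseline`, so anatomy is visible before contrast, as in real images).
#' @param blood_baseline pre-contrast blood-pool intensity.
#' @param conditions subset of `c("stress", "rest")`.
#' @return a list of class `PhantomSpec`.
#' @export
phantom_spec <- function(image_size = 128, aif_size = c(64, 48),
                         n_frames = 60, rr_interval_s = 1.0,
                         epi_radius = image_size / 4,
                         endo_radius = image_size * 0.156,
                         slice_scale = c(1, 0.88, 0.75),
                         stress_mbf = 3.0, rest_mbf = 1.0,
                         ischemia = NULL,
                         aif_stress = gamma_variate_params(t0 = 8, beta = 1.5),
                         aif_rest = gamma_variate_params(t0 = 10, beta = 2.0,
                                                         recirculation_delay = 14),
                         fermi_k = 0.8, fermi_w = 3, fermi_tau_d = 1,
                         shading_coef = c(0.25, 0.2, 0.1, -0.15, 0),
                         motion_max_px = 0, noise_snr = Inf,
                         baseline = 100, gain = 400, pd_value = 300,
                         background_value = 70, blood_baseline = 110,
                         conditions = c("stress", "rest")) {
  if (endo_radius >= epi_radius)
    pq_error("pq_bad_params", "endo_radius must be < epi_radius")
  expand <- function(v) {
    if (is.matrix(v)) { stopifnot(all(dim(v) == c(3, 6))); v }
    else matrix(v, 3, 6)
  }
  truth <- list(stress = expand(stress_mbf), rest = expand(rest_mbf))
  if (!is.null(ischemia)) {
    truth$stress[ischemia$slice, ischemia$sectors] <- ischemia$stress_mbf
    if (!is.null(ischemia$rest_mbf))
      truth$rest[ischemia$slice, ischemia$sectors] <- ischemia$rest_mbf
  }
  if (any(unlist(truth) < 0) || any(unlist(truth) > 10))
    pq_error("pq_bad_params", "regional MBF truth must lie in [0, 10] ml/g/min")
  structure(list(
    image_size = image_size, aif_size = aif_size, n_frames = n_frames,
    rr_interval_s = rr_interval_s, epi_radius = epi_radius,
    endo_radius = endo_radius, slice_scale = slice_scale,
    regional_truth = truth[intersect(c("stress", "rest"), conditions)],
    aif_params = list(stress = aif_stress, rest = aif_rest),
    fermi = list(k = fermi_k, w = fermi_w, tau_d = fermi_tau_d),
    shading_coef = shading_coef, motion_max_px = motion_max_px,
    noise_snr = noise_snr, baseline = baseline, gain = gain,
    pd_value = pd_value, background_value = background_value,
    blood_baseline = blood_baseline, conditions = conditions
  ), class = "PhantomSpec")
}

shading_field <- function(n, coef) {
  u <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)  # x (cols)
  v <- matrix(seq(-1, 1, length.out = n), n, n)                # y (rows)
  s <- 1 + coef[1] * u + coef[2] * v + coef[3] * u * v +
    coef[4] * u^2 + coef[5] * v^2
  s <- pmax(s, 0.05)
  s / mean(s)
}

motion_schedule <- function(n, max_px, rr) {
  if (max_px <= 0)
    return(data.frame(ty = numeric(n), tx = numeric(n)))
  t <- (seq_len(n) - 1) * rr
  # respiratory-like drift plus beat-to-beat jitter, clipped to +/- max_px
  ty <- 0.8 * max_px * sin(2 * pi * 0.21 * t + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, 0.15 * max_px)
  tx <- 0.8 * max_px * sin(2 * pi * 0.16 * t + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, 0.15 * max_px)
  # median-centered: breathing excursions around a neutral position, so the
  # ground-truth anchor coincides with the unshifted painting grid
  ty <- ty - stats::median(ty)
  tx <- tx - stats::median(tx)
  data.frame(ty = pmin(pmax(ty, -max_px), max_px),
             tx = pmin(pmax(tx, -max_px), max_px))
}

# concentration-units tissue curve for a target MBF under the painted residue
phantom_tissue_curve <- function(mbf, aif_conc, fermi, tgrid, dt) {
  amp <- mbf * (1 + exp(-fermi$k * fermi$w))
  irf <- fermi_irf(fermi_irf_params(amp, fermi$k, fermi$w, fermi$tau_d), tgrid)
  synthesize_tissue_curve(aif_conc, irf / 60, dt)
}

#' Generate a synthetic perfusion study with ground truth
#'
#' Myocardial frames are painted from per-pixel tissue curves (sector-specific
#' MBF through a Fermi residue) inside the annulus, the LV cavity carries the
#' AIF curve and the background is static; multiplicative shading, per-frame
#' translation and Gaussian noise are then applied. Proton-density frames are
#' the unshaded baseline times the shading field, noise-free. The AIF series
#' is a low-resolution two-chamber image (RV enhances 4 s earlier than LV).
#' Deterministic given `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; all randomness flows through it.
#' @return `list(study = PerfusionStudy, truth = list(...))`; `truth` holds
#'   per-condition per-slice MBF maps (`NA` outside the annulus), sector
#'   labels, the shading field, per-series true translations, and the
#'   noise-free AIF curves in concentration and signal units.
#' @export
build_phantom <- function(spec, seed = 1L) {
  n <- spec$image_size
  if (spec$epi_radius + spec$motion_max_px + 1 >= n / 2)
    pq_error("pq_geometry", "annulus plus motion margin does not fit the image")
  tgrid <- (seq_len(spec$n_frames) - 1) * spec$rr_interval_s
  dt <- spec$rr_interval_s
  center <- c((n + 1) / 2, (n + 1) / 2)
  shading <- shading_field(n, spec$shading_coef)

  # per-condition noise scale: the SNR is defined on that condition's normal
  # (modal) tissue curve, so stress and rest curves carry comparable SNR
  noise_sd <- list()
  for (cond in spec$conditions) {
    vals <- spec$regional_truth[[cond]]
    ref_mbf <- as.numeric(names(sort(table(vals), decreasing = TRUE))[1])
    ref_curve <- phantom_tissue_curve(ref_mbf,
                                      gamma_variate(spec$aif_params[[cond]],
                                                    tgrid),
                                      spec$fermi, tgrid, dt)
    noise_sd[[cond]] <- if (is.finite(spec$noise_snr))
      spec$gain * max(ref_curve) / spec$noise_snr else 0
  }

  dd <- sqrt(outer((seq_len(n) - center[1])^2,
                   (seq_len(n) - center[2])^2, "+"))
  truth <- list(mbf = list(), sector_labels = list(), shading = shading,
                motion = list(), aif_conc = list(), aif_signal = list(),
                noise_sd = noise_sd, t = tgrid, center = center,
                radii = list())
  conditions <- list()

  with_seed(seed, {
    for (cond in spec$conditions) {
      aif_conc <- gamma_variate(spec$aif_params[[cond]], tgrid)
      truth$aif_conc[[cond]] <- aif_conc
      truth$aif_signal[[cond]] <- spec$blood_baseline + spec$gain * aif_conc
      mbf_truth <- spec$regional_truth[[cond]]
      myo <- list(); pd <- list(); motion <- list(myo = list())

      for (sl in 1:3) {
        sc <- spec$slice_scale[sl]
        epi <- spec$epi_radius * sc
        endo <- epi - (spec$epi_radius - spec$endo_radius)
        annulus <- dd >= endo & dd <= epi
        cavity <- dd <= (endo - 2)
        labels <- sectorize(annulus, center, reference_angle = pi / 2,
                            n_sectors = 6)
        if (cond == spec$conditions[[1]]) {
          truth$sector_labels[[sl]] <- labels
          truth$radii[[sl]] <- c(endo = endo, epi = epi)
        }
        mbf_map_true <- matrix(NA_real_, n, n)
        conc <- matrix(0, spec$n_frames, sum(annulus))
        for (s in 1:6) {
          sel <- labels[annulus] == s
          if (!any(sel)) next
          curve <- phantom_tissue_curve(mbf_truth[sl, s], aif_conc,
                                        spec$fermi, tgrid, dt)
          conc[, sel] <- curve
          mbf_map_true[annulus][sel] <- mbf_truth[sl, s]
        }
        truth$mbf[[cond]][[sl]] <- mbf_map_true

        sched <- motion_schedule(spec$n_frames, spec$motion_max_px,
                                 spec$rr_interval_s)
        motion$myo[[sl]] <- sched
        frames <- array(0, dim = c(spec$n_frames, n, n))
        base <- matrix(spec$background_value, n, n)
        base[dd <= epi] <- spec$baseline           # static anatomic contrast
        for (f in seq_len(spec$n_frames)) {
          img <- base
          img[cavity] <- spec$blood_baseline + spec$gain * aif_conc[f]
          img[annulus] <- spec$baseline + spec$gain * conc[f, ]
          # anatomy moves inside the static coil sensitivity field
          if (spec$motion_max_px > 0)
            img <- translate_image(img, sched$ty[f], sched$tx[f])
          img <- img * shading
          if (noise_sd[[cond]] > 0)
            img <- img + matrix(stats::rnorm(n * n, 0, noise_sd[[cond]]), n, n)
          frames[f, , ] <- pmax(img, 0)
        }
        myo[[sl]] <- dynamic_series(frames,
          frame_meta(tgrid, seq_len(spec$n_frames) - 1L, sl - 1L), "MYO")
        pd_img <- matrix(spec$pd_value, n, n) * shading
        pd[[sl]] <- dynamic_series(
          aperm(array(pd_img, dim = c(n, n, 2)), c(3, 1, 2)),
          frame_meta(c(0, spec$rr_interval_s), 0:1, sl - 1L), "PD")
      }

      # low-resolution AIF series: LV blob (the specified curve) + RV blob
      ar <- spec$aif_size[1]; ac <- spec$aif_size[2]
      acenter <- c((ar + 1) / 2, (ac + 1) / 2)
      rad <- max(3, round(min(ar, ac) / 6))
      lv_c <- c(acenter[1], acenter[2] + rad + 1)
      rv_c <- c(acenter[1], acenter[2] - rad - 1)
      addd <- function(ctr) sqrt(outer((seq_len(ar) - ctr[1])^2,
                                       (seq_len(ac) - ctr[2])^2, "+"))
      lv_mask <- addd(lv_c) <= rad
      rv_mask <- addd(rv_c) <= rad & !lv_mask
      rv_par <- spec$aif_params[[cond]]
      rv_par$t0 <- max(0, rv_par$t0 - 4)
      rv_par$amplitude <- 0.9 * rv_par$amplitude
      rv_conc <- gamma_variate(rv_par, tgrid)
      asched <- motion_schedule(spec$n_frames,
                                min(spec$motion_max_px, rad / 2),
                                spec$rr_interval_s)
      motion$aif <- asched
      aframes <- array(0, dim = c(spec$n_frames, ar, ac))
      for (f in seq_len(spec$n_frames)) {
        img <- matrix(spec$background_value, ar, ac)
        img[lv_mask] <- spec$blood_baseline + spec$gain * aif_conc[f]
        img[rv_mask] <- spec$blood_baseline + spec$gain * rv_conc[f]
        if (spec$motion_max_px > 0)
          img <- translate_image(img, asched$ty[f], asched$tx[f])
        if (noise_sd[[cond]] > 0)
          img <- img + matrix(stats::rnorm(ar * ac, 0, noise_sd[[cond]]), ar, ac)
        aframes[f, , ] <- pmax(img, 0)
      }
      aif <- dynamic_series(aframes,
        frame_meta(tgrid, seq_len(spec$n_frames) - 1L), "AIF")
      if (cond == spec$conditions[[1]]) {
        truth$aif_lv_mask <- lv_mask
        truth$aif_rv_mask <- rv_mask
      }
      truth$motion[[cond]] <- motion
      conditions[[cond]] <- list(aif = aif, myo = myo, pd = pd)
    }
  })
  study <- perfusion_study(conditions,
                           subject_id = sprintf("phantom-%d", seed),
                           rr_interval_s = spec$rr_interval_s)
  list(study = study, truth = truth, spec = spec)
}
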