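#' perfquant: automated pixel-wise quantitative myocardial perfusion mapping
#'
#' Converts dual-sequence first-pass contrast-enhanced cardiac MR perfusion
#' series (a low-resolution arterial-input-function series plus three
#' myocardial short-axis slices per heartbeat and proton-density reference
#' frames) into pixel-wise myocardial blood flow (MBF) maps by
#' Fermi-constrained deconvolution, then into 18-segment / 9-coronary-territory
#' summaries, perfusion-reserve and relative measures, and ROC-based
#' diagnostic-accuracy statistics.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Structured errors

pq_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "perfquant_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# ---------------------------------------------------------------------------
# FrameMeta

#' Per-frame acquisition metadata
#'
#' One row per frame. `acquisition_time` is seconds from series start and must
#' be strictly increasing with `trigger_index` (heartbeat number) within a
#' series; gaps from skipped beats are retained, not interpolated.
#'
#' @param acquisition_time numeric, seconds from series start.
#' @param trigger_index integer heartbeat number (>= 0).
#' @param slice_index integer slice in `0:2` for myocardial frames, `NA` for
#'   AIF / proton-density frames.
#' @param pixel_spacing_row,pixel_spacing_col mm per pixel, > 0.
#' @param slice_thickness mm.
#' @return a `data.frame` with one row per frame.
#' @export
frame_meta <- function(acquisition_time, trigger_index,
                       slice_index = NA_integer_,
                       pixel_spacing_row = 1, pixel_spacing_col = 1,
                       slice_thickness = 8) {
  n <- length(acquisition_time)
  m <- data.frame(
    acquisition_time  = as.numeric(acquisition_time),
    trigger_index     = as.integer(trigger_index),
    slice_index       = rep_len(as.integer(slice_index), n),
    pixel_spacing_row = rep_len(as.numeric(pixel_spacing_row), n),
    pixel_spacing_col = rep_len(as.numeric(pixel_spacing_col), n),
    slice_thickness   = rep_len(as.numeric(slice_thickness), n)
  )
  validate_frame_meta(m)
  m
}

validate_frame_meta <- function(m) {
  stopifnot(is.data.frame(m))
  need <- c("acquisition_time", "trigger_index", "slice_index",
            "pixel_spacing_row", "pixel_spacing_col", "slice_thickness")
  if (!all(need %in% names(m)))
    pq_error("pq_invalid_meta", "frame metadata missing required columns")
  if (any(m$pixel_spacing_row <= 0) || any(m$pixel_spacing_col <= 0))
    pq_error("pq_invalid_meta", "pixel_spacing components must be > 0")
  o <- order(m$trigger_index)
  if (nrow(m) > 1 && any(diff(m$acquisition_time[o]) <= 0))
    pq_error("pq_invalid_meta",
             "acquisition_time must be strictly increasing with trigger_index")
  invisible(m)
}

# ---------------------------------------------------------------------------
# DynamicSeries

#' A dynamic image series (time x rows x cols)
#'
#' @param frames numeric 3-D array `[time, rows, cols]`, nonnegative.
#' @param meta a [frame_meta()] data.frame, one row per frame.
#' @param role one of `"AIF"`, `"MYO"`, `"PD"`.
#' @return an object of class `DynamicSeries`.
#' @export
dynamic_series <- function(frames, meta, role = c("MYO", "AIF", "PD")) {
  role <- match.arg(role)
  if (length(dim(frames)) != 3L)
    pq_error("pq_invalid_series", "frames must be a 3-D array [time, rows, cols]")
  if (dim(frames)[1] != nrow(meta))
    pq_error("pq_invalid_series", sprintf(
      "frame count (%d) != metadata rows (%d)", dim(frames)[1], nrow(meta)))
  validate_frame_meta(meta)
  if (any(frames < 0, na.rm = TRUE))
    pq_error("pq_invalid_series", "frame intensities must be nonnegative")
  o <- order(meta$trigger_index)
  structure(list(frames = frames[o, , , drop = FALSE],
                 meta = meta[o, , drop = FALSE],
                 role = role),
            class = "DynamicSeries")
}

#' @export
print.DynamicSeries <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<DynamicSeries role=%s frames=%d size=%dx%d t=[%.1f, %.1f]s>\n",
              x$role, d[1], d[2], d[3],
              min(x$meta$acquisition_time), max(x$meta$acquisition_time)))
  invisible(x)
}

n_frames <- function(s) dim(s$frames)[1]
frame_dim <- function(s) dim(s$frames)[2:3]

series_times <- function(s) s$meta$acquisition_time

# ---------------------------------------------------------------------------
# PerfusionStudy

#' A stress/rest perfusion study
#'
#' Bundles, per condition, one low-resolution AIF series, three myocardial
#' slice series (basal/mid/apical), and two proton-density frames per slice.
#' A single condition is allowed for MBF-only runs; both are needed for MPR.
#'
#' @param conditions named list; names from `c("stress","rest")`. Each element
#'   is `list(aif = DynamicSeries, myo = list of 3 DynamicSeries,
#'   pd = list of 3 DynamicSeries with 2 frames each)`.
#' @param subject_id opaque identifier string.
#' @param rr_interval_s nominal seconds per heartbeat.
#' @return an object of class `PerfusionStudy`.
#' @export
perfusion_study <- function(conditions, subject_id = "anon",
                            rr_interval_s = 1.0) {
  if (!length(conditions))
    pq_error("pq_invalid_study", "study has no conditions")
  if (!all(names(conditions) %in% c("stress", "rest")))
    pq_error("pq_invalid_study", "condition names must be 'stress'/'rest'")
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    for (rl in c("aif", "myo", "pd"))
      if (is.null(cond[[rl]]))
        pq_error("pq_missing_role",
                 sprintf("condition '%s' is missing role %s", cn, toupper(rl)),
                 role = toupper(rl), condition = cn)
    if (cond$aif$role != "AIF")
      pq_error("pq_invalid_study", "aif slot must hold an AIF-role series")
    if (length(cond$myo) != 3L)
      pq_error("pq_invalid_study", sprintf(
        "condition '%s': expected 3 myocardial slice series, got %d",
        cn, length(cond$myo)))
    for (k in seq_along(cond$myo)) {
      if (cond$myo[[k]]$role != "MYO")
        pq_error("pq_invalid_study", "myo slot must hold MYO-role series")
      pd <- if (length(cond$pd) >= k) cond$pd[[k]] else NULL
      if (is.null(pd) || pd$role != "PD")
        pq_error("pq_missing_role",
                 sprintf("condition '%s' slice %d is missing role PD", cn, k),
                 role = "PD", condition = cn)
      if (!identical(frame_dim(pd), frame_dim(cond$myo[[k]])))
        pq_error("pq_geometry_mismatch", sprintf(
          "condition '%s' slice %d: PD geometry %s != MYO geometry %s",
          cn, k, paste(frame_dim(pd), collapse = "x"),
          paste(frame_dim(cond$myo[[k]]), collapse = "x")))
    }
    # AIF is acquired at lower spatial resolution than the myocardial series
    if (prod(frame_dim(cond$aif)) >= prod(frame_dim(cond$myo[[1]])))
      pq_error("pq_invalid_study",
               "AIF series must have lower spatial resolution than MYO series")
  }
  structure(list(conditions = conditions, subject_id = subject_id,
                 rr_interval_s = rr_interval_s),
            class = "PerfusionStudy")
}

#' @export
print.PerfusionStudy <- function(x, ...) {
  cat(sprintf("<PerfusionStudy subject=%s RR=%.2fs conditions=%s>\n",
              x$subject_id, x$rr_interval_s,
              paste(names(x$conditions), collapse = "+")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MBFMap

#' A pixel-wise myocardial blood flow map
#'
#' @param values numeric matrix, ml/g/min; `NA` allowed only outside the mask
#'   or where the fit failed (then flagged in `failed`).
#' @param mask logical matrix, TRUE on myocardium.
#' @param slice_index integer in `0:2`.
#' @param condition `"stress"` or `"rest"`.
#' @param failed logical matrix of flagged fit failures (optional).
#' @return an object of class `MBFMap`.
#' @export
mbf_map <- function(values, mask, slice_index, condition,
                    failed = NULL) {
  if (!identical(dim(values), dim(mask)))
    pq_error("pq_geometry_mismatch", "values / mask dimensions differ")
  if (is.null(failed)) failed <- matrix(FALSE, nrow(values), ncol(values))
  bad <- mask & !failed & (!is.finite(values) | values < 0)
  if (any(bad))
    pq_error("pq_invalid_map",
             "masked MBF values must be finite and >= 0 unless flagged failed")
  structure(list(values = values, mask = mask, failed = failed,
                 slice_index = as.integer(slice_index),
                 condition = condition),
            class = "MBFMap")
}

#' @export
print.MBFMap <- function(x, ...) {
  v <- x$values[x$mask & !x$failed]
  cat(sprintf("<MBFMap %s slice %d: %d px, median %.2f ml/g/min, %d failed>\n",
              x$condition, x$slice_index, sum(x$mask),
              stats::median(v, na.rm = TRUE), sum(x$failed)))
  invisible(x)
}
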