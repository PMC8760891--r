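# Top-level orchestration: corrected study -> ROIs -> timing -> MBF/MPR maps
# -> segment/territory tables, plus the command-line entry points.

pq_log <- function(fmt, ...) {
  message(sprintf("[perfquant %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

default_config <- function() {
  list(baseline_n = 4, smoothing_scale_px = NULL, max_shift_px = 5,
       n_reference_passes = 2, n_starts = 9, reference_angle = pi / 2)
}

#' Run the full automated perfusion quantification pipeline on a study
#'
#' Stages per condition: (1) rigid motion correction of the AIF and
#' myocardial series; (2) surface-coil intensity correction of each
#' myocardial series from its proton-density frames; (3) AIF blood-pool and
#' myocardial ROI detection; (4) first-pass timing detection on the AIF
#' curve; (5) pixel-wise Fermi-constrained deconvolution into MBF maps; then
#' MPR maps (when both conditions are present), sectorization and the
#' 18-segment / 9-territory table with relative measures and minima.
#'
#' @param study a [perfusion_study()].
#' @param config list, see `default_config()`; missing keys take defaults.
#' @param verbose emit per-stage log lines to stderr.
#' @return list: `maps`, `mpr_maps`, `rois`, `timing`, `traces`,
#'   `sector_labels`, `table` (SegmentTable), `territories` (with
#'   rmbf/rmpr), `summary` (patient/vessel minima).
#' @export
run_study_pipeline <- function(study, config = list(), verbose = FALSE) {
  cfg <- utils::modifyList(default_config(), config)
  say <- function(...) if (verbose) pq_log(...)
  rois <- list(); timing <- list(); traces <- list(); labels <- list()
  corrected <- study
  for (cond in names(study$conditions)) {
    t0 <- Sys.time()
    cnd <- study$conditions[[cond]]
    mc_aif <- motion_correct(cnd$aif, cfg)
    traces[[cond]]$aif <- mc_aif$trace
    myo <- list()
    for (sl in 1:3) {
      # coil correction precedes motion correction: the receive field is
      # static in the scanner frame while the anatomy moves through it, so
      # dividing registered frames by a static field would imprint a
      # per-frame multiplicative error proportional to the field gradient
      field <- estimate_bias_field(cnd$pd[[sl]], cfg$smoothing_scale_px)
      unshaded <- apply_bias_correction(cnd$myo[[sl]], field)
      mc <- motion_correct(unshaded, cfg)
      traces[[cond]]$myo[[sl]] <- mc$trace
      myo[[sl]] <- mc$series
    }
    corrected$conditions[[cond]]$aif <- mc_aif$series
    corrected$conditions[[cond]]$myo <- myo
    say("%s: motion + coil correction done (%.1fs)", cond,
        as.numeric(Sys.time() - t0, units = "secs"))

    t0 <- Sys.time()
    aif_det <- detect_aif_roi(mc_aif$series, cfg$baseline_n)
    timing[[cond]] <- detect_timing(aif_det$curve, cfg$baseline_n)
    myo_det <- lapply(myo, detect_myocardium, baseline_n = cfg$baseline_n)
    rois[[cond]] <- list(aif = aif_det, myo = myo_det)
    labels[[cond]] <- lapply(myo_det, function(d)
      sectorize(d$mask, d$lv_center, cfg$reference_angle, 6))
    say("%s: ROI + timing detection done (%.1fs)", cond,
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  t0 <- Sys.time()
  maps <- compute_mbf_map(corrected, rois, timing, cfg)
  say("deconvolution done (%.1fs)", as.numeric(Sys.time() - t0, units = "secs"))

  mpr_maps <- NULL
  if (all(c("stress", "rest") %in% names(maps)))
    mpr_maps <- lapply(1:3, function(sl)
      compute_mpr(maps$stress[[sl]], maps$rest[[sl]]))

  tab <- segment_table(maps, labels)
  territories <- tryCatch(relative_measures(tab),
                          perfquant_error = function(e) tab$territories)
  summary <- if (!is.null(territories$rmbf))
    patient_vessel_summary(territories) else NULL
  list(maps = maps, mpr_maps = mpr_maps, rois = rois, timing = timing,
       traces = traces, sector_labels = labels, table = tab,
       territories = territories, summary = summary)
}

read_config_file <- function(path) {
  if (is.null(path)) return(list())
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' CLI: run the pipeline on a study directory
#'
#' @param study_dir study location (archive or DICOM directory).
#' @param out_dir output directory.
#' @param config_file optional JSON (or YAML) config.
#' @param condition `"both"`, `"stress"` or `"rest"`.
#' @param dialect study dialect for [read_study()].
#' @return the pipeline result, invisibly.
#' @export
perfquant_run <- function(study_dir, out_dir, config_file = NULL,
                          condition = "both", dialect = "archive") {
  cfg <- read_config_file(config_file)
  study <- read_study(study_dir, dialect = dialect)
  if (condition != "both")
    study$conditions <- study$conditions[condition]
  res <- run_study_pipeline(study, cfg, verbose = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(res$maps)) for (sl in 1:3) {
    write_map(res$maps[[cond]][[sl]],
              file.path(out_dir, sprintf("mbf_%s_slice%d.nii", cond, sl - 1)))
    write_map(res$maps[[cond]][[sl]],
              file.path(out_dir, sprintf("mbf_%s_slice%d.csv", cond, sl - 1)),
              format = "table")
    utils::write.csv(res$traces[[cond]]$myo[[sl]],
                     file.path(out_dir, sprintf("trace_%s_slice%d.csv",
                                                cond, sl - 1)),
                     row.names = FALSE)
  }
  utils::write.csv(res$table$segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(res$territories, file.path(out_dir, "territories.csv"),
                   row.names = FALSE)
  if (!is.null(res$summary)) {
    utils::write.csv(data.frame(metric = names(res$summary$patient),
                                value = unname(res$summary$patient)),
                     file.path(out_dir, "patient_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary$vessel,
                     file.path(out_dir, "vessel_summary.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}

#' CLI: generate a phantom study
#'
#' @param spec_file optional JSON/YAML file of [phantom_spec()] arguments.
#' @param seed integer seed.
#' @param out_dir output directory (archive + ground-truth arrays + spec echo).
#' @return the phantom, invisibly.
#' @export
perfquant_phantom <- function(spec_file = NULL, seed = 1L, out_dir) {
  args <- read_config_file(spec_file)
  if (!is.null(args$ischemia)) args$ischemia <- as.list(args$ischemia)
  spec <- do.call(phantom_spec, args)
  ph <- build_phantom(spec, seed)
  write_study(ph$study, out_dir)
  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  for (cond in names(ph$truth$mbf)) for (sl in 1:3)
    write_nifti(ph$truth$mbf[[cond]][[sl]] |>
                  (\(m) { m[is.na(m)] <- -1; m })(),
                file.path(gt_dir, sprintf("mbf_%s_slice%d.nii", cond, sl - 1)))
  write_nifti(ph$truth$shading, file.path(gt_dir, "shading.nii"))
  echo <- args
  echo$seed <- seed
  jsonlite::write_json(echo, file.path(gt_dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ph)
}

#' CLI: cohort diagnostic-accuracy statistics
#'
#' @param segments_file CSV of per-unit summaries
#'   (`unit_id, level, metric, value`).
#' @param truth_file CSV of labels (`unit_id, level, label`).
#' @param out_dir output directory for the accuracy table and ROC points.
#' @return the [evaluate_cohort()] report, invisibly.
#' @export
perfquant_stats <- function(segments_file, truth_file, out_dir) {
  summaries <- utils::read.csv(segments_file)
  truth <- utils::read.csv(truth_file)
  rep <- evaluate_cohort(summaries, truth,
                         metrics = intersect(c("mbf", "mpr", "rmbf", "rmpr"),
                                             unique(summaries$metric)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep$table, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$delong, file.path(out_dir, "delong.csv"),
                   row.names = FALSE)
  utils::write.csv(rep$mcnemar, file.path(out_dir, "mcnemar.csv"),
                   row.names = FALSE)
  pts <- do.call(rbind, lapply(names(rep$rocs), function(nm) {
    r <- rep$rocs[[nm]]
    data.frame(roc = nm, threshold = r$thresholds,
               sensitivity = r$sensitivities, specificity = r$specificities)
  }))
  utils::write.csv(pts, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  invisible(rep)
}

#' Command-line entry point
#'
#' Dispatches `perfquant run|phantom|stats`; see `exec/perfquant`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
perfquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: perfquant run --study <dir> --out <dir> [--config cfg.json]",
    "[--condition stress|rest|both] [--dialect archive|dicom]",
    "       perfquant phantom [--spec spec.json] --seed N --out <dir>",
    "       perfquant stats --segments table.csv --truth labels.csv --out <dir>",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- if (i + 1 <= length(args)) args[i + 1] else NA
    i <- i + 2
  }
  switch(cmd,
    run = perfquant_run(opt$study, opt$out, opt$config,
                        opt$condition %||% "both",
                        opt$dialect %||% "archive"),
    phantom = perfquant_phantom(opt$spec, as.integer(opt$seed %||% "1"),
                                opt$out),
    stats = perfquant_stats(opt$segments, opt$truth, opt$out),
    { message(usage); return(invisible(1L)) })
  invisible(0L)
}
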