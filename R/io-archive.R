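# Study archive: a directory holding one NIfTI array container per series
# plus a JSON manifest of frame metadata. This is the self-describing dialect
# used throughout the tests; DICOM ingestion lives in io-dicom.R.

ARCHIVE_MANIFEST <- "manifest.json"

meta_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))

meta_from_list <- function(l) {
  m <- do.call(rbind, lapply(l, function(r) {
    if (is.null(r$slice_index)) r$slice_index <- NA_integer_   # JSON null
    as.data.frame(r)
  }))
  m$trigger_index <- as.integer(m$trigger_index)
  m$slice_index <- suppressWarnings(as.integer(m$slice_index))
  m
}

#' Write a perfusion study to a self-describing archive directory
#'
#' Arrays are stored losslessly (float64 NIfTI), frame metadata and study
#' attributes in a JSON manifest. [read_study()] round-trips bit-exactly.
#'
#' @param study a [perfusion_study()].
#' @param path directory to create/populate.
#' @return the manifest (a list), invisibly.
#' @export
write_study <- function(study, path) {
  if (!inherits(study, "PerfusionStudy"))
    pq_error("pq_invalid_study", "write_study expects a PerfusionStudy")
  if (!length(study$conditions))
    pq_error("pq_invalid_study", "refusing to write an empty study")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) pq_error("pq_io", sprintf("cannot create %s", path))
  manifest <- list(format = "perfquant-archive", version = 1L,
                   subject_id = study$subject_id,
                   rr_interval_s = study$rr_interval_s,
                   conditions = list())
  put_series <- function(s, file) {
    write_nifti(s$frames, file.path(path, file), datatype = "float64")
    list(file = file, role = s$role, meta = meta_to_list(s$meta))
  }
  for (cn in names(study$conditions)) {
    cond <- study$conditions[[cn]]
    entry <- list(aif = put_series(cond$aif, sprintf("%s_aif.nii", cn)),
                  myo = list(), pd = list())
    for (k in 1:3) {
      entry$myo[[k]] <- put_series(cond$myo[[k]],
                                   sprintf("%s_myo_slice%d.nii", cn, k - 1))
      entry$pd[[k]] <- put_series(cond$pd[[k]],
                                  sprintf("%s_pd_slice%d.nii", cn, k - 1))
    }
    manifest$conditions[[cn]] <- entry
  }
  jsonlite::write_json(manifest, file.path(path, ARCHIVE_MANIFEST),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_archive_study <- function(path) {
  mf <- file.path(path, ARCHIVE_MANIFEST)
  if (!file.exists(mf))
    pq_error("pq_io", sprintf("no archive manifest at %s", path))
  manifest <- jsonlite::read_json(mf)
  get_series <- function(e) {
    dynamic_series(read_nifti(file.path(path, e$file)),
                   meta_from_list(e$meta), role = e$role)
  }
  conditions <- lapply(manifest$conditions, function(cond) {
    for (rl in c("aif", "myo", "pd"))
      if (is.null(cond[[rl]]))
        pq_error("pq_missing_role",
                 sprintf("archive condition is missing role %s", toupper(rl)),
                 role = toupper(rl))
    list(aif = get_series(cond$aif),
         myo = lapply(cond$myo, get_series),
         pd  = lapply(cond$pd, get_series))
  })
  perfusion_study(conditions, subject_id = manifest$subject_id,
                  rr_interval_s = as.numeric(manifest$rr_interval_s))
}

#' Read a perfusion study
#'
#' @param path study directory.
#' @param dialect `"archive"` (see [write_study()]) or `"dicom"` (a directory
#'   of single-frame DICOM files; series roles resolved by a sequence-name
#'   regex table or a `sidecar.json` manifest, see [read_dicom_study()]).
#' @param ... passed to the dialect reader.
#' @return a [perfusion_study()].
#' @export
read_study <- function(path, dialect = c("archive", "dicom"), ...) {
  dialect <- match.arg(dialect)
  if (!dir.exists(path)) pq_error("pq_io", sprintf("no such directory: %s", path))
  switch(dialect,
         archive = read_archive_study(path),
         dicom   = read_dicom_study(path, ...))
}

#' Write an MBF/MPR map to disk
#'
#' @param map an [mbf_map()] (or any list with `values`/`mask`).
#' @param path output file (`.nii` for `float_image`, `.csv` for `table`).
#' @param format `"float_image"` (lossless float64 NIfTI) or `"table"`
#'   (CSV of `row,col,value` restricted to the mask).
#' @param datatype NIfTI datatype for `float_image`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, format = c("float_image", "table"),
                      datatype = "float64") {
  format <- match.arg(format)
  if (format == "float_image") {
    write_nifti(map$values, path, datatype = datatype)
  } else {
    idx <- which(map$mask, arr.ind = TRUE)
    df <- data.frame(row = idx[, 1], col = idx[, 2],
                     value = map$values[idx])
    df <- df[order(df$row, df$col), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
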