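# Minimal DICOM Part-10 ingestion (explicit VR little endian, uncompressed,
# one frame per file), plus a matching writer used to export studies and to
# build test fixtures. Scope is deliberately narrow: the tags a dual-sequence
# perfusion series needs, no sequences (SQ) with nested datasets, no private
# vendor tags. Series roles (AIF / MYO / PD), condition and slice index are
# resolved from the SeriesDescription via a configurable regex table, or
# overridden explicitly by a sidecar.json manifest in the same directory.

dcm_default_role_regex <- function() {
  list(AIF = "(?i)\\baif\\b", PD = "(?i)proton|\\bpd\\b",
       MYO = "(?i)\\bmyo|perf")
}

.dcm_tag <- function(group, elem) sprintf("%04X,%04X", group, elem)

dcm_write_element <- function(con, group, elem, vr, value) {
  writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (vr %in% c("US")) {
    payload <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("UL")) {
    payload <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "OW") {
    payload <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else { # string VRs: DS IS LO CS UI SH
    s <- paste(value, collapse = "\\")
    payload <- charToRaw(s)
    if (length(payload) %% 2 == 1)
      payload <- c(payload, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  if (long_vr) {
    writeBin(raw(2), con)
    writeBin(length(payload), con, size = 4, endian = "little")
  } else {
    writeBin(length(payload), con, size = 2, endian = "little")
  }
  writeBin(payload, con)
}

dcm_write_frame <- function(file, pixels, series_desc, series_number,
                            instance_number, meta_row, slope, intercept) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  # file meta group (always explicit LE)
  ts <- "1.2.840.10008.1.2.1"
  meta_con <- rawConnection(raw(0), "wb")
  dcm_write_element(meta_con, 0x0002, 0x0010, "UI", ts)
  meta_raw <- rawConnectionValue(meta_con); close(meta_con)
  dcm_write_element(con, 0x0002, 0x0000, "UL", length(meta_raw))
  writeBin(meta_raw, con)

  stored <- as.integer(round((pixels - intercept) / slope))
  stored[stored < 0L] <- 0L; stored[stored > 65535L] <- 65535L
  # unsigned 16-bit as signed for writeBin
  stored_s <- ifelse(stored > 32767L, stored - 65536L, stored)

  dcm_write_element(con, 0x0008, 0x103E, "LO", series_desc)
  dcm_write_element(con, 0x0018, 0x0050, "DS",
                    format(meta_row$slice_thickness, digits = 10))
  dcm_write_element(con, 0x0018, 0x1060, "DS",
                    format(meta_row$acquisition_time * 1000, digits = 12))
  dcm_write_element(con, 0x0020, 0x0011, "IS", as.character(series_number))
  dcm_write_element(con, 0x0020, 0x0012, "IS",
                    as.character(meta_row$trigger_index))
  dcm_write_element(con, 0x0020, 0x0013, "IS", as.character(instance_number))
  dcm_write_element(con, 0x0028, 0x0002, "US", 1L)
  dcm_write_element(con, 0x0028, 0x0004, "CS", "MONOCHROME2")
  dcm_write_element(con, 0x0028, 0x0010, "US", nrow(pixels))
  dcm_write_element(con, 0x0028, 0x0011, "US", ncol(pixels))
  dcm_write_element(con, 0x0028, 0x0030, "DS",
                    c(format(meta_row$pixel_spacing_row, digits = 10),
                      format(meta_row$pixel_spacing_col, digits = 10)))
  dcm_write_element(con, 0x0028, 0x0100, "US", 16L)
  dcm_write_element(con, 0x0028, 0x0101, "US", 16L)
  dcm_write_element(con, 0x0028, 0x0102, "US", 15L)
  dcm_write_element(con, 0x0028, 0x0103, "US", 0L)
  dcm_write_element(con, 0x0028, 0x1052, "DS", format(intercept, digits = 12))
  dcm_write_element(con, 0x0028, 0x1053, "DS", format(slope, digits = 12))
  # column-major stored pixel order; reader restores with the same convention
  dcm_write_element(con, 0x7FE0, 0x0010, "OW", as.vector(stored_s))
  invisible(file)
}

#' Export a study as a directory of DICOM files
#'
#' One explicit-VR little-endian file per frame, 16-bit stored pixels with a
#' per-series rescale slope/intercept. Integer-valued studies in
#' `[0, 65535]` round-trip losslessly; other intensities are quantized to
#' 16 bits (use the archive dialect for a bit-exact container).
#'
#' @param study a [perfusion_study()].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_dicom_study <- function(study, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sn <- 0L
  for (cn in names(study$conditions)) {
    cond <- study$conditions[[cn]]
    emit <- function(series, desc) {
      sn <<- sn + 1L
      rng <- range(series$frames)
      if (all(series$frames == round(series$frames)) &&
          rng[1] >= 0 && rng[2] <= 65535) {
        slope <- 1; intercept <- 0
      } else {
        slope <- max((rng[2] - rng[1]) / 65535, .Machine$double.eps)
        intercept <- rng[1]
      }
      for (i in seq_len(n_frames(series))) {
        f <- sprintf("%s/%s_%04d.dcm", path, gsub("[^A-Za-z0-9]+", "_", desc), i)
        dcm_write_frame(f, series$frames[i, , ], desc, sn, i,
                        series$meta[i, ], slope, intercept)
      }
    }
    emit(cond$aif, sprintf("%s AIF", cn))
    for (k in 1:3) {
      emit(cond$myo[[k]], sprintf("%s MYO slice%d", cn, k - 1))
      emit(cond$pd[[k]], sprintf("%s PD slice%d", cn, k - 1))
    }
  }
  invisible(path)
}

dcm_read_file <- function(file) {
  sz <- file.info(file)$size
  con <- file(file, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 132)
  if (length(head) < 132 || rawToChar(head[129:132]) != "DICM")
    seek(con, 0)
  out <- new.env(parent = emptyenv())
  repeat {
    ge <- readBin(con, "integer", 2, size = 2, signed = FALSE,
                  endian = "little")
    if (length(ge) < 2) break
    vr <- readChar(con, 2, useBytes = TRUE)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, "raw", 2)
      len <- readBin(con, "integer", 1, size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                     endian = "little")
    }
    tag <- .dcm_tag(ge[1], ge[2])
    if (tag == "7FE0,0010") {
      out$pixel_raw <- readBin(con, "integer", len / 2, size = 2,
                               signed = FALSE, endian = "little")
    } else if (vr %in% c("US")) {
      out[[tag]] <- readBin(con, "integer", len / 2, size = 2,
                            signed = FALSE, endian = "little")
    } else if (vr == "UL") {
      out[[tag]] <- readBin(con, "integer", len / 4, size = 4,
                            endian = "little")
    } else {
      raw <- readBin(con, "raw", len)
      out[[tag]] <- trimws(rawToChar(raw[raw != as.raw(0)]))
    }
    if (seek(con, NA) >= sz) break
  }
  out
}

dcm_num <- function(e, tag, default = NA_real_) {
  v <- e[[tag]]
  if (is.null(v)) return(default)
  as.numeric(strsplit(as.character(v), "\\\\")[[1]])
}

#' Read a perfusion study from a DICOM directory
#'
#' Groups files by SeriesDescription, resolves roles/condition/slice from the
#' description via `role_regex` (or a `sidecar.json` manifest listing
#' `series_desc`, `condition`, `role`, `slice_index`), and assembles a
#' [perfusion_study()]. Stored values are rescaled by the vendor
#' slope/intercept only.
#'
#' @param path directory of `.dcm` files.
#' @param role_regex named list of regexes for `AIF`, `PD`, `MYO`.
#' @param subject_id identifier for the returned study.
#' @param rr_interval_s nominal RR interval, seconds.
#' @return a [perfusion_study()].
#' @export
read_dicom_study <- function(path, role_regex = dcm_default_role_regex(),
                             subject_id = basename(path), rr_interval_s = 1.0) {
  files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) pq_error("pq_io", sprintf("no DICOM files in %s", path))
  sidecar <- NULL
  sc_file <- file.path(path, "sidecar.json")
  if (file.exists(sc_file)) sidecar <- jsonlite::read_json(sc_file)

  parsed <- lapply(files, dcm_read_file)
  desc <- vapply(parsed, function(e) {
    d <- e[["0008,103E"]]; if (is.null(d)) "" else d
  }, "")

  resolve <- function(d) {
    if (!is.null(sidecar)) {
      for (row in sidecar)
        if (grepl(row$series_desc, d, fixed = TRUE))
          return(list(role = row$role,
                      condition = row$condition,
                      slice = if (is.null(row$slice_index)) NA_integer_
                              else as.integer(row$slice_index)))
    }
    role <- NA_character_
    for (r in names(role_regex))
      if (grepl(role_regex[[r]], d, perl = TRUE)) { role <- r; break }
    condition <- if (grepl("(?i)stress", d, perl = TRUE)) "stress"
                 else if (grepl("(?i)rest", d, perl = TRUE)) "rest"
                 else NA_character_
    sl <- regmatches(d, regexpr("(?i)slice\\s*([0-9])", d, perl = TRUE))
    slice <- if (length(sl)) as.integer(gsub("\\D", "", sl)) else NA_integer_
    list(role = role, condition = condition, slice = slice)
  }

  conditions <- list()
  for (d in unique(desc)) {
    sel <- which(desc == d)
    info <- resolve(d)
    if (is.na(info$role))
      pq_error("pq_missing_role",
               sprintf("cannot resolve series role for '%s'", d), role = d)
    es <- parsed[sel]
    dims <- t(vapply(es, function(e)
      c(dcm_num(e, "0028,0010"), dcm_num(e, "0028,0011")), numeric(2)))
    if (nrow(unique(dims)) != 1L)
      pq_error("pq_geometry_mismatch", sprintf(
        "mixed geometries within series '%s': frames %s", d,
        paste(basename(files[sel][!duplicated(dims) | duplicated(dims, fromLast = TRUE)]),
              collapse = ", ")))
    r <- dims[1, 1]; cc <- dims[1, 2]
    frames <- array(0, dim = c(length(es), r, cc))
    meta <- data.frame(acquisition_time = numeric(length(es)),
                       trigger_index = integer(length(es)),
                       slice_index = rep(info$slice, length(es)),
                       pixel_spacing_row = 1, pixel_spacing_col = 1,
                       slice_thickness = 8)
    for (i in seq_along(es)) {
      e <- es[[i]]
      slope <- dcm_num(e, "0028,1053", 1); inter <- dcm_num(e, "0028,1052", 0)
      frames[i, , ] <- matrix(e$pixel_raw, r, cc) * slope + inter
      meta$acquisition_time[i] <- dcm_num(e, "0018,1060", NA) / 1000
      meta$trigger_index[i] <- as.integer(dcm_num(e, "0020,0012",
                                                  dcm_num(e, "0020,0013") - 1))
      ps <- dcm_num(e, "0028,0030", c(1, 1))
      meta$pixel_spacing_row[i] <- ps[1]; meta$pixel_spacing_col[i] <- ps[2]
      meta$slice_thickness[i] <- dcm_num(e, "0018,0050", 8)
    }
    ds <- dynamic_series(frames, meta, role = info$role)
    cn <- if (is.na(info$condition)) "stress" else info$condition
    if (is.null(conditions[[cn]]))
      conditions[[cn]] <- list(aif = NULL, myo = vector("list", 3),
                               pd = vector("list", 3))
    if (info$role == "AIF") conditions[[cn]]$aif <- ds
    else if (info$role == "MYO") conditions[[cn]]$myo[[info$slice + 1L]] <- ds
    else conditions[[cn]]$pd[[info$slice + 1L]] <- ds
  }
  perfusion_study(conditions, subject_id = subject_id,
                  rr_interval_s = rr_interval_s)
}
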