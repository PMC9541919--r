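# Readers and writers. Three on-disk layouts are supported:
#   * "rds_bundle": one R-native serialized file, the lossless reference
#     interchange format;
#   * "nifti_series": one NIfTI-1 volume per frame per velocity component
#     plus per-frame mask volumes, with a JSON sidecar for timing, units and
#     landmarks (interoperable with imaging tools);
#   * "vtk_series": legacy-ASCII VTK structured-points files, one per frame,
#     with the same JSON sidecar.
# Internal units are always mm / s / m/s; declared on-disk units are
# converted at this boundary.

landmarks_to_plain <- function(lms) {
  lapply(lms, function(lm) {
    lapply(lm[c("apex", "mitral_points", "aortic_points", "pm_tips", "pm_bases")],
           function(p) if (is.null(p)) NULL else unname(rbind(p)))
  })
}

landmarks_from_plain <- function(x) {
  lapply(x, function(lm) {
    mk <- function(p) if (is.null(p) || !length(p)) NULL else do.call(rbind, lapply(p, unlist))
    landmark_set(apex = unlist(lm$apex), mitral_points = mk(lm$mitral_points),
                 aortic_points = mk(lm$aortic_points),
                 pm_tips = mk(lm$pm_tips), pm_bases = mk(lm$pm_bases))
  })
}

dataset_meta <- function(ds, n_frames) {
  list(format_version = 1L, n_frames = n_frames,
       spacing = ds$spacing, spatial_units = "mm",
       velocity_units = "m/s",
       frame_times = ds$frame_times, rr_interval = ds$rr_interval,
       hematocrit = ds$hematocrit,
       origin = ds$origin, orientation = ds$orientation)
}

length_factor <- function(units) {
  switch(units, mm = 1, cm = 10, m = 1000,
         stop("unknown spatial unit: ", units))
}

velocity_factor <- function(units) {
  switch(units, `m/s` = 1, `cm/s` = 0.01, `mm/s` = 0.001,
         stop("unknown velocity unit: ", units))
}

#' Write a flow dataset to disk
#'
#' @param ds a [flow_dataset()].
#' @param path output file (`rds_bundle`) or directory (series formats).
#' @param format `"rds_bundle"`, `"nifti_series"` or `"vtk_series"`.
#' @return `path`, invisibly.
#' @export
write_flow_dataset <- function(ds, path,
                               format = c("rds_bundle", "nifti_series", "vtk_series")) {
  format <- match.arg(format)
  nt <- dim(ds$mask)[4]
  if (format == "rds_bundle") {
    saveRDS(list(meta = dataset_meta(ds, nt), velocity = ds$velocity,
                 mask = ds$mask, landmarks = ds$landmarks), path)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset_meta(ds, nt)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(ds$landmarks)) {
    jsonlite::write_json(landmarks_to_plain(ds$landmarks),
                         file.path(path, "landmarks.json"), digits = NA, pretty = TRUE)
  }
  if (format == "nifti_series") {
    for (k in seq_len(nt)) {
      for (c3 in 1:3) {
        im <- RNifti::asNifti(ds$velocity[, , , c3, k])
        RNifti::pixdim(im) <- ds$spacing
        RNifti::writeNifti(im, file.path(path, sprintf("vel_f%03d_c%d.nii.gz", k, c3)))
      }
      im <- RNifti::asNifti(ds$mask[, , , k] * 1)
      RNifti::pixdim(im) <- ds$spacing
      RNifti::writeNifti(im, file.path(path, sprintf("mask_f%03d.nii.gz", k)))
    }
  } else {
    for (k in seq_len(nt)) {
      write_vtk_frame(ds, k, file.path(path, sprintf("frame_%03d.vtk", k)))
    }
  }
  invisible(path)
}

write_vtk_frame <- function(ds, k, file) {
  d <- dim(ds$mask)[1:3]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("lvflow frame %d", k), "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("SPACING %.17g %.17g %.17g", ds$spacing[1], ds$spacing[2], ds$spacing[3]),
               sprintf("ORIGIN %.17g %.17g %.17g", ds$origin[1], ds$origin[2], ds$origin[3]),
               sprintf("POINT_DATA %d", prod(d)),
               "VECTORS velocity double"), con)
  vm <- cbind(as.vector(ds$velocity[, , , 1, k]),
              as.vector(ds$velocity[, , , 2, k]),
              as.vector(ds$velocity[, , , 3, k]))
  writeLines(sprintf("%.17g %.17g %.17g", vm[, 1], vm[, 2], vm[, 3]), con)
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(ds$mask[, , , k])), con)
}

read_vtk_frame <- function(file) {
  ln <- readLines(file)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "", ln[grep("^DIMENSIONS", ln)])), "\\s+")[[1]])
  sp <- as.numeric(strsplit(trimws(sub("SPACING", "", ln[grep("^SPACING", ln)])), "\\s+")[[1]])
  iv <- grep("^VECTORS velocity", ln)
  npt <- prod(dims)
  vm <- do.call(rbind, lapply(strsplit(trimws(ln[(iv + 1):(iv + npt)]), "\\s+"), as.numeric))
  im <- grep("^LOOKUP_TABLE", ln)[1]
  mk <- as.integer(ln[(im + 1):(im + npt)])
  list(dims = dims, spacing = sp,
       velocity = array(vm, c(dims, 3)),
       mask = array(mk == 1L, dims))
}

#' Read a flow dataset
#'
#' Validates grids and converts declared on-disk units (see the `spatial_units`
#' and `velocity_units` fields of the JSON sidecar) to the internal mm / m/s.
#' Missing frame files raise an error naming the first gap.
#'
#' @param path file or directory written by [write_flow_dataset()].
#' @param format the on-disk layout.
#' @return a [flow_dataset()].
#' @export
read_flow_dataset <- function(path,
                              format = c("rds_bundle", "nifti_series", "vtk_series")) {
  format <- match.arg(format)
  if (format == "rds_bundle") {
    x <- readRDS(path)
    m <- x$meta
    return(flow_dataset(x$velocity, x$mask, m$spacing, m$frame_times,
                        m$rr_interval, hematocrit = m$hematocrit,
                        landmarks = x$landmarks,
                        origin = m$origin, orientation = m$orientation))
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  nt <- meta$n_frames
  lf <- length_factor(meta$spatial_units %||% "mm")
  vf <- velocity_factor(meta$velocity_units %||% "m/s")
  vel <- NULL; mask <- NULL
  for (k in seq_len(nt)) {
    if (format == "nifti_series") {
      fm <- file.path(path, sprintf("mask_f%03d.nii.gz", k))
      fv <- file.path(path, sprintf("vel_f%03d_c%d.nii.gz", k, 1:3))
      miss <- c(fm, fv)[!file.exists(c(fm, fv))]
      if (length(miss)) stop(sprintf("format error: frame %d is missing (%s)", k, basename(miss[1])))
      mk <- as.array(RNifti::readNifti(fm)) > 0.5
      d3 <- dim(mk)
      if (is.null(vel)) { vel <- array(0, c(d3, 3, nt)); mask <- array(FALSE, c(d3, nt)) }
      if (!identical(dim(mk), dim(mask)[1:3])) {
        stop(sprintf("shape error: frame %d grid disagrees with frame 1", k))
      }
      for (c3 in 1:3) {
        v <- as.array(RNifti::readNifti(fv[c3]))
        if (!identical(dim(v), d3)) stop(sprintf("shape error: velocity frame %d component %d", k, c3))
        vel[, , , c3, k] <- v * vf
      }
      mask[, , , k] <- mk
    } else {
      fk <- file.path(path, sprintf("frame_%03d.vtk", k))
      if (!file.exists(fk)) stop(sprintf("format error: frame %d is missing (%s)", k, basename(fk)))
      fr <- read_vtk_frame(fk)
      if (is.null(vel)) { vel <- array(0, c(fr$dims, 3, nt)); mask <- array(FALSE, c(fr$dims, nt)) }
      if (!identical(fr$dims, dim(mask)[1:3])) {
        stop(sprintf("shape error: frame %d grid disagrees with frame 1", k))
      }
      vel[, , , , k] <- fr$velocity * vf
      mask[, , , k] <- fr$mask
    }
  }
  lmf <- file.path(path, "landmarks.json")
  lms <- NULL
  if (file.exists(lmf)) {
    lms <- landmarks_from_plain(jsonlite::read_json(lmf, simplifyVector = FALSE))
    lms <- lapply(lms, transform_landmarks, fun = function(p) p * lf)
  }
  flow_dataset(vel, mask, meta$spacing * lf, meta$frame_times, meta$rr_interval,
               hematocrit = meta$hematocrit %||% 0.45, landmarks = lms,
               origin = (meta$origin %||% c(0, 0, 0)) * lf,
               orientation = meta$orientation %||% diag(3))
}

# Pathline polylines as legacy-ASCII VTK polydata; one scalar per line
# encodes the flow-component class (1 df, 2 ri, 3 de, 4 rv, 0 unclassified).
write_pathlines_vtk <- function(tracks, classes, file) {
  npts <- vapply(tracks, nrow, integer(1))
  total <- sum(npts)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "lvflow pathlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", total)), con)
  allp <- do.call(rbind, tracks)
  writeLines(sprintf("%.8g %.8g %.8g", allp[, 1], allp[, 2], allp[, 3]), con)
  writeLines(sprintf("LINES %d %d", length(tracks), length(tracks) + total), con)
  off <- 0L
  for (i in seq_along(tracks)) {
    writeLines(paste(c(npts[i], seq_len(npts[i]) - 1L + off), collapse = " "), con)
    off <- off + npts[i]
  }
  code <- c(df = 1L, ri = 2L, de = 3L, rv = 4L, unclassified = 0L)
  writeLines(c(sprintf("CELL_DATA %d", length(tracks)),
               "SCALARS component int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(code[classes]), con)
}

#' Write a result bundle to a directory
#'
#' Emits the per-frame time series as a CSV (one row per frame), the scalar
#' summaries as JSON, labelled pathlines (when present) as VTK polydata, and
#' a manifest listing every file with its MD5 checksum. Output is
#' deterministic for a fixed bundle.
#'
#' @param bundle a [run_analysis()] result.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)

  ts <- bundle$timeseries
  f <- file.path(out_dir, "timeseries.csv")
  utils::write.csv(format(ts, digits = 10, trim = TRUE, scientific = FALSE), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(bundle$summary, f, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  files <- c(files, f)

  if (!is.null(bundle$pathline_tracks) && length(bundle$pathline_tracks)) {
    f <- file.path(out_dir, "pathlines.vtk")
    write_pathlines_vtk(bundle$pathline_tracks, bundle$pathline_classes, f)
    files <- c(files, f)
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"), pretty = TRUE)
  invisible(manifest)
}
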