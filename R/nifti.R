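#' Minimal NIfTI-1 input/output
#'
#' Single-volume (3-D) and time-series (4-D) NIfTI-1 files with float32 data,
#' written uncompressed (`.nii`) or gzip-compressed (`.nii.gz`).  Only the
#' header fields needed to round-trip simulated volumes are populated: a
#' diagonal voxel-size affine (sform, code 1), dimensions, and datatype.
#' This is deliberately not a general NIfTI implementation; no R NIfTI
#' package is available in the target environment, and the package only needs
#' to exchange its own volumes with standard neuroimaging tools.
#'
#' @param vol numeric array, 3-D or 4-D.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size numeric length-3 voxel dimensions in mm (default 3 mm
#'   isotropic, the resampled resolution typical of group fMRI analyses).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns the
#'   array with attributes `voxel_size`.
#' @export
write_nifti <- function(vol, path, voxel_size = c(3, 3, 3)) {
  stopifnot(is.array(vol), length(dim(vol)) %in% c(3L, 4L))
  nd <- length(dim(vol))
  dims <- rep(1L, 7)
  dims[seq_len(nd)] <- dim(vol)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                     # sizeof_hdr
  writeBin(raw(36), con)                            # unused historic fields
  writeBin(as.integer(c(nd, dims)), con, size = 2)  # dim[8]
  writeBin(raw(14), con)                            # intent_p*, intent_code
  writeBin(16L, con, size = 2)                      # datatype = float32
  writeBin(32L, con, size = 2)                      # bitpix
  writeBin(0L, con, size = 2)                       # slice_start
  pixdim <- c(1, voxel_size, 1, 1, 1, 1)
  writeBin(as.numeric(pixdim), con, size = 4)       # pixdim[8]
  writeBin(as.numeric(352), con, size = 4)          # vox_offset
  writeBin(as.numeric(c(1, 0)), con, size = 4)      # scl_slope, scl_inter
  writeBin(raw(8), con)                             # slice_end..cal_max
  writeBin(raw(20), con)                            # cal_min..glmin
  writeBin(raw(80), con)                            # descrip
  writeBin(raw(24), con)                            # aux_file
  writeBin(c(0L, 1L), con, size = 2)                # qform_code=0, sform_code=1
  writeBin(numeric(6), con, size = 4)               # quaternions + qoffsets
  srow <- rbind(c(voxel_size[1], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4)      # srow_x/y/z
  writeBin(charToRaw(sprintf("%-16s", "")), con)    # intent_name
  magic <- charToRaw("n+1")
  writeBin(c(magic, raw(1)), con)                   # magic
  writeBin(raw(4), con)                             # extension flag
  writeBin(as.numeric(vol), con, size = 4)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sizeof <- readBin(hdr[1:4], "integer", 1, size = 4)
  endian <- "little"
  if (sizeof != 348L) {
    sizeof <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "big")
    if (sizeof != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  dims <- readBin(hdr[41:56], "integer", 8, size = 2, endian = endian)
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4, endian = endian)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  n <- prod(shape)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  vol <- array(vals, dim = shape)
  attr(vol, "voxel_size") <- pixdim[2:4]
  vol
}

#' Read and write BIDS-dialect event tables
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`
#' (seconds), the interchange format for event-related paradigms.
#'
#' @param schedule an [event_schedule] object.
#' @param path output/input `.tsv` path.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  df <- schedule$events
  names(df)[names(df) == "condition"] <- "trial_type"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(df)))
  events <- data.frame(onset = df$onset, duration = df$duration,
                       condition = df$trial_type, stringsAsFactors = FALSE)
  new_event_schedule(events,
                     total_duration = max(events$onset + events$duration),
                     seed = NA_integer_)
}
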