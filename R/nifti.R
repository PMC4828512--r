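# Minimal NIfTI-1 volume I/O (no NIfTI package ships with this stack).
# Only the fields this pipeline relies on are interpreted: dim, datatype,
# pixdim (voxel spacing) and the scaling slope/intercept. All volumes are
# assumed co-registered; the affine is written as a diagonal spacing matrix
# and not interpreted on read.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1L, signed = FALSE),
                 `4` = list(what = "integer", size = 2L, signed = TRUE),
                 `8` = list(what = "integer", size = 4L, signed = TRUE),
                 `16` = list(what = "double", size = 4L, signed = TRUE),
                 `64` = list(what = "double", size = 8L, signed = TRUE))

#' Write a volume as NIfTI-1
#'
#' Data are stored as float64 (or uint8 for 0/1 masks); a \code{.gz} suffix
#' selects gzip compression. Voxel spacing is taken from the
#' \code{"spacing"} attribute when present.
#'
#' @param volume 3D numeric array.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @param spacing voxel spacing in mm (length 3).
#' @export
write_volume <- function(volume, path,
                         spacing = attr(volume, "spacing")) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  d <- dim(volume)
  is_mask <- all(volume %in% c(0L, 1L))
  datatype <- if (is_mask) 2L else 64L
  bitpix <- if (is_mask) 8L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad_raw <- function(n) writeBin(raw(n), con)

  wb(348L, 4L)                                   # sizeof_hdr
  pad_raw(10L + 18L + 4L + 2L)                   # data_type..session_error
  writeBin(charToRaw("r"), con); pad_raw(1L)     # regular, dim_info
  wb(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  wb(numeric(3), 4L)                             # intent_p1..p3
  wb(0L, 2L)                                     # intent_code
  wb(datatype, 2L); wb(bitpix, 2L); wb(0L, 2L)   # datatype, bitpix, slice_start
  wb(as.numeric(c(1, spacing, 0, 0, 0, 0)), 4L)  # pixdim[8]
  wb(352, 4L)                                    # vox_offset
  wb(c(1, 0), 4L)                                # scl_slope, scl_inter
  wb(0L, 2L); pad_raw(1L)                        # slice_end, slice_code
  writeBin(as.raw(2L), con)                      # xyzt_units: mm
  wb(numeric(4), 4L)                             # cal_max..toffset
  wb(c(0L, 0L), 4L)                              # glmax, glmin
  desc <- charToRaw("hippoboost")
  writeBin(c(desc, raw(80L - length(desc))), con)  # descrip
  pad_raw(24L)                                   # aux_file
  wb(0L, 2L); wb(1L, 2L)                         # qform_code, sform_code
  wb(numeric(6), 4L)                             # quatern_b..qoffset_z
  wb(c(spacing[1L], 0, 0, 0), 4L)                # srow_x
  wb(c(0, spacing[2L], 0, 0), 4L)                # srow_y
  wb(c(0, 0, spacing[3L], 0), 4L)                # srow_z
  pad_raw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  pad_raw(4L)                                    # extender
  if (is_mask) writeBin(as.integer(volume), con, size = 1L)
  else writeBin(as.numeric(volume), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Accepts plain and gzip-compressed files, either byte order, and the
#' uint8/int16/int32/float32/float64 data types. The scaling slope and
#' intercept are applied when meaningful.
#'
#' @param path input file.
#' @return 3D numeric array with a \code{"spacing"} attribute (mm).
#' @export
read_volume <- function(path) {
  con <- gzfile(path, "rb") # transparently reads uncompressed files too
  raw_all <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", 16777216L)
    if (!length(chunk)) break
    raw_all <- c(raw_all, chunk)
  }
  close(con)
  if (length(raw_all) < 352L) stop("not a NIfTI-1 file: ", path)

  parse <- function(endian) {
    rc <- rawConnection(raw_all)
    on.exit(close(rc))
    rd <- function(what, n, size, signed = TRUE)
      readBin(rc, what, n = n, size = size, endian = endian, signed = signed)
    hdr <- list()
    hdr$sizeof_hdr <- rd("integer", 1L, 4L)
    if (!identical(hdr$sizeof_hdr, 348L)) return(NULL)
    seek(rc, 40L)
    hdr$dim <- rd("integer", 8L, 2L)
    seek(rc, 70L)
    hdr$datatype <- rd("integer", 1L, 2L)
    hdr$bitpix <- rd("integer", 1L, 2L)
    seek(rc, 76L)
    hdr$pixdim <- rd("double", 8L, 4L)
    hdr$vox_offset <- rd("double", 1L, 4L)
    hdr$scl_slope <- rd("double", 1L, 4L)
    hdr$scl_inter <- rd("double", 1L, 4L)
    seek(rc, 344L)
    hdr$magic <- rawToChar(rd("raw", 3L, 1L))
    hdr
  }
  endian <- "little"
  hdr <- parse("little")
  if (is.null(hdr)) { hdr <- parse("big"); endian <- "big" }
  if (is.null(hdr)) stop("not a NIfTI-1 file (bad header size): ", path)
  if (!hdr$magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  if (hdr$dim[1L] < 3L) stop("expected a 3D volume: ", path)
  d <- hdr$dim[2:4]
  n <- prod(d) * max(1L, prod(pmax(hdr$dim[5:8], 1L)))
  dt <- NIFTI_DT[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", hdr$datatype)

  rc <- rawConnection(raw_all)
  on.exit(close(rc))
  seek(rc, as.integer(round(hdr$vox_offset)))
  data <- readBin(rc, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  data <- as.numeric(data[seq_len(prod(d))])
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0))
    data <- data * hdr$scl_slope + hdr$scl_inter
  out <- array(data, d)
  attr(out, "spacing") <- hdr$pixdim[2:4]
  out
}

#' Read a binary mask
#'
#' Reads a NIfTI-1 volume and validates that every voxel is 0 or 1 within a
#' tolerance of 1e-6 after rounding.
#'
#' @param path input file.
#' @return 0/1 integer array with a \code{"spacing"} attribute.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  r <- round(v)
  if (any(abs(v - r) > 1e-6) || !all(r %in% c(0, 1)))
    stop("volume is not a binary mask (values outside {0,1}): ", path)
  out <- array(as.integer(r), dim(v))
  attr(out, "spacing") <- attr(v, "spacing")
  out
}
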