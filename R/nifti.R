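# Minimal single-file NIfTI-1 (.nii) I/O.
#
# No NIfTI reader is available in the dependency set, so the 348-byte
# NIfTI-1 header is read/written directly. Only the features the pipeline
# needs are supported: uncompressed .nii, sform affine, datatypes uint8,
# int16, int32, float32, float64, scl_slope/scl_inter on read.

NIFTI_DT <- list(
  "2"  = list(what = "integer", size = 1L, signed = FALSE, mode = "integer"),
  "4"  = list(what = "integer", size = 2L, signed = TRUE,  mode = "integer"),
  "8"  = list(what = "integer", size = 4L, signed = TRUE,  mode = "integer"),
  "16" = list(what = "double",  size = 4L, signed = TRUE,  mode = "double"),
  "64" = list(what = "double",  size = 8L, signed = TRUE,  mode = "double")
)

#' Write a 3D or 4D array as an uncompressed NIfTI-1 volume
#'
#' @param data numeric array, 3 or 4 dimensional.
#' @param path output file path ending in `.nii`.
#' @param affine 4x4 voxel-to-world matrix (applied to 0-based voxel
#'   indices), written as the sform.
#' @param pixdim numeric vector of voxel sizes in mm (length 3) optionally
#'   followed by the TR in seconds for 4D data.
#' @param datatype one of `"float64"`, `"float32"`, `"int32"`, `"int16"`,
#'   `"uint8"`. Default `"float64"` so that write/read roundtrips are exact.
#' @param description up to 79 characters stored in the header.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), pixdim = c(3, 3, 3.4375),
                        datatype = "float64", description = "") {
  nd <- length(dim(data))
  if (!(nd %in% c(3L, 4L))) stopf("write_nifti: data must be 3D or 4D, got %dD", nd)
  code <- switch(datatype,
    uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
    stopf("write_nifti: unsupported datatype '%s'", datatype))
  spec <- NIFTI_DT[[as.character(code)]]
  dims <- dim(data)
  dim8 <- rep(1L, 8); dim8[1] <- nd; dim8[1 + seq_len(nd)] <- as.integer(dims)
  pd8 <- rep(0, 8); pd8[1] <- 1
  pd8[2:4] <- pixdim[1:3]
  if (nd == 4L) pd8[5] <- if (length(pixdim) >= 4) pixdim[4] else 1

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")            # sizeof_hdr
  writeBin(raw(10), con)                                      # data_type
  writeBin(raw(18), con)                                      # db_name
  writeBin(0L, con, size = 4, endian = "little")              # extents
  writeBin(0L, con, size = 2, endian = "little")              # session_error
  writeBin(charToRaw("r"), con)                               # regular
  writeBin(raw(1), con)                                       # dim_info
  writeBin(dim8, con, size = 2, endian = "little")            # dim
  writeBin(numeric(3), con, size = 4, endian = "little")      # intent_p1..p3
  writeBin(0L, con, size = 2, endian = "little")              # intent_code
  writeBin(code, con, size = 2, endian = "little")            # datatype
  writeBin(as.integer(spec$size * 8L), con, size = 2, endian = "little") # bitpix
  writeBin(0L, con, size = 2, endian = "little")              # slice_start
  writeBin(pd8, con, size = 4, endian = "little")             # pixdim
  writeBin(352, con, size = 4, endian = "little")             # vox_offset
  writeBin(1, con, size = 4, endian = "little")               # scl_slope
  writeBin(0, con, size = 4, endian = "little")               # scl_inter
  writeBin(0L, con, size = 2, endian = "little")              # slice_end
  writeBin(raw(1), con)                                       # slice_code
  writeBin(as.raw(10L), con)                                  # xyzt_units: mm + s
  writeBin(numeric(4), con, size = 4, endian = "little")      # cal_max..toffset
  writeBin(integer(2), con, size = 4, endian = "little")      # glmax, glmin
  desc <- raw(80)
  db <- utf8ToInt(substr(description, 1, 79))
  if (length(db)) desc[seq_along(db)] <- as.raw(db)
  writeBin(desc, con)                                         # descrip
  writeBin(raw(24), con)                                      # aux_file
  writeBin(0L, con, size = 2, endian = "little")              # qform_code
  writeBin(1L, con, size = 2, endian = "little")              # sform_code
  writeBin(numeric(6), con, size = 4, endian = "little")      # quatern, qoffset
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4, endian = "little") # srow
  writeBin(raw(16), con)                                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)                  # magic
  writeBin(raw(4), con)                                       # extension flag
  if (spec$mode == "integer") {
    writeBin(as.integer(round(data)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 volume
#'
#' @param path path to a `.nii` file.
#' @return a list with `data` (array), `affine` (4x4 sform, or pixdim
#'   diagonal if no sform), `pixdim`, `tr_seconds` (for 4D data) and
#'   `description`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    if (bitwAnd(hdr_size, 0xFFFFFF) == 0) hdr_size <- 348L # swapped
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8, size = 2, endian = endian)
  seek(con, 70)
  code <- readBin(con, "integer", 1, size = 2, endian = endian)
  spec <- NIFTI_DT[[as.character(code)]]
  if (is.null(spec)) stopf("read_nifti: unsupported datatype code %d in %s", code, path)
  seek(con, 76)
  pd8 <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, size = 4, endian = endian)
  seek(con, 148)
  descrip <- readBin(con, "raw", 80)
  seek(con, 252)
  qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 280)
  srow <- readBin(con, "double", 12, size = 4, endian = endian)
  nd <- dim8[1]
  dims <- dim8[1 + seq_len(nd)]
  n <- prod(dims)
  seek(con, vox_offset)
  vals <- readBin(con, spec$what, n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- matrix(srow, 3, 4, byrow = TRUE)
  } else {
    diag(affine)[1:3] <- pd8[2:4]
  }
  dtxt <- rawToChar(descrip[descrip != as.raw(0)])
  list(data = array(vals, dim = dims), affine = affine,
       pixdim = pd8[2:4], tr_seconds = if (nd >= 4) pd8[5] else NA_real_,
       description = dtxt)
}
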