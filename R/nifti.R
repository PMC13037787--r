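#' @include containers.R
NULL

# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No installed R package provides NIfTI in this stack, so the subset needed
# here is implemented directly: 2-D/3-D volumes, datatypes uint8/int16/
# int32/float32/float64, little-endian, no extensions. scl_slope/scl_inter
# are honoured on read; orientation matrices are ignored (voxel grids and
# pixdim spacing are the interface used by this package).

niftiDatatypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "numeric", "numeric"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

niftiOpen <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param asLabelMap if `TRUE`, return a [LabelMap-class] (values must be
#'   non-negative integers); otherwise a [ScanImage-class].
#' @return a `ScanImage` or `LabelMap` with spacing taken from `pixdim`.
#' @export
readNifti <- function(path, asLabelMap = FALSE) {
  con <- niftiOpen(path, "rb")
  on.exit(close(con))
  sizeofHdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeofHdr != 348L) {
    stop("unsupported NIfTI header (expected little-endian sizeof_hdr = 348)",
         call. = FALSE)
  }
  readBin(con, "raw", 36L)                                   # skip to dim
  dimField <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                   # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # bitpix
  readBin(con, "raw", 2L)                                    # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  voxOffset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  sclSlope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  sclInter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 224L)                                  # rest of header
  magic <- rawToChar(readBin(con, "raw", 4L), multiple = FALSE)
  if (!startsWith(magic, "n+1")) {
    stop("not a single-file NIfTI-1 volume (bad magic)", call. = FALSE)
  }
  nd <- dimField[1L]
  if (!(nd %in% c(2L, 3L))) {
    stop(sprintf("only 2-D/3-D volumes supported (dim[0] = %d)", nd), call. = FALSE)
  }
  dims <- dimField[2L:(1L + nd)]
  spec <- niftiDatatypes[niftiDatatypes$code == datatype, ]
  if (nrow(spec) != 1L) {
    stop(sprintf("unsupported NIfTI datatype code %d", datatype), call. = FALSE)
  }
  skip <- voxOffset - 352
  if (skip > 0) readBin(con, "raw", as.integer(skip)) else readBin(con, "raw", 4L)
  n <- prod(dims)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data section", call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(sclSlope) && sclSlope != 0 && !(sclSlope == 1 && sclInter == 0)) {
    vals <- vals * sclSlope + sclInter
  }
  arr <- array(vals, dim = dims)
  spacing <- pixdim[2L:(1L + nd)]
  spacing[spacing <= 0 | !is.finite(spacing)] <- 1
  if (asLabelMap) LabelMap(arr, spacing) else ScanImage(arr, spacing)
}

#' Write a NIfTI-1 volume
#'
#' `LabelMap`s are stored as int32, `ScanImage`s as float32 by default.
#'
#' @param x a [ScanImage-class] or [LabelMap-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"`, `"float64"` or `"int32"`; default chosen
#'   from the class of `x`.
#' @export
writeNifti <- function(x, path, datatype = NULL) {
  isLabel <- is(x, "LabelMap")
  if (!isLabel && !is(x, "ScanImage")) {
    stop("x must be a ScanImage or LabelMap", call. = FALSE)
  }
  if (is.null(datatype)) datatype <- if (isLabel) "int32" else "float32"
  code <- switch(datatype, int32 = 8L, float32 = 16L, float64 = 64L,
                 stop("unsupported datatype", call. = FALSE))
  size <- switch(datatype, int32 = 4L, float32 = 4L, float64 = 8L)
  vals <- x@values
  dims <- dim(vals)
  nd <- length(dims)
  dimField <- rep(1L, 8L)
  dimField[1L] <- nd
  dimField[2L:(1L + nd)] <- dims
  pixdim <- rep(0, 8L)
  pixdim[2L:(1L + nd)] <- x@spacing

  con <- niftiOpen(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L, endian = "little")
  writeBin(raw(36L), con)
  writeBin(as.integer(dimField), con, size = 2L, endian = "little")
  writeBin(raw(14L), con)
  writeBin(code, con, size = 2L, endian = "little")
  writeBin(as.integer(size * 8L), con, size = 2L, endian = "little")  # bitpix
  writeBin(raw(2L), con)
  writeBin(pixdim, con, size = 4L, endian = "little")
  writeBin(352, con, size = 4L, endian = "little")                    # vox_offset
  writeBin(c(1, 0), con, size = 4L, endian = "little")                # scl_slope/inter
  writeBin(raw(224L), con)
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                                              # extension flag
  if (datatype == "int32") {
    writeBin(as.integer(vals), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = size, endian = "little")
  }
  invisible(path)
}
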