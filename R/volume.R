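#' CT volume container
#'
#' A `ct_volume` holds an axial stack of CT/CBCT slices as a 3D array of
#' Hounsfield units with voxel spacing in millimetres. The array is indexed
#' `[row, col, slice]`; the slice axis is always the third dimension and
#' slices are ordered along the acquisition normal (inferior to superior
#' for a standard axial series).
#'
#' @param voxels numeric 3D array `(rows, cols, n_slices)` of HU values.
#' @param spacing numeric length-3 vector `(row_mm, col_mm, slice_mm)`,
#'   all strictly positive.
#' @return An object of class `ct_volume` with elements `voxels` and
#'   `spacing`.
#' @examples
#' v <- ct_volume(array(-1000, c(16, 16, 4)), spacing = c(0.3, 0.3, 0.3))
#' dim(v$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    pd_error("voxels must be a 3D array (rows, cols, n_slices)",
             "pdx_input_error")
  d <- dim(voxels)
  if (d[1] < 16L || d[2] < 16L)
    pd_error("slice dimensions must be at least 16 x 16", "pdx_input_error")
  if (d[3] < 1L)
    pd_error("volume must contain at least one slice", "pdx_input_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    pd_error("spacing must be 3 positive finite numbers", "pdx_input_error")
  if (any(!is.finite(voxels)))
    pd_error("voxel values must be finite", "pdx_input_error")
  structure(list(voxels = voxels,
                 spacing = c(row = spacing[1], col = spacing[2],
                             slice = spacing[3])),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d slices of %d x %d, spacing %.3g/%.3g/%.3g mm\n",
              d[3], d[1], d[2],
              x$spacing["row"], x$spacing["col"], x$spacing["slice"]))
  cat(sprintf("  HU range [%.0f, %.0f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# ---- packed volume container --------------------------------------------
# A simple binary container (magic + dims + spacing + doubles, little
# endian) that round-trips voxels and spacing bit-exactly.

PD_VOLUME_MAGIC <- "PDVOL1"

#' Save a CT volume to a packed binary file
#'
#' The packed format stores dimensions, spacing and the voxel array as
#' little-endian doubles and round-trips bit-exactly through
#' [load_volume_file()].
#'
#' @param volume a [ct_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_volume_file <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(PD_VOLUME_MAGIC, con, nchars = 6, eos = NULL)
  writeBin(as.integer(dim(volume$voxels)), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(volume$spacing), con, size = 8L, endian = "little")
  writeBin(as.numeric(volume$voxels), con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a CT volume from a packed binary file
#'
#' @param path file written by [save_volume_file()].
#' @return A [ct_volume()].
#' @export
load_volume_file <- function(path) {
  if (!file.exists(path))
    pd_error(sprintf("no such volume file: %s", path), "pdx_input_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- tryCatch(readChar(con, 6, useBytes = TRUE), error = function(e) "")
  if (!identical(magic, PD_VOLUME_MAGIC))
    pd_error("not a packed volume file (bad magic)", "pdx_format_error")
  d <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (length(d) != 3L || any(d < 1L))
    pd_error("corrupt packed volume header", "pdx_format_error")
  spacing <- readBin(con, "numeric", n = 3L, size = 8L, endian = "little")
  n <- prod(d)
  vox <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  if (length(vox) != n)
    pd_error("truncated packed volume file", "pdx_format_error")
  ct_volume(array(vox, dim = d), spacing = spacing)
}
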