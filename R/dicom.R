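# Minimal DICOM support: single-frame, uncompressed, little-endian axial
# series. Covers the tags an HU-calibrated CT stack needs (geometry,
# pixel description, rescale) and nothing else. Explicit and implicit VR
# little endian are read; files are written as explicit VR little endian
# with a standard 128-byte preamble.

DICOM_TS_IMPLICIT <- "1.2.840.10008.1.2"
DICOM_TS_EXPLICIT <- "1.2.840.10008.1.2.1"

raw_u16le <- function(x) {
  x <- as.integer(round(x))
  as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
}

raw_u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# pad a string value to even length; UI pads with NUL, text VRs with space
dcm_pad <- function(raw_val, vr) {
  if (length(raw_val) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    raw_val <- c(raw_val, pad)
  }
  raw_val
}

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, elem, vr, raw_val) {
  raw_val <- dcm_pad(raw_val, vr)
  head <- c(raw_u16le(group), raw_u16le(elem), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), raw_u32le(length(raw_val)), raw_val)
  } else {
    c(head, raw_u16le(length(raw_val)), raw_val)
  }
}

dcm_str <- function(group, elem, vr, s) {
  dcm_element(group, elem, vr, charToRaw(s))
}

dcm_us <- function(group, elem, x) {
  dcm_element(group, elem, "US", raw_u16le(x))
}

pd_uid <- function(suffix) {
  paste0("1.2.826.0.1.3680043.9.7656.", suffix)
}

#' Write a CT volume as a synthetic DICOM series
#'
#' Emits one single-frame explicit-VR little-endian DICOM file per axial
#' slice, with geometry, pixel-spacing and rescale tags, so that the
#' package's own reader (and standard DICOM tooling) can load it. This is
#' a deliberately minimal writer intended for phantoms and test fixtures,
#' not for clinical interchange.
#'
#' @param volume a [ct_volume()].
#' @param dir output directory (created if missing).
#' @param rescale_slope,rescale_intercept HU calibration written to the
#'   files; stored pixel values are `(HU - intercept) / slope`, which must
#'   land in the unsigned 16-bit range.
#' @param series_uid series instance UID; a fixed synthetic UID by default.
#' @param origin_mm patient-space position of the first slice's first pixel.
#' @return Character vector of the written file paths, invisibly.
#' @export
write_dicom_series <- function(volume, dir, rescale_slope = 1,
                               rescale_intercept = -1024,
                               series_uid = pd_uid("1.1"),
                               origin_mm = c(0, 0, 0)) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(volume$voxels)
  rows <- d[1]; cols <- d[2]; nz <- d[3]
  study_uid <- pd_uid("1.0")
  paths <- character(nz)
  for (z in seq_len(nz)) {
    hu <- volume$voxels[, , z]
    stored <- round_half_away((hu - rescale_intercept) / rescale_slope)
    if (any(stored < 0) || any(stored > 65535))
      pd_error("stored pixel values out of unsigned 16-bit range",
               "pdx_input_error")
    pix <- raw_u16le(as.vector(t(stored)))  # row-major pixel order

    ts <- dcm_str(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT)
    meta_body <- ts
    meta <- c(dcm_element(0x0002, 0x0000, "UL",
                          raw_u32le(length(meta_body))), meta_body)

    ipp <- sprintf("%g\\%g\\%g", origin_mm[1], origin_mm[2],
                   origin_mm[3] + (z - 1) * volume$spacing["slice"])
    ds <- c(
      dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      dcm_str(0x0008, 0x0018, "UI", pd_uid(sprintf("2.%d", z))),
      dcm_str(0x0008, 0x0060, "CS", "CT"),
      dcm_str(0x0020, 0x000D, "UI", study_uid),
      dcm_str(0x0020, 0x000E, "UI", series_uid),
      dcm_str(0x0020, 0x0013, "IS", sprintf("%d", z)),
      dcm_str(0x0020, 0x0032, "DS", ipp),
      dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_us(0x0028, 0x0002, 1L),
      dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_us(0x0028, 0x0010, rows),
      dcm_us(0x0028, 0x0011, cols),
      dcm_str(0x0028, 0x0030, "DS",
              sprintf("%g\\%g", volume$spacing["row"],
                      volume$spacing["col"])),
      dcm_us(0x0028, 0x0100, 16L),
      dcm_us(0x0028, 0x0101, 16L),
      dcm_us(0x0028, 0x0102, 15L),
      dcm_us(0x0028, 0x0103, 0L),
      dcm_str(0x0028, 0x1052, "DS", sprintf("%g", rescale_intercept)),
      dcm_str(0x0028, 0x1053, "DS", sprintf("%g", rescale_slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    path <- file.path(dir, sprintf("slice_%04d.dcm", z))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
    paths[z] <- path
  }
  invisible(paths)
}

# ---- reading -------------------------------------------------------------

read_u16le <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

read_u32le <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

# Parse one DICOM dataset from raw bytes starting at `pos` (1-based).
# Returns a named list keyed "gggg,eeee" holding raw values plus VR.
parse_dicom_elements <- function(bytes, pos, explicit, stop_after_group = NULL) {
  n <- length(bytes)
  out <- list()
  while (pos + 7L <= n) {
    group <- read_u16le(bytes, pos)
    elem <- read_u16le(bytes, pos + 2L)
    if (!is.null(stop_after_group) && group > stop_after_group) break
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% DICOM_LONG_VRS) {
        len <- read_u32le(bytes, pos + 8L)
        vpos <- pos + 12L
      } else {
        len <- read_u16le(bytes, pos + 6L)
        vpos <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- read_u32le(bytes, pos + 4L)
      vpos <- pos + 8L
    }
    if (len == 4294967295)  # undefined length (sequences) unsupported
      pd_error("unsupported DICOM element with undefined length",
               "pdx_format_error")
    if (vpos + len - 1L > n)
      pd_error("truncated DICOM file", "pdx_format_error")
    key <- sprintf("%04x,%04x", group, elem)
    val <- if (len > 0) bytes[vpos:(vpos + len - 1L)] else raw(0)
    out[[key]] <- list(vr = vr, value = val)
    pos <- vpos + len
  }
  list(elements = out, pos = pos)
}

dcm_get_str <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  gsub("\\x00", "", trimws(rawToChar(v$value)), fixed = TRUE)
}

dcm_get_numvec <- function(el, key) {
  s <- dcm_get_str(el, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}

dcm_get_us <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NULL)
  read_u16le(v$value, 1L)
}

read_dicom_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 16L)
    pd_error(sprintf("not a DICOM file: %s", path), "pdx_format_error")
  ts <- DICOM_TS_EXPLICIT
  pos <- 1L
  if (length(bytes) >= 132L &&
      identical(rawToChar(bytes[129:132]), "DICM")) {
    meta <- parse_dicom_elements(bytes, 133L, explicit = TRUE,
                                 stop_after_group = 0x0002)
    ts <- dcm_get_str(meta$elements, "0002,0010") %||% DICOM_TS_EXPLICIT
    pos <- meta$pos
  }
  explicit <- !identical(ts, DICOM_TS_IMPLICIT)
  if (!ts %in% c(DICOM_TS_IMPLICIT, DICOM_TS_EXPLICIT))
    pd_error(sprintf("unsupported transfer syntax %s in %s", ts, path),
             "pdx_format_error")
  parsed <- parse_dicom_elements(bytes, pos, explicit = explicit)$elements

  nframes <- dcm_get_str(parsed, "0028,0008")
  if (!is.null(nframes) && suppressWarnings(as.integer(nframes)) > 1L)
    pd_error(sprintf("multi-frame DICOM not supported: %s", path),
             "pdx_input_error")

  rows <- dcm_get_us(parsed, "0028,0010")
  cols <- dcm_get_us(parsed, "0028,0011")
  bits <- dcm_get_us(parsed, "0028,0100") %||% 16L
  pixrep <- dcm_get_us(parsed, "0028,0103") %||% 0L
  pix <- parsed[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix))
    pd_error(sprintf("missing image data in %s", path), "pdx_format_error")
  if (bits != 16L)
    pd_error(sprintf("only 16-bit pixel data supported (%s)", path),
             "pdx_format_error")
  vals <- readBin(pix$value, "integer", n = rows * cols, size = 2L,
                  signed = (pixrep == 1L), endian = "little")
  if (length(vals) != rows * cols)
    pd_error(sprintf("pixel data size mismatch in %s", path),
             "pdx_format_error")
  mat <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  slope <- dcm_get_numvec(parsed, "0028,1053")
  intercept <- dcm_get_numvec(parsed, "0028,1052")
  list(
    pixels = mat,
    slope = if (is.null(slope)) NA_real_ else slope[1],
    intercept = if (is.null(intercept)) NA_real_ else intercept[1],
    pixel_spacing = dcm_get_numvec(parsed, "0028,0030"),
    ipp = dcm_get_numvec(parsed, "0020,0032"),
    iop = dcm_get_numvec(parsed, "0020,0037"),
    instance = suppressWarnings(as.integer(dcm_get_str(parsed, "0020,0013"))),
    series_uid = dcm_get_str(parsed, "0020,000e"),
    slice_thickness = dcm_get_numvec(parsed, "0018,0050")
  )
}

#' Load an axial DICOM series as an HU-calibrated CT volume
#'
#' Reads every single-frame DICOM file in a directory, checks that they
#' belong to one series, sorts slices by the projection of the image
#' position on the slice normal (instance number as tie-break), and
#' converts stored values to Hounsfield units via the rescale slope and
#' intercept tags. Missing rescale tags fall back to slope 1 / intercept 0
#' with a warning.
#'
#' @param directory_path directory containing one DICOM series.
#' @return A [ct_volume()].
#' @export
load_dicom_series <- function(directory_path) {
  if (!dir.exists(directory_path))
    pd_error(sprintf("no such directory: %s", directory_path),
             "pdx_input_error")
  files <- list.files(directory_path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    pd_error("empty directory: no DICOM files to read", "pdx_input_error")

  slices <- lapply(files, read_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "<none>",
                        character(1)))
  if (length(uids) > 1L)
    pd_error(sprintf("directory mixes multiple series UIDs: %s",
                     paste(uids, collapse = ", ")), "pdx_ambiguous_series")

  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    pd_error("slices have inconsistent dimensions", "pdx_format_error")

  # primary sort key: projection of ImagePositionPatient on the normal
  keys <- vapply(slices, function(s) {
    if (is.null(s$ipp) || is.null(s$iop) || length(s$iop) != 6L)
      return(NA_real_)
    normal <- c(
      s$iop[2] * s$iop[6] - s$iop[3] * s$iop[5],
      s$iop[3] * s$iop[4] - s$iop[1] * s$iop[6],
      s$iop[1] * s$iop[5] - s$iop[2] * s$iop[4])
    sum(s$ipp * normal)
  }, numeric(1))
  inst <- vapply(slices, function(s) {
    v <- s$instance
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_integer_ else v
  }, integer(1))
  ord <- order(keys, inst, na.last = TRUE)
  slices <- slices[ord]
  keys <- keys[ord]

  slope <- slices[[1]]$slope
  intercept <- slices[[1]]$intercept
  if (is.na(slope) || is.na(intercept)) {
    warning("rescale slope/intercept tags missing; assuming slope=1, ",
            "intercept=0 (values treated as HU)")
    if (is.na(slope)) slope <- 1
    if (is.na(intercept)) intercept <- 0
  }

  vox <- vapply(slices, function(s) slope * s$pixels + intercept,
                matrix(0, dims[1, 1], dims[2, 1]))

  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps) || length(ps) != 2L) {
    warning("PixelSpacing tag missing; assuming 1 mm pixels")
    ps <- c(1, 1)
  }
  dz <- NA_real_
  if (length(slices) > 1L && all(is.finite(keys)))
    dz <- stats::median(abs(diff(keys)))
  if (!is.finite(dz) || dz <= 0) {
    st <- slices[[1]]$slice_thickness
    if (!is.null(st) && is.finite(st[1]) && st[1] > 0) {
      dz <- st[1]
    } else {
      warning("slice increment undetermined; assuming 1 mm")
      dz <- 1
    }
  }
  ct_volume(vox, spacing = c(ps[1], ps[2], dz))
}
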