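#' Write a 2D scalar image as 16-bit grayscale TIFF
#'
#' Maps intensities linearly from the HU window `(lo, hi)` onto the
#' unsigned 16-bit range: `lo` to 0, `hi` to 65535, values clipped outside
#' the window. Fractional codes are rounded half away from zero. With
#' `window = "auto"` the image's own min/max are used; a constant image
#' then writes all zeros with a warning rather than dividing by zero.
#'
#' @param image finite numeric matrix (e.g. a panoramic image in HU).
#' @param path output path; must end in `.tif` or `.tiff` (the lossless
#'   16-bit container this package writes).
#' @param window length-2 numeric `(lo, hi)` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, window = "auto") {
  if (!is.matrix(image) || any(!is.finite(image)))
    pd_error("image must be a finite numeric matrix", "pdx_input_error")
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    pd_error("write_image writes 16-bit grayscale TIFF; use a .tif/.tiff path",
             "pdx_input_error")
  if (identical(window, "auto")) window <- range(image)
  lo <- window[1]; hi <- window[2]
  if (hi <= lo) {
    if (hi == lo) {
      warning("constant image with auto window; writing all zeros")
      codes <- matrix(0, nrow(image), ncol(image))
    } else {
      pd_error("window must satisfy lo < hi", "pdx_input_error")
    }
  } else {
    codes <- (image - lo) / (hi - lo) * 65535
    codes <- pmin(pmax(codes, 0), 65535)
    codes <- round_half_away(codes)
  }
  tiff::writeTIFF(codes / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read back a 16-bit grayscale TIFF as integer codes
#'
#' Inverse of the quantisation in [write_image()]: returns the stored
#' 16-bit codes (0..65535) as a numeric matrix.
#'
#' @param path a TIFF written by [write_image()].
#' @return numeric matrix of pixel codes.
#' @export
read_image_codes <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  round(x * 65535)
}

#' Export sampled curves as CSV
#'
#' Writes one row per curve sample with columns
#' `curve_id, sample_index, t, x, y`. Curve ids follow the offset index
#' convention (0 = the fitted arch curve, negative/positive = offsets).
#'
#' @param family an offset family from [offset_curves()], or a single
#'   sampled polyline (matrix with columns x, y) which is written as
#'   curve 0.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(family, path) {
  if (is.matrix(family))
    family <- list(curves = list(family), k = 0L,
                   m = nrow(family) - 1L)
  m <- family$m
  tt <- seq(0, 1, length.out = m + 1L)
  rows <- lapply(seq_along(family$curves), function(i) {
    cur <- family$curves[[i]]
    data.frame(curve_id = family$k[i], sample_index = seq_len(m + 1L) - 1L,
               t = tt, x = cur[, 1], y = cur[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export a curve fit as JSON
#'
#' Serialises the fitted control points, initial/final cost and the
#' configuration used, so a run can be reproduced exactly. Costs are in
#' pixels of the reference slice.
#'
#' @param fit a [fit_bezier()] result.
#' @param path output JSON path.
#' @param extra optional named list merged into the output (e.g. provenance).
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, extra = list()) {
  obj <- c(list(
    control_points = unname(fit$curve$control_points),
    degree = fit$curve$degree,
    f_initial = fit$f_initial,
    f_final = fit$f_final,
    n_iterations = fit$n_iterations,
    converged = fit$converged,
    cost_units = "pixels",
    config = fit$config
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
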