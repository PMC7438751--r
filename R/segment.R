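# Dental-arch segmentation: HU thresholding, reference-slice selection,
# morphological connection, Gaussian smoothing, largest component.

#' Segmentation configuration
#'
#' Parameters of the arch-mask chain. Defaults follow the standard
#' enamel-segmentation recipe: a 1500 HU global threshold (dental enamel is
#' the brightest dental tissue), a 20 x 20 px rectangular dilation to bridge
#' gaps left by missing teeth, and a sigma = 4 px Gaussian smoothing of the
#' binary mask re-binarised at the symmetric 0.5 level.
#'
#' @param threshold_hu global threshold in HU (voxels >= threshold kept).
#' @param dilation_size integer length-2 `(rows, cols)` of the all-ones
#'   structuring element; origin at the floor-centre for even sizes.
#' @param gaussian_sigma Gaussian standard deviation in pixels.
#' @param rebinarize_level level in (0, 1) at which the blurred mask is
#'   re-binarised (strictly greater than the level -> foreground).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(threshold_hu = 1500,
                                dilation_size = c(20L, 20L),
                                gaussian_sigma = 4,
                                rebinarize_level = 0.5) {
  if (!is.finite(threshold_hu))
    pd_error("threshold_hu must be finite", "pdx_input_error")
  dilation_size <- as.integer(rep(dilation_size, length.out = 2L))
  if (any(dilation_size < 1L))
    pd_error("dilation_size components must be >= 1", "pdx_input_error")
  if (!is.finite(gaussian_sigma) || gaussian_sigma <= 0)
    pd_error("gaussian_sigma must be > 0", "pdx_input_error")
  if (!is.finite(rebinarize_level) || rebinarize_level <= 0 ||
      rebinarize_level >= 1)
    pd_error("rebinarize_level must lie in (0, 1)", "pdx_input_error")
  structure(list(threshold_hu = threshold_hu,
                 dilation_size = dilation_size,
                 gaussian_sigma = gaussian_sigma,
                 rebinarize_level = rebinarize_level),
            class = "segmentation_config")
}

#' Threshold a volume at a Hounsfield level
#'
#' @param volume a [ct_volume()].
#' @param threshold_hu threshold; voxels with HU `>=` the threshold are
#'   foreground (the printed limit value itself stays in-mask).
#' @return logical 3D array of the volume's shape.
#' @export
threshold_volume <- function(volume, threshold_hu = 1500) {
  stopifnot(inherits(volume, "ct_volume"))
  volume$voxels >= threshold_hu
}

#' Select the reference axial slice
#'
#' Returns the index of the slice with the most foreground voxels — in a
#' dental scan, the slice cutting through the tips of the teeth. Ties go
#' to the smallest index.
#'
#' @param binary_volume logical 3D array from [threshold_volume()].
#' @return integer slice index (1-based).
#' @export
select_reference_slice <- function(binary_volume) {
  counts <- apply(binary_volume, 3L, sum)
  if (sum(counts) == 0)
    pd_error("no enamel-range voxels; check threshold/units",
             "pdx_empty_segmentation")
  which.max(counts)  # which.max takes the first maximum: smallest index
}

#' Bridge disjoint tooth regions by morphological dilation
#'
#' Dilates the mask with an all-ones rectangular structuring element
#' (default 20 x 20 px, origin at floor-centre) so regions separated by
#' missing teeth merge into one arch. Dilation is extensive: the output is
#' always a superset of the input.
#'
#' @param mask logical matrix.
#' @param cfg a [segmentation_config()].
#' @return logical matrix.
#' @export
connect_regions <- function(mask, cfg = segmentation_config()) {
  kern <- matrix(1, cfg$dilation_size[1], cfg$dilation_size[2])
  out <- EBImage::dilate(mask * 1, kern)
  matrix(out > 0.5, nrow(mask), ncol(mask))
}

#' Smooth a binary mask with a Gaussian filter
#'
#' Casts the mask to {0,1} reals, blurs with a Gaussian of the configured
#' sigma, and re-binarises (value strictly greater than
#' `rebinarize_level`). Smooths jagged dilation boundaries before
#' skeletonisation; an isolated pixel disappears because the blurred
#' impulse peak (about `1/(2*pi*sigma^2)`) is far below the level.
#'
#' @param mask logical matrix.
#' @param cfg a [segmentation_config()].
#' @return logical matrix.
#' @export
smooth_mask <- function(mask, cfg = segmentation_config()) {
  g <- EBImage::gblur(mask * 1, sigma = cfg$gaussian_sigma)
  matrix(g > cfg$rebinarize_level, nrow(mask), ncol(mask))
}

#' Keep only the largest connected component
#'
#' Components use 8-connectivity. Ties between equal-sized components go
#' to the one containing the smallest pixel in row-major (top-left raster)
#' order.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return logical matrix containing exactly one component.
#' @export
largest_component <- function(mask) {
  if (!any(mask))
    pd_error("empty mask: no component to select", "pdx_empty_segmentation")
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))[1]  # labels are raster-ordered
  lab == best
}

#' Segment the dental arch from a CT volume
#'
#' Runs the full mask chain: global HU threshold, reference-slice
#' selection, rectangular dilation, Gaussian smoothing, largest
#' 8-connected component. Returns the reference slice index together with
#' the final single-component arch mask.
#'
#' @param volume a [ct_volume()].
#' @param cfg a [segmentation_config()].
#' @return list with elements `slice_index`, `mask` (final arch mask) and
#'   `stages` (named list of the intermediate masks: `threshold`,
#'   `dilated`, `smoothed`).
#' @export
segment_arch <- function(volume, cfg = segmentation_config()) {
  sp <- volume$spacing
  if (abs(sp["row"] - sp["col"]) / max(sp["row"], sp["col"]) > 0.1)
    warning("row/col pixel spacing differs by more than 10%; ",
            "the 2D arch fit assumes near-isotropic slices")
  bv <- threshold_volume(volume, cfg$threshold_hu)
  z <- select_reference_slice(bv)
  thr <- bv[, , z]
  dil <- connect_regions(thr, cfg)
  smo <- smooth_mask(dil, cfg)
  if (!any(smo))
    pd_error("segmentation vanished after smoothing; check parameters",
             "pdx_empty_segmentation")
  final <- largest_component(smo)
  list(slice_index = z, mask = final,
       stages = list(threshold = thr, dilated = dil, smoothed = smo))
}
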