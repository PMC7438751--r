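# Offset-curve family and average-intensity-projection panoramic synthesis.

#' Parallel offset curves of the fitted arch
#'
#' Samples the curve at `t_i = i/m`, computes the unit normal as the
#' derivative rotated 90 degrees counterclockwise
#' (`(dx, dy) -> (-dy, dx)`, normalised), and builds `2K + 1` sampled
#' polylines: curve `k` has points `B(t_i) + k * q * N(t_i)` for
#' `k = -K .. +K`. Curve `k = 0` is the fitted Bezier itself. Samples
#' where the derivative vanishes (cusps) reuse the nearest
#' non-degenerate sample's normal.
#'
#' @param curve a [bezier_curve()] of degree >= 1.
#' @param q offset spacing between neighbouring curves, in pixels (> 0).
#' @param n_offsets_per_side K, the number of offset curves on each side.
#' @param m_samples sampling density m (each polyline has `m + 1` points).
#' @return An `offset_family`: list with `curves` (list of `(m+1) x 2`
#'   matrices ordered k = -K..K), `k` (offset indices), `q`,
#'   `central_index` (position of k = 0) and `m`.
#' @export
offset_curves <- function(curve, q = 2, n_offsets_per_side = 5L,
                          m_samples = 1000L) {
  if (q <= 0) pd_error("offset spacing q must be > 0", "pdx_input_error")
  K <- as.integer(n_offsets_per_side)
  if (K < 0L) pd_error("n_offsets_per_side must be >= 0", "pdx_input_error")
  t <- seq(0, 1, length.out = m_samples + 1L)
  b <- bezier_eval(curve, t)
  d <- bezier_derivative(curve, t)
  nrm <- sqrt(rowSums(d^2))
  good <- nrm > 1e-12
  if (!any(good))
    pd_error("degenerate curve: derivative vanishes everywhere",
             "pdx_degenerate_curve")
  if (!all(good)) {
    # reuse the nearest non-degenerate sample's direction
    gi <- which(good)
    for (i in which(!good)) {
      j <- gi[which.min(abs(gi - i))]
      d[i, ] <- d[j, ]
      nrm[i] <- nrm[j]
    }
  }
  normal <- cbind(-d[, 2], d[, 1]) / nrm
  ks <- (-K):K
  curves <- lapply(ks, function(k) {
    out <- b + k * q * normal
    colnames(out) <- c("x", "y")
    out
  })
  structure(list(curves = curves, k = ks, q = q, central_index = K + 1L,
                 m = as.integer(m_samples)),
            class = "offset_family")
}

#' @export
print.offset_family <- function(x, ...) {
  cat(sprintf("offset_family: %d curves (k = %d..%d), q = %g px, %d samples\n",
              length(x$curves), min(x$k), max(x$k), x$q, x$m + 1L))
  invisible(x)
}

#' Sample an axial slice along a polyline
#'
#' Bilinear interpolation of the slice at each sample point; samples
#' falling outside the slice take the air value -1000 HU.
#'
#' @param slice_image numeric matrix (one axial slice, HU).
#' @param polyline numeric matrix with columns x, y (pixel coordinates,
#'   1-based, x = column).
#' @param method `"bilinear"` or `"nearest"`.
#' @param fill out-of-bounds fill value.
#' @return numeric vector of length `nrow(polyline)`.
#' @export
sample_slice <- function(slice_image, polyline, method = "bilinear",
                         fill = -1000) {
  x <- polyline[, 1]; y <- polyline[, 2]
  if (identical(method, "nearest")) {
    xr <- round_half_away(x); yr <- round_half_away(y)
    out <- rep(fill, length(x))
    inb <- xr >= 1 & xr <= ncol(slice_image) & yr >= 1 & yr <= nrow(slice_image)
    out[inb] <- slice_image[cbind(yr[inb], xr[inb])]
    out
  } else {
    bilinear_sample(slice_image, x, y, fill = fill)
  }
}

#' Synthesize the panoramic image by average intensity projection
#'
#' For every axial slice `z` and sample index `i`, the panoramic pixel is
#' the mean over the offset curves `k` of the slice sampled along curve
#' `k` at index `i`. Rows follow the volume's slice order; columns run
#' along the arch from the image-left end of the fitted curve.
#'
#' @param volume a [ct_volume()].
#' @param family an [offset_curves()] family.
#' @param method interpolation passed to [sample_slice()].
#' @return A `panoramic_image`: list with `pixels`
#'   (`n_slices x (m + 1)` HU matrix) and `provenance`.
#' @export
reconstruct_panoramic <- function(volume, family, method = "bilinear") {
  stopifnot(inherits(volume, "ct_volume"), inherits(family, "offset_family"))
  nz <- dim(volume$voxels)[3]
  ncurves <- length(family$curves)
  npts <- family$m + 1L
  allpts <- do.call(rbind, family$curves)  # (ncurves * npts) x 2
  pano <- matrix(NA_real_, nz, npts)
  for (z in seq_len(nz)) {
    prof <- sample_slice(volume$voxels[, , z], allpts, method = method)
    pano[z, ] <- rowMeans(matrix(prof, nrow = npts, ncol = ncurves))
  }
  structure(list(pixels = pano,
                 provenance = list(q = family$q, k_range = range(family$k),
                                   m = family$m, interpolation = method,
                                   row_order = "volume slice order",
                                   units = "HU")),
            class = "panoramic_image")
}

#' @export
print.panoramic_image <- function(x, ...) {
  cat(sprintf("panoramic_image: %d x %d px, HU range [%.0f, %.0f]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = c(class(e)[!class(e) %in%
                                             c("simpleError", "error",
                                               "condition")],
                                  "pdx_stage_error", "panodont_error")))
  })
}

#' Run the full panoramic reconstruction pipeline
#'
#' Composes the whole chain on a CT/CBCT volume: arch segmentation
#' (threshold, reference slice, dilation, smoothing, largest component),
#' medial-axis skeleton, branch pruning/ordering, Bezier fit, offset
#' family, and average-intensity-projection synthesis. Deterministic
#' given the configuration (including its seed).
#'
#' @param volume a [ct_volume()].
#' @param config a [pipeline_config()] (defaults reproduce the standard
#'   recipe: 1500 HU, 20 x 20 dilation, sigma 4, m = 1000, 11 control
#'   points, q = 2, K = 5).
#' @return list with `panoramic` ([reconstruct_panoramic()] output),
#'   `fit` ([fit_bezier()] result) and `diagnostics` (reference slice
#'   index, masks, skeleton, offset family, resolved config).
#' @export
run_pipeline <- function(volume, config = pipeline_config()) {
  seg_cfg <- segmentation_config(config$threshold_hu, config$dilation_size,
                                 config$gaussian_sigma,
                                 config$rebinarize_level)
  seg <- with_stage("segment", segment_arch(volume, seg_cfg))
  skel_px <- with_stage("skeleton", medial_axis(seg$mask))
  skel <- with_stage("skeleton", prune_and_order(skel_px))
  fcfg <- fit_config(config$n_control_points, config$m_samples,
                     config$max_iter, config$tol, config$seed,
                     config$init_mode)
  fit <- with_stage("bezier", fit_bezier(skel, fcfg))
  family <- with_stage("panoramic",
                       offset_curves(fit$curve, config$offset_q,
                                     config$offsets_per_side,
                                     config$m_samples))
  pano <- with_stage("panoramic",
                     reconstruct_panoramic(volume, family,
                                           method = config$interpolation))
  list(panoramic = pano, fit = fit,
       diagnostics = list(slice_index = seg$slice_index, mask = seg$mask,
                          stages = seg$stages, skeleton_pixels = skel_px,
                          skeleton = skel, family = family,
                          config = config))
}
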