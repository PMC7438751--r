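# Synthetic CBCT-like dental phantom with known arch geometry.

#' Phantom specification
#'
#' Describes a synthetic axial CBCT-like volume: air background, a
#' soft-tissue ellipse, a bone-density band following a known Bezier arch
#' curve, and tooth cylinders (enamel-density discs stacked across a
#' central slab of slices) centred at equally spaced arc-length fractions
#' of the arch. Truncated Gaussian HU noise is added; the truncation (at
#' `noise_clip_sigmas` standard deviations) guarantees no bone or
#' soft-tissue voxel ever crosses the 1500 HU enamel threshold and no
#' tooth voxel ever drops below it, so segmentation outcomes are
#' deterministic.
#'
#' The default geometry (256 x 256 x 60, 14 teeth of radius 3 px on a
#' ~110 px arch) keeps tests fast while preserving the property that a
#' missing adjacent pair of teeth leaves a gap (~17.6 px) that a 20 x 20
#' dilation can still bridge, while neighbouring teeth stay disconnected
#' (~1.8 px gaps) before dilation. The truth arch is a deliberately
#' asymmetric degree-4 Bezier: real dental arches are not parabolas, so a
#' low-degree fit should underfit it, as it does on patients.
#'
#' @param n_slices,rows,cols volume dimensions.
#' @param arch_control_points control points of the ground-truth arch
#'   Bezier (degree 4 by default).
#' @param n_teeth number of teeth along the arch.
#' @param tooth_radius_px tooth disc radius in pixels.
#' @param tooth_hu,bone_hu,soft_tissue_hu,air_hu tissue intensities;
#'   teeth must be at or above 1500 HU and bone below it.
#' @param missing_teeth integer indices (1-based, 1 = image-left end) of
#'   teeth to omit.
#' @param noise_sigma_hu Gaussian noise standard deviation.
#' @param noise_clip_sigmas truncation of the noise in sigmas.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 60L, rows = 256L, cols = 256L,
                         arch_control_points = rbind(c(96.9, 157.2),
                                                     c(102.4, 115.3),
                                                     c(126.1, 97.1),
                                                     c(149.8, 118.9),
                                                     c(158.9, 153.5)),
                         n_teeth = 14L, tooth_radius_px = 3,
                         tooth_hu = 2200, bone_hu = 900,
                         soft_tissue_hu = 40, air_hu = -1000,
                         missing_teeth = integer(0),
                         noise_sigma_hu = 30, noise_clip_sigmas = 4,
                         seed = 0L) {
  if (tooth_hu < 1500 || bone_hu >= 1500)
    pd_error("phantom needs tooth_hu >= 1500 > bone_hu so enamel (and only
 enamel) survives the threshold", "pdx_input_error")
  if (n_teeth < 1L)
    pd_error("n_teeth must be >= 1", "pdx_input_error")
  hu <- c(tooth_hu, bone_hu, soft_tissue_hu, air_hu)
  if (any(!is.finite(hu)))
    pd_error("all HU values must be finite", "pdx_input_error")
  if (noise_sigma_hu < 0 || noise_clip_sigmas <= 0)
    pd_error("noise parameters must be non-negative", "pdx_input_error")
  clip <- noise_sigma_hu * noise_clip_sigmas
  if (bone_hu + clip >= 1500 || tooth_hu - clip < 1500)
    pd_error("noise clip too wide: thresholding would be non-deterministic",
             "pdx_input_error")
  structure(list(n_slices = as.integer(n_slices), rows = as.integer(rows),
                 cols = as.integer(cols),
                 arch_control_points = as.matrix(arch_control_points),
                 n_teeth = as.integer(n_teeth),
                 tooth_radius_px = tooth_radius_px, tooth_hu = tooth_hu,
                 bone_hu = bone_hu, soft_tissue_hu = soft_tissue_hu,
                 air_hu = air_hu,
                 missing_teeth = as.integer(missing_teeth),
                 noise_sigma_hu = noise_sigma_hu,
                 noise_clip_sigmas = noise_clip_sigmas,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Named phantom presets
#'
#' `"default"` is the standard desk-scale phantom; `"missing-teeth"`
#' removes an adjacent pair (indices 6 and 7) to emulate a patient with
#' missing teeth; `"full-scale"` doubles the geometry to 512 x 512 slices
#' with a 250-slice stack, the size range of clinical CBCT series.
#'
#' @param preset preset name.
#' @param seed noise seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("default", "missing-teeth",
                                      "full-scale"), seed = 0L) {
  preset <- match.arg(preset)
  switch(preset,
    "default" = phantom_spec(seed = seed),
    "missing-teeth" = phantom_spec(missing_teeth = c(6L, 7L), seed = seed),
    "full-scale" = {
      cps <- (phantom_spec()$arch_control_points - 128) * 2 + 256
      phantom_spec(n_slices = 250L, rows = 512L, cols = 512L,
                   arch_control_points = cps, tooth_radius_px = 6,
                   seed = seed)
    })
}

# dense arc-length table of a bezier curve: list(t, pts, s (cumulative), L)
arc_table <- function(curve, n_dense = 4000L) {
  t <- seq(0, 1, length.out = n_dense + 1L)
  pts <- bezier_eval(curve, t)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  list(t = t, pts = pts, s = s, L = s[length(s)])
}

#' Generate a synthetic dental-arch phantom volume
#'
#' Builds the volume described by a [phantom_spec()] and returns it
#' together with the ground truth needed to score reconstructions: the
#' arch curve, each tooth's arc-length fraction, parameter and centre,
#' and the slice ranges of the bone band and tooth slab.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [ct_volume()], 0.25 mm isotropic) and
#'   `truth`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  curve <- bezier_curve(spec$arch_control_points)
  at <- arc_table(curve)

  fr <- (seq_len(spec$n_teeth) - 0.5) / spec$n_teeth
  tooth_t <- stats::approx(at$s, at$t, xout = fr * at$L)$y
  centers <- bezier_eval(curve, tooth_t)

  r <- spec$tooth_radius_px
  if (any(centers[, 1] < r + 2) || any(centers[, 1] > spec$cols - r - 1) ||
      any(centers[, 2] < r + 2) || any(centers[, 2] > spec$rows - r - 1))
    pd_error("tooth discs overlap the image border; shrink the arch",
             "pdx_input_error")

  nr <- spec$rows; nc <- spec$cols
  px <- matrix(rep(seq_len(nc), each = nr), nr, nc)   # x = column
  py <- matrix(rep(seq_len(nr), times = nc), nr, nc)  # y = row

  # soft-tissue ellipse roughly centred on the arch
  cx <- mean(range(at$pts[, 1]))
  cy <- mean(range(at$pts[, 2]))
  rx <- (diff(range(at$pts[, 1])) / 2 + 0.25 * nc)
  ry <- (diff(range(at$pts[, 2])) / 2 + 0.25 * nr)
  soft <- ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1

  # bone band: pixels within halfwidth of the arch polyline
  halfwidth <- 10
  dense <- at$pts[seq(1, nrow(at$pts), by = 8), ]  # ~500 samples suffice
  box <- soft  # limit distance computation to the ellipse
  cand <- which(box &
                  px >= min(at$pts[, 1]) - halfwidth - 2 &
                  px <= max(at$pts[, 1]) + halfwidth + 2 &
                  py >= min(at$pts[, 2]) - halfwidth - 2 &
                  py <= max(at$pts[, 2]) + halfwidth + 2)
  bone <- matrix(FALSE, nr, nc)
  if (length(cand) > 0L) {
    q <- cbind(px[cand], py[cand])
    ni <- nearest_indices(q, dense)
    d <- sqrt(rowSums((q - dense[ni, , drop = FALSE])^2))
    bone[cand[d <= halfwidth]] <- TRUE
  }

  teeth <- matrix(FALSE, nr, nc)
  keep <- setdiff(seq_len(spec$n_teeth), spec$missing_teeth)
  for (i in keep) {
    teeth <- teeth | ((px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= r^2)
  }

  base <- matrix(spec$air_hu, nr, nc)
  base[soft] <- spec$soft_tissue_hu
  bone_slice <- base; bone_slice[bone] <- spec$bone_hu
  tooth_slice <- bone_slice; tooth_slice[teeth] <- spec$tooth_hu

  nz <- spec$n_slices
  slab <- seq.int(max(1L, floor(nz / 3)), min(nz, ceiling(2 * nz / 3)))
  bone_range <- seq.int(max(1L, floor(nz / 6)), min(nz, ceiling(5 * nz / 6)))

  vox <- array(0, c(nr, nc, nz))
  for (z in seq_len(nz)) {
    vox[, , z] <- if (z %in% slab) tooth_slice
                  else if (z %in% bone_range) bone_slice
                  else base
  }
  if (spec$noise_sigma_hu > 0) {
    clip <- spec$noise_sigma_hu * spec$noise_clip_sigmas
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(vox), 0, spec$noise_sigma_hu))
    vox <- vox + pmin(pmax(noise, -clip), clip)
  }

  truth <- list(arch_curve = curve, arc_length = at$L,
                tooth_fractions = fr, tooth_t = tooth_t,
                tooth_centers = centers,
                missing_teeth = spec$missing_teeth,
                present_teeth = keep,
                tooth_slab = slab, bone_slices = bone_range,
                spec = spec)
  list(volume = ct_volume(vox, spacing = c(0.25, 0.25, 0.25)),
       truth = truth)
}

#' Mean distance from a fitted curve to the ground-truth arch
#'
#' Evaluates the fitted curve at `n_eval` uniform parameters and averages
#' the distance from each point to the nearest point of a densely sampled
#' ground-truth curve.
#'
#' @param curve fitted [bezier_curve()].
#' @param truth ground truth from [generate_phantom()] (or any list with
#'   an `arch_curve` element).
#' @param n_eval number of evaluation parameters.
#' @param n_dense minimum density of the ground-truth sampling; rounded up
#'   to a multiple of `n_eval - 1` so the evaluation parameters are a
#'   subset of the reference parameters (identical curves then score an
#'   exact zero).
#' @return mean distance in pixels.
#' @export
arch_distance <- function(curve, truth, n_eval = 200L, n_dense = 4000L) {
  n_dense <- (n_eval - 1L) * ceiling(n_dense / (n_eval - 1L))
  ref <- bezier_eval(truth$arch_curve,
                     seq(0, 1, length.out = n_dense + 1L))
  q <- bezier_eval(curve, seq(0, 1, length.out = n_eval))
  ni <- nearest_indices(q, ref)
  mean(sqrt(rowSums((q - ref[ni, , drop = FALSE])^2)))
}
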