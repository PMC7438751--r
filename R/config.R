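# Pipeline configuration: defaults, YAML file parsing, CLI overrides.

pd_default_config <- function() {
  list(
    threshold_hu = 1500,
    dilation_size = c(20L, 20L),
    gaussian_sigma = 4,
    rebinarize_level = 0.5,
    n_control_points = 11L,
    m_samples = 1000L,
    max_iter = 500L,
    tol = 1e-6,
    seed = 0L,
    init_mode = "skeleton_uniform",
    offset_q = 2,
    offsets_per_side = 5L,
    interpolation = "bilinear"
  )
}

#' Pipeline configuration
#'
#' Bundles the segmentation, fit and offset settings used by
#' [run_pipeline()]. All defaults are the standard recipe: 1500 HU
#' threshold, 20 x 20 px dilation, Gaussian sigma 4 px, m = 1000 curve
#' samples, 11 control points, offset spacing q = 2 px with K = 5 curves
#' per side (11 curves, about 20 px of arch thickness — the same scale as
#' the dilation element).
#'
#' @param ... named settings overriding the defaults; unknown names are
#'   rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  validate_pipeline_config(merge_config(pd_default_config(), overrides))
}

merge_config <- function(base, overrides) {
  if (length(overrides) == 0L) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(!nzchar(nms)))
    pd_error("configuration overrides must be named", "pdx_input_error")
  unknown <- setdiff(nms, names(base))
  if (length(unknown) > 0L)
    pd_error(sprintf("unknown configuration key(s): %s. Valid keys: %s",
                     paste(unknown, collapse = ", "),
                     paste(names(base), collapse = ", ")),
             "pdx_input_error")
  base[nms] <- overrides
  base
}

validate_pipeline_config <- function(cfg) {
  # delegates range checks to the component constructors
  seg <- segmentation_config(cfg$threshold_hu, cfg$dilation_size,
                             cfg$gaussian_sigma, cfg$rebinarize_level)
  cfg$dilation_size <- seg$dilation_size
  fit <- fit_config(cfg$n_control_points, cfg$m_samples, cfg$max_iter,
                    cfg$tol, cfg$seed, cfg$init_mode)
  cfg$n_control_points <- fit$n_control_points
  cfg$m_samples <- fit$m_samples
  if (!is.finite(cfg$offset_q) || cfg$offset_q <= 0)
    pd_error("offset_q must be > 0", "pdx_input_error")
  cfg$offsets_per_side <- as.integer(cfg$offsets_per_side)
  if (cfg$offsets_per_side < 0L)
    pd_error("offsets_per_side must be >= 0", "pdx_input_error")
  if (!cfg$interpolation %in% c("bilinear", "nearest"))
    pd_error("interpolation must be 'bilinear' or 'nearest'",
             "pdx_input_error")
  structure(cfg, class = "pipeline_config")
}

#' Resolve a pipeline configuration from file and overrides
#'
#' Precedence is overrides (e.g. command-line flags) over file values over
#' package defaults. The file is flat YAML whose keys mirror
#' [pipeline_config()]; unknown keys in either source are rejected with
#' the list of valid keys.
#'
#' @param file optional YAML file path.
#' @param overrides named list of explicit settings.
#' @return A validated `pipeline_config`.
#' @export
parse_config <- function(file = NULL, overrides = list()) {
  cfg <- pd_default_config()
  if (!is.null(file)) {
    if (!file.exists(file))
      pd_error(sprintf("no such config file: %s", file), "pdx_input_error")
    vals <- yaml::read_yaml(file)
    if (!is.null(vals)) cfg <- merge_config(cfg, vals)
  }
  cfg <- merge_config(cfg, overrides)
  validate_pipeline_config(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x))
    cat(sprintf("  %-18s %s\n", k, paste(x[[k]], collapse = " x ")))
  invisible(x)
}

#' Write a provenance sidecar for a pipeline run
#'
#' Records the resolved configuration, seed, input checksum and fit
#' summary as JSON, enough to reproduce the run bit-exactly.
#'
#' @param path output JSON path.
#' @param config resolved [pipeline_config()].
#' @param fit [fit_bezier()] result (optional).
#' @param input_path input file/directory the volume came from (optional;
#'   single files are checksummed).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, fit = NULL, input_path = NULL) {
  checksum <- NULL
  if (!is.null(input_path) && file.exists(input_path) &&
      !dir.exists(input_path)) {
    checksum <- unname(tools::md5sum(input_path))
  }
  obj <- list(config = unclass(config), input = input_path,
              input_md5 = checksum)
  if (!is.null(fit)) {
    obj$fit <- list(control_points = unname(fit$curve$control_points),
                    f_initial = fit$f_initial, f_final = fit$f_final,
                    converged = fit$converged, cost_units = "pixels")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
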