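#' Pipeline configuration
#'
#' Numerical parameters shared across the measurement stages, with the
#' defaults used throughout: a cross-sectional slab of total width 0.2 mm
#' sampled at 0.05 mm stations for thickness profiling, a 0.5 N preload
#' defining the displacement origin, and truncation of the failure ramp
#' once force falls below 95% of the maximum past the peak.
#'
#' @param slab_width total width (mm) of the thickness-profiling slab.
#' @param station_step station spacing (mm) along the fibre; must not
#'   exceed `slab_width`.
#' @param preload force (N) defining the zero-displacement sample.
#' @param failure_stop_fraction fraction of the maximum force at which the
#'   post-peak tail is truncated (machine stopping criterion).
#' @param linear_fit_min_span minimum width of the linear-region search
#'   window, as a fraction of the pre-peak strain range.
#' @param first_peak_drop relative force drop after a local maximum that
#'   qualifies it as the first (fibre-failure) peak.
#' @param r2_warn minimum r-squared below which the linear fit is flagged.
#' @param attachment_width_mode `"axial"` projects attachment width on the
#'   bone axis (longitudinal distance); `"euclidean"` uses the 3D chord.
#' @param rng_seed integer seed for seeded stages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(slab_width = 0.2,
                            station_step = 0.05,
                            preload = 0.5,
                            failure_stop_fraction = 0.95,
                            linear_fit_min_span = 0.15,
                            first_peak_drop = 0.05,
                            r2_warn = 0.9,
                            attachment_width_mode = c("axial", "euclidean"),
                            rng_seed = 1L) {
  attachment_width_mode <- match.arg(attachment_width_mode)
  if (!is.numeric(slab_width) || slab_width <= 0)
    stopf("slab_width must be > 0")
  if (!is.numeric(station_step) || station_step <= 0 || station_step > slab_width)
    stopf("station_step must satisfy 0 < station_step <= slab_width")
  if (!is.numeric(failure_stop_fraction) ||
      failure_stop_fraction <= 0 || failure_stop_fraction >= 1)
    stopf("failure_stop_fraction must be in (0, 1)")
  if (!is.numeric(preload) || preload < 0) stopf("preload must be >= 0")
  if (!is.numeric(linear_fit_min_span) ||
      linear_fit_min_span <= 0 || linear_fit_min_span >= 1)
    stopf("linear_fit_min_span must be in (0, 1)")
  if (!is.numeric(first_peak_drop) || first_peak_drop <= 0 || first_peak_drop >= 1)
    stopf("first_peak_drop must be in (0, 1)")
  structure(list(slab_width = slab_width,
                 station_step = station_step,
                 preload = preload,
                 failure_stop_fraction = failure_stop_fraction,
                 linear_fit_min_span = linear_fit_min_span,
                 first_peak_drop = first_peak_drop,
                 r2_warn = r2_warn,
                 attachment_width_mode = attachment_width_mode,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so that typos in a config file fail loudly.
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
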