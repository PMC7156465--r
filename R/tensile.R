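#' Trapezoidal cross-sectional area of a ligament
#'
#' The CSA perpendicular to the loading force, approximated as the
#' trapezoid formed by the radial and ulnar attachment widths and the mean
#' ligament thickness: `((width_radial + width_ulnar) / 2) * mean_thickness`.
#'
#' @param width_radial,width_ulnar attachment widths (mm).
#' @param mean_thickness mean ligament thickness (mm).
#' @return area in mm^2.
#' @export
trapezoid_csa <- function(width_radial, width_ulnar, mean_thickness) {
  if (any(c(width_radial, width_ulnar, mean_thickness) <= 0))
    stopf("domain error: widths and thickness must be > 0")
  (width_radial + width_ulnar) / 2 * mean_thickness
}

#' Nominal stress
#'
#' Force divided by the initial cross-sectional area.
#'
#' @param force force (N).
#' @param csa initial cross-sectional area (mm^2).
#' @return stress in MPa (N/mm^2).
#' @export
nominal_stress <- function(force, csa) {
  if (!is.numeric(csa) || any(csa <= 0)) stopf("domain error: csa must be > 0")
  force / csa
}

#' Preprocess a tensile curve
#'
#' Applies the testing protocol's conventions: the displacement origin is
#' moved to the first sample where force reaches the preload, and the
#' post-peak tail is truncated at the stopping criterion -- the curve ends
#' at the last sample before force first falls below
#' `failure_stop_fraction` times the maximum force past the global
#' maximum.
#'
#' @param c a `tensile_curve`.
#' @param cfg a [pipeline_config()].
#' @return the preprocessed `tensile_curve`.
#' @export
preprocess_curve <- function(c, cfg = pipeline_config()) {
  stopifnot(inherits(c, "tensile_curve"))
  i0 <- which(c$force >= cfg$preload)[1L]
  if (is.na(i0))
    stopf("insufficient-load error: force never reaches the %.2f N preload",
          cfg$preload)
  x <- c$displacement[i0:length(c$displacement)] - c$displacement[i0]
  y <- c$force[i0:length(c$force)]
  im <- which.max(y)
  thr <- cfg$failure_stop_fraction * max(y)
  post <- which(seq_along(y) > im & y < thr)
  if (length(post)) {
    cut <- min(post) - 1L
    x <- x[1:cut]; y <- y[1:cut]
  }
  suppressWarnings(tensile_curve(x, y, c$gauge_length, c$specimen_id,
                                 c$ligament_id))
}

#' Locate the linear region of a force-displacement curve
#'
#' Searches every contiguous window of the pre-peak curve whose strain
#' span is at least `cfg$linear_fit_min_span` of the pre-peak strain range
#' and returns the window maximising the r-squared of a first-order
#' polynomial fit; r-squared ties (within 1e-9) go to the widest window,
#' then the earliest. The window always ends at or before the global force
#' maximum, matching the observation that the linear section precedes the
#' ultimate force; when a first fibre-failure peak is present the search is
#' additionally bounded there (detected on a lightly smoothed curve, with a
#' drop threshold inflated above the noise floor), since a window spanning
#' the failure drop cannot be a linear region however high its pooled
#' r-squared. If no window reaches r-squared `cfg$r2_warn`, the best window
#' is still returned with a poor-linearity warning.
#'
#' @param c a preprocessed `tensile_curve` with at least 20 samples before
#'   the global force maximum.
#' @param cfg a [pipeline_config()].
#' @return list with `strain_lo`/`strain_hi` (the window in % strain),
#'   `slope` (N/mm), `intercept` (N), `r2`, and the sample `window`
#'   indices.
#' @export
detect_linear_region <- function(c, cfg = pipeline_config()) {
  stopifnot(inherits(c, "tensile_curve"))
  im <- which.max(c$force)
  if (im < 20L)
    stopf("insufficient-data error: only %d samples before the force maximum (need >= 20)",
          im)
  x <- c$displacement[1:im]; y <- c$force[1:im]
  n <- length(x)
  minspan <- cfg$linear_fit_min_span * (x[n] - x[1L])
  if (minspan <= 0) stopf("degenerate pre-peak displacement range")
  bound <- first_failure_bound(y, cfg)
  if (x[bound] - x[1L] >= minspan) n <- bound  # else keep the full range
  Sx <- c(0, cumsum(x)); Sy <- c(0, cumsum(y))
  Sxx <- c(0, cumsum(x * x)); Syy <- c(0, cumsum(y * y))
  Sxy <- c(0, cumsum(x * y))
  best <- list(r2 = -Inf, span = -Inf, i = NA_integer_, j = NA_integer_)
  rtol <- 1e-9
  for (i in seq_len(n - 1L)) {
    jmin <- i + findInterval(x[i] + minspan - 1e-12, x[(i + 1L):n])
    jmin <- max(jmin, i + 1L)
    if (jmin > n) next
    ## findInterval gives the last index with x <= target; the window must
    ## reach at least the span, so start one past it when short
    while (jmin <= n && x[jmin] - x[i] < minspan - 1e-12) jmin <- jmin + 1L
    if (jmin > n) next
    j <- jmin:n
    nw <- j - i + 1
    SX <- Sx[j + 1L] - Sx[i]; SY <- Sy[j + 1L] - Sy[i]
    SXX <- Sxx[j + 1L] - Sxx[i]; SYY <- Syy[j + 1L] - Syy[i]
    SXY <- Sxy[j + 1L] - Sxy[i]
    sxx <- SXX - SX^2 / nw
    syy <- SYY - SY^2 / nw
    sxy <- SXY - SX * SY / nw
    r2 <- ifelse(sxx > 0 & syy > 1e-300, sxy^2 / (sxx * syy), 0)
    r2m <- max(r2)
    cand <- which(r2 >= r2m - rtol)
    jb <- j[cand[length(cand)]]        # widest among tied windows
    r2b <- r2[cand[length(cand)]]
    span <- x[jb] - x[i]
    if (r2b > best$r2 + rtol ||
        (abs(r2b - best$r2) <= rtol && span > best$span + 1e-12)) {
      best <- list(r2 = r2b, span = span, i = i, j = jb)
    }
  }
  if (!is.finite(best$r2)) stopf("no admissible linear-fit window found")
  i <- best$i; j <- best$j; nw <- j - i + 1
  SX <- Sx[j + 1L] - Sx[i]; SY <- Sy[j + 1L] - Sy[i]
  SXX <- Sxx[j + 1L] - Sxx[i]; SXY <- Sxy[j + 1L] - Sxy[i]
  slope <- (nw * SXY - SX * SY) / (nw * SXX - SX^2)
  intercept <- (SY - slope * SX) / nw
  if (best$r2 < cfg$r2_warn)
    warnf("poor-linearity warning: best window r-squared %.3f < %.2f",
          best$r2, cfg$r2_warn)
  list(strain_lo = 100 * x[i] / c$gauge_length,
       strain_hi = 100 * x[j] / c$gauge_length,
       slope = slope, intercept = intercept, r2 = best$r2,
       window = c(i, j))
}

## Index of the earliest first-failure peak in the pre-maximum force
## series, or the series length when none exists. Detection runs on a
## short running-mean smooth and requires the post-peak drop to exceed
## both the relative first-peak threshold and five standard errors of the
## smoothed noise, so measurement noise cannot fake a failure event.
first_failure_bound <- function(y, cfg) {
  n <- length(y)
  w <- max(3L, min(15L, n %/% 50L))
  ys <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2L))
  sigma <- stats::sd(diff(y)) / sqrt(2)
  need <- 5 * sigma / sqrt(w)
  lo <- w + 1L; hi <- n - w - 1L
  if (hi <= lo) return(n)
  for (i in lo:hi) {
    if (is.na(ys[i]) || ys[i] < ys[i - 1L] || ys[i] < ys[i + 1L]) next
    thr <- ys[i] - max(cfg$first_peak_drop * ys[i], need)
    if (min(ys[i:hi], na.rm = TRUE) <= thr) return(i)
  }
  n
}

#' Stiffness of a tensile curve
#'
#' The slope of the linear part of the force-displacement curve, as found
#' by [detect_linear_region()].
#'
#' @param c a preprocessed `tensile_curve`.
#' @param cfg a [pipeline_config()].
#' @return stiffness in N/mm.
#' @export
stiffness <- function(c, cfg = pipeline_config()) {
  detect_linear_region(c, cfg)$slope
}

#' Detect the biphasic failure peaks
#'
#' The ultimate force is the global force maximum and the ultimate strain
#' the grip-to-grip strain at which it occurs. The first peak is the force
#' at the earliest local maximum that is followed, before the global
#' maximum, by a relative force drop of at least `first_peak_drop` -- the
#' signature of the thinner fibres failing first. A curve with no such
#' local maximum is monophasic and the first peak equals the ultimate
#' force.
#'
#' @param c a preprocessed `tensile_curve` with at least 5 samples.
#' @param cfg a [pipeline_config()]; supplies `first_peak_drop`.
#' @return list with `first_peak_force`, `ultimate_force` (N) and
#'   `ultimate_strain` (%).
#' @export
detect_peaks <- function(c, cfg = pipeline_config()) {
  stopifnot(inherits(c, "tensile_curve"))
  y <- c$force
  if (length(y) < 5L)
    stopf("insufficient-data error: fewer than 5 samples")
  im <- which.max(y)
  ultimate <- y[im]
  strain <- 100 * c$displacement[im] / c$gauge_length
  first <- ultimate
  if (im > 2L) {
    drop <- cfg$first_peak_drop
    for (i in 2:(im - 1L)) {
      if (y[i] >= y[i - 1L] && y[i] >= y[i + 1L] &&
          min(y[i:im]) <= (1 - drop) * y[i]) {
        first <- y[i]
        break
      }
    }
  }
  list(first_peak_force = first, ultimate_force = ultimate,
       ultimate_strain = strain)
}

#' Full analysis of one tensile curve
#'
#' Preprocesses the curve, locates the linear region, detects the biphasic
#' peaks, and assembles one result row per specimen in the layout of a
#' tensile-testing summary table.
#'
#' @param curve a raw `tensile_curve` (ramp to failure; run
#'   [trim_preconditioning()] first if the recording includes cycling).
#' @param cfg a [pipeline_config()].
#' @param csa cross-sectional area (mm^2) for the record, e.g. from
#'   [trapezoid_csa()]; `NA` when unknown.
#' @return one-row `data.frame` with columns `ligament_id`, `specimen_id`,
#'   `csa`, `first_peak_force`, `ultimate_force`, `stiffness`,
#'   `ultimate_strain`, `strain_lo`, `strain_hi`, `fit_r2`.
#' @export
analyse_tensile_curve <- function(curve, cfg = pipeline_config(), csa = NA_real_) {
  pc <- preprocess_curve(curve, cfg)
  lin <- detect_linear_region(pc, cfg)
  pk <- detect_peaks(pc, cfg)
  data.frame(ligament_id = pc$ligament_id, specimen_id = pc$specimen_id,
             csa = csa,
             first_peak_force = pk$first_peak_force,
             ultimate_force = pk$ultimate_force,
             stiffness = lin$slope,
             ultimate_strain = pk$ultimate_strain,
             strain_lo = lin$strain_lo, strain_hi = lin$strain_hi,
             fit_r2 = lin$r2,
             stringsAsFactors = FALSE)
}
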