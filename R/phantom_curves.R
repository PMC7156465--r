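#' Ground truth for a synthetic biphasic tensile curve
#'
#' Parameters of an idealised ramp-to-failure force-displacement curve
#' with the biphasic failure shape seen in ligament testing: a concave toe
#' region, a linear region of known slope, a first fibre-failure peak
#' followed by a force drop, a rise to the ultimate peak, and a terminal
#' drop past the machine's stopping criterion.
#'
#' @param stiffness slope of the linear region (N/mm).
#' @param first_peak_force force at the first fibre-failure peak (N); must
#'   not exceed `ultimate_force`. Equal values give a monophasic curve.
#' @param ultimate_force global maximum force (N).
#' @param ultimate_strain grip-to-grip strain (%) at the ultimate force.
#' @param gauge_length initial specimen length (mm).
#' @param toe_span displacement extent of the toe region (mm).
#' @param noise_sd standard deviation of i.i.d. Gaussian force noise (N);
#'   displacement is machine-controlled and noise-free.
#' @param seed seed for the noise stream.
#' @param preload force (N) at zero displacement; recording starts at the
#'   preload in the testing protocol.
#' @param drop_fraction relative force drop after the first peak (>= 0.1).
#' @param drop_span displacement extent of the first-failure drop (mm).
#' @param specimen_id,ligament_id labels.
#' @return an object of class `tensile_truth`.
#' @export
tensile_truth <- function(stiffness, first_peak_force, ultimate_force,
                          ultimate_strain, gauge_length = 300,
                          toe_span = 0.5, noise_sd = 0, seed = 1L,
                          preload = 0.5, drop_fraction = 0.15,
                          drop_span = 0.3,
                          specimen_id = "synthetic", ligament_id = "") {
  if (stiffness <= 0 || first_peak_force <= 0 || ultimate_force <= 0 ||
      ultimate_strain <= 0 || gauge_length <= 0 || toe_span <= 0)
    stopf("stiffness, forces, strain, gauge length and toe span must be positive")
  if (first_peak_force > ultimate_force + 1e-9)
    stopf("first_peak_force must not exceed ultimate_force")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (drop_fraction < 0.1 || drop_fraction >= 0.9)
    stopf("drop_fraction must be in [0.1, 0.9) so the first peak is a clear failure event")
  structure(list(stiffness = stiffness, first_peak_force = first_peak_force,
                 ultimate_force = ultimate_force,
                 ultimate_strain = ultimate_strain,
                 gauge_length = gauge_length, toe_span = toe_span,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 preload = preload, drop_fraction = drop_fraction,
                 drop_span = drop_span, specimen_id = specimen_id,
                 ligament_id = ligament_id),
            class = "tensile_truth")
}

#' @export
print.tensile_truth <- function(x, ...) {
  cat(sprintf("<tensile_truth %s/%s: k %.2f N/mm, F1 %.2f N, Fu %.2f N, strain %.2f%%, noise %.2f N>\n",
              x$ligament_id, x$specimen_id, x$stiffness, x$first_peak_force,
              x$ultimate_force, x$ultimate_strain, x$noise_sd))
  invisible(x)
}

#' Generate a synthetic tensile curve from ground truth
#'
#' The curve starts at the preload force at displacement zero and is built
#' from, in order: a quadratic toe joining the linear region with matching
#' slope; a linear segment of slope `stiffness`; a linear drop of
#' `drop_fraction` after the first peak; a concave parabolic rise with its
#' apex exactly at the ultimate force and displacement; and a terminal
#' linear decay to 88% of the ultimate force, so the 95%-of-maximum
#' stopping criterion falls strictly inside the recorded tail. Gaussian
#' noise of sd `noise_sd` is added to force under the truth's seed without
#' disturbing the caller's RNG. When `first_peak_force` equals
#' `ultimate_force` the drop and rise are omitted (monophasic curve) and
#' the ultimate occurs at the end of the linear region.
#'
#' @param truth a [tensile_truth()].
#' @param sample_step_mm displacement sampling step (mm).
#' @return a `tensile_curve`; the truth plus derived break points
#'   (`d_toe`, `d_first_peak`, `d_ultimate`, `d_stop95`) are attached as
#'   attribute `"truth"`.
#' @export
make_tensile_curve <- function(truth, sample_step_mm = 0.01) {
  stopifnot(inherits(truth, "tensile_truth"))
  if (sample_step_mm <= 0) stopf("sample_step_mm must be > 0")
  k <- truth$stiffness; F0 <- truth$preload
  t <- truth$toe_span; F1 <- truth$first_peak_force
  Fu <- truth$ultimate_force
  F_t <- F0 + k * t / 2
  if (F1 <= F_t)
    stopf("configuration error: first peak force %.2f N does not exceed the toe-end force %.2f N",
          F1, F_t)
  d1 <- t + (F1 - F_t) / k
  monophasic <- (Fu - F1) <= 1e-9
  d_u <- truth$gauge_length * truth$ultimate_strain / 100
  if (!monophasic && d_u <= t)
    stopf("configuration error: ultimate strain places the peak inside the toe region")
  if (monophasic) {
    d_u <- d1
  } else {
    d2 <- d1 + truth$drop_span
    F2 <- F1 * (1 - truth$drop_fraction)
    if (d_u <= d2 + 2 * sample_step_mm)
      stopf("configuration error: ultimate peak at %.2f mm overlaps the first-failure drop ending at %.2f mm",
            d_u, d2)
    cpar <- (Fu - F2) / (d_u - d2)^2
  }
  tail_span <- 1.0
  tail_drop <- 0.12 * Fu
  d_end <- d_u + tail_span
  x <- seq(0, d_end, by = sample_step_mm)
  y <- numeric(length(x))
  toe <- x <= t
  y[toe] <- F0 + k * x[toe]^2 / (2 * t)
  lin <- x > t & x <= d1
  y[lin] <- F_t + k * (x[lin] - t)
  if (monophasic) {
    tail <- x > d1
    y[tail] <- Fu - tail_drop * (x[tail] - d1) / tail_span
  } else {
    drop <- x > d1 & x <= d2
    y[drop] <- F1 - (F1 - F2) * (x[drop] - d1) / truth$drop_span
    rise <- x > d2 & x <= d_u
    y[rise] <- Fu - cpar * (d_u - x[rise])^2
    tail <- x > d_u
    y[tail] <- Fu - tail_drop * (x[tail] - d_u) / tail_span
  }
  if (truth$noise_sd > 0)
    y <- y + with_seed(truth$seed,
                       stats::rnorm(length(y), 0, truth$noise_sd))
  curve <- tensile_curve(x, y, truth$gauge_length,
                         specimen_id = truth$specimen_id,
                         ligament_id = truth$ligament_id)
  derived <- c(unclass(truth),
               list(d_toe = t, d_first_peak = d1, d_ultimate = d_u,
                    d_stop95 = d_u + 0.05 * Fu / (tail_drop / tail_span),
                    sample_step = sample_step_mm))
  attr(curve, "truth") <- derived
  curve
}
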