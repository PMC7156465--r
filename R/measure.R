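#' Full morphometric record of one ligament
#'
#' Runs the complete 3D measurement chain for a single ligament: separates
#' it from the membrane (unless a pre-separated mesh is supplied), derives
#' the fibre vectors and signed fan-out angles, projects the attachment
#' points to percentages of bone length, measures the attachment widths,
#' profiles the thickness along each fibre direction and along the bone
#' axis, and pools the thickness summary.
#'
#' @param iom membrane `surface_mesh` (or the pre-separated ligament when
#'   `split = FALSE`).
#' @param lm [landmark_set()] of the ligament.
#' @param radius_axis,ulna_axis [bone_axis()] objects.
#' @param cfg a [pipeline_config()].
#' @param clip_half_width DOAC plane half-separation (mm); see
#'   [split_ligament()].
#' @param split separate the ligament from `iom` first.
#' @return an object of class `morphometry_record`.
#' @export
measure_ligament <- function(iom, lm, radius_axis, ulna_axis,
                             cfg = pipeline_config(),
                             clip_half_width = NULL, split = TRUE) {
  stopifnot(inherits(lm, "landmark_set"))
  piece <- if (split) split_ligament(iom, lm, radius_axis, clip_half_width)
           else iom
  fv <- fibre_vectors(lm)

  att <- do.call(rbind, lapply(fv, function(f) {
    data.frame(position = f$position,
               radial_pct = attachment_percentage(f$radial, radius_axis),
               ulnar_pct = attachment_percentage(f$ulnar, ulna_axis),
               fan_out_deg = fan_out_angle(f, radius_axis),
               stringsAsFactors = FALSE)
  }))
  rownames(att) <- NULL

  if (lm$ligament_id == "DOAC") {
    width_radial <- NA_real_
    width_ulnar <- NA_real_
  } else {
    width_radial <- attachment_width(lm$points$R_p, lm$points$R_d,
                                     radius_axis, cfg$attachment_width_mode)
    width_ulnar <- attachment_width(lm$points$U_p, lm$points$U_d,
                                    ulna_axis, cfg$attachment_width_mode)
  }

  profiles <- lapply(fv, function(f)
    thickness_profile(piece, f, (f$radial + f$ulnar) / 2, cfg,
                      reference = radius_axis, position = f$position))
  ## axial profile: slice along the bone axis through the ligament centre,
  ## with the mean fibre direction building the slab-plane normal
  centroid <- colMeans(do.call(rbind, lm$points))
  fbar <- unit3(rowMeans(vapply(fv, `[[`, numeric(3), "unit")))
  axial <- tryCatch(
    thickness_profile(piece, radius_axis$direction, centroid, cfg,
                      reference = fbar, position = "axial"),
    error = function(e) NULL)
  if (!is.null(axial)) profiles <- c(profiles, list(axial = axial))

  th <- average_thickness(profiles)

  structure(list(ligament_id = lm$ligament_id,
                 attachment = att,
                 width_radial = width_radial, width_ulnar = width_ulnar,
                 thickness_mean = th$mean, thickness_sd = th$sd,
                 thickness_range = th$range,
                 profiles = profiles, mesh = piece),
            class = "morphometry_record")
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf("<morphometry_record %s>\n", x$ligament_id))
  print(x$attachment, row.names = FALSE)
  cat(sprintf("  widths: radial %.2f mm, ulnar %.2f mm\n",
              x$width_radial, x$width_ulnar))
  cat(sprintf("  thickness: mean %.2f mm (sd %.2f, range %.2f-%.2f)\n",
              x$thickness_mean, x$thickness_sd,
              x$thickness_range[1], x$thickness_range[2]))
  invisible(x)
}

#' @export
as.data.frame.morphometry_record <- function(x, ...) {
  df <- x$attachment
  df$ligament_id <- x$ligament_id
  df$width_radial <- x$width_radial
  df$width_ulnar <- x$width_ulnar
  df$thickness_mean <- x$thickness_mean
  df$thickness_sd <- x$thickness_sd
  df$thickness_min <- x$thickness_range[1]
  df$thickness_max <- x$thickness_range[2]
  df[, c("ligament_id", setdiff(names(df), "ligament_id"))]
}

#' Measure every ligament of a phantom or specimen
#'
#' Convenience driver: estimates both bone axes (using supplied distal
#' hints), then runs [measure_ligament()] for each landmark set.
#'
#' @param radius,ulna,membrane `surface_mesh` objects.
#' @param landmarks list of [landmark_set()].
#' @param distal_hints list with 3D points `radius` and `ulna` near the
#'   distal bone ends, orienting the axes.
#' @param cfg a [pipeline_config()].
#' @param clip_half_width DOAC plane half-separation (mm).
#' @return named list of `morphometry_record`, plus the estimated axes as
#'   attribute `"axes"`.
#' @export
measure_iom <- function(radius, ulna, membrane, landmarks, distal_hints,
                        cfg = pipeline_config(), clip_half_width = NULL) {
  radius_axis <- estimate_bone_axis(radius, distal_hints$radius)
  ulna_axis <- estimate_bone_axis(ulna, distal_hints$ulna)
  recs <- lapply(landmarks, function(lm)
    measure_ligament(membrane, lm, radius_axis, ulna_axis, cfg,
                     clip_half_width = clip_half_width))
  names(recs) <- vapply(landmarks, `[[`, "", "ligament_id")
  attr(recs, "axes") <- list(radius = radius_axis, ulna = ulna_axis)
  recs
}
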