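#' Longitudinal bone axis
#'
#' @param distal_point 3D point at the most distal end of the bone (mm).
#' @param direction unit vector pointing distal to proximal.
#' @param length bone length (mm).
#' @return an object of class `bone_axis`.
#' @export
bone_axis <- function(distal_point, direction, length) {
  direction <- vec3(direction, "axis direction")
  n <- vnorm(direction)
  if (abs(n - 1) > 1e-6) stopf("axis direction must be a unit vector")
  direction <- direction / n
  if (!is.numeric(length) || length <= 0) stopf("bone length must be > 0")
  structure(list(distal_point = vec3(distal_point, "distal point"),
                 direction = direction, length = as.numeric(length)),
            class = "bone_axis")
}

#' @export
print.bone_axis <- function(x, ...) {
  cat(sprintf("<bone_axis: length %.1f mm, direction (%.3f, %.3f, %.3f)>\n",
              x$length, x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Estimate the longitudinal axis of a long bone
#'
#' The axis is the principal axis of the vertex cloud, oriented distal to
#' proximal using a caller-supplied hint point near the distal end. The
#' distal point is the mesh vertex extremal against the direction; the
#' length is the extent of the vertex projections along it. A mesh whose
#' principal extents are near-isotropic (spread ratio below 1.5) is
#' rejected -- the principal axis of such a shape is not meaningful.
#'
#' @param bone a `surface_mesh` of an elongated bone.
#' @param distal_hint 3D point nearer the distal than the proximal end.
#' @return a [bone_axis()].
#' @export
estimate_bone_axis <- function(bone, distal_hint) {
  validate_surface_mesh(bone)
  distal_hint <- vec3(distal_hint, "distal hint")
  v <- bone$vertices
  ctr <- colMeans(v)
  e <- eigen(stats::cov(v), symmetric = TRUE)
  spread <- sqrt(pmax(e$values, 0))
  if (spread[2] <= 0 || spread[1] / spread[2] < 1.5)
    stopf("degeneracy error: mesh is not elongated (principal spread ratio %.2f < 1.5)",
          spread[1] / max(spread[2], 1e-12))
  dir <- e$vectors[, 1L]
  if (sum((distal_hint - ctr) * dir) > 0) dir <- -dir
  proj <- as.numeric(v %*% dir)
  bone_axis(v[which.min(proj), ], dir, max(proj) - min(proj))
}

#' Fibre direction vectors of a ligament
#'
#' The displacement from each radial attachment point to its paired ulnar
#' point: the proximal and distal fibres for the CB, AB and DOB, the single
#' mid fibre for the DOAC.
#'
#' @param lm a [landmark_set()].
#' @return named list (`p`/`d` or `m`) of `fibre_vector` objects, each with
#'   the endpoints, the raw displacement `vector` (ulnar minus radial, mm)
#'   and its `unit` direction.
#' @export
fibre_vectors <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  mk <- function(pos, R, U) {
    v <- U - R
    structure(list(ligament_id = lm$ligament_id, position = pos,
                   radial = R, ulnar = U, vector = v, unit = unit3(v)),
              class = "fibre_vector")
  }
  p <- lm$points
  if (lm$ligament_id == "DOAC")
    list(m = mk("m", p$R_m, p$U_m))
  else
    list(p = mk("p", p$R_p, p$U_p), d = mk("d", p$R_d, p$U_d))
}

#' @export
print.fibre_vector <- function(x, ...) {
  cat(sprintf("<fibre_vector %s/%s: |V| = %.2f mm>\n",
              x$ligament_id, x$position, vnorm(x$vector)))
  invisible(x)
}

#' Signed fan-out angle of a fibre against the radius axis
#'
#' The magnitude is the acute angle between the fibre line and the axis
#' line, in degrees. The sign encodes the fibre's course: positive when the
#' radial-to-ulnar vector has a distally-directed component along the bone
#' axis (the CB/AB course, radial origin proximal to the ulnar insertion),
#' negative when proximally-directed (the DOAC/DOB course). A fibre exactly
#' perpendicular to the axis returns +90; a parallel fibre returns exactly
#' 0.
#'
#' @param v a `fibre_vector` (from [fibre_vectors()]) or a 3-vector.
#' @param radius_axis a [bone_axis()] or a 3-vector.
#' @return signed angle in degrees, in (-90, 90].
#' @export
fan_out_angle <- function(v, radius_axis) {
  vv <- if (inherits(v, "fibre_vector")) v$vector else vec3(v, "fibre vector")
  aa <- if (inherits(radius_axis, "bone_axis")) radius_axis$direction
        else vec3(radius_axis, "axis")
  if (vnorm(vv) < 1e-12) stopf("degeneracy error: zero-length fibre vector")
  d <- sum(unit3(vv) * unit3(aa))
  acute <- acos(clamp(abs(d), 0, 1)) * 180 / pi
  if (abs(d) >= 1) return(0)
  if (d == 0) return(90)
  if (d < 0) acute else -acute
}

#' Axial attachment location as a percentage of bone length
#'
#' The attachment point is projected onto the bone's longitudinal axis and
#' expressed as the percent distance from the most distal point of the
#' bone. Values outside [0, 100] by more than 1 point raise a warning
#' before clamping.
#'
#' @param point 3D attachment point (mm).
#' @param axis a [bone_axis()].
#' @return percentage in \[0, 100\].
#' @export
attachment_percentage <- function(point, axis) {
  stopifnot(inherits(axis, "bone_axis"))
  point <- vec3(point, "attachment point")
  pct <- 100 * sum((point - axis$distal_point) * axis$direction) / axis$length
  if (pct < -1 || pct > 101)
    warnf("attachment projects at %.1f%%, outside the bone span", pct)
  clamp(pct, 0, 100)
}

#' Attachment width along the bone axis
#'
#' The longitudinal distance between the proximal and distal attachment
#' points of a ligament on one bone: the absolute difference of their
#' projections onto the bone axis (the default), or the 3D chord length
#' with `mode = "euclidean"`.
#'
#' @param p_point,d_point proximal and distal 3D attachment points (mm).
#' @param axis a [bone_axis()].
#' @param mode `"axial"` (projected) or `"euclidean"` (chord).
#' @return width in mm.
#' @export
attachment_width <- function(p_point, d_point, axis,
                             mode = c("axial", "euclidean")) {
  mode <- match.arg(mode)
  p_point <- vec3(p_point, "proximal point")
  d_point <- vec3(d_point, "distal point")
  if (mode == "euclidean") return(vnorm(p_point - d_point))
  stopifnot(inherits(axis, "bone_axis"))
  abs(sum((p_point - d_point) * axis$direction))
}

## Population standard deviation (divisor n), the convention of the
## printed summary tables.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Pooled thickness summary over profiles
#'
#' Pools all non-missing station thicknesses across the supplied profiles
#' (typically the fibre-direction profiles plus the axial-direction
#' profile) and returns their mean, population standard deviation and
#' range.
#'
#' @param profiles a `thickness_profile` or list of them.
#' @return list with `mean`, `sd`, `range` (min, max) and `n` stations.
#' @export
average_thickness <- function(profiles) {
  if (inherits(profiles, "thickness_profile")) profiles <- list(profiles)
  th <- unlist(lapply(profiles, `[[`, "thickness"), use.names = FALSE)
  th <- th[!is.na(th)]
  if (length(th) == 0L)
    stopf("empty-data error: no non-missing thickness stations")
  list(mean = mean(th), sd = pop_sd(th), range = c(min(th), max(th)),
       n = length(th))
}

#' Linear trend of thickness against axial position
#'
#' Ordinary least-squares fit of thickness (mm) on attachment location
#' (percent of bone length), describing how ligament thickness varies
#' along the forearm.
#'
#' @param records data frame with columns `axial_pct` and `thickness`.
#' @return named vector `c(slope, intercept)`; slope in mm per percent.
#' @export
thickness_axial_trend <- function(records) {
  x <- records$axial_pct; y <- records$thickness
  if (length(x) < 2L || length(unique(x)) < 2L)
    stopf("degeneracy error: need >= 2 distinct axial positions")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  c(slope = unname(co[2L]), intercept = unname(co[1L]))
}
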