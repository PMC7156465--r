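#' Clip a mesh by a half-space
#'
#' Keeps the part of the mesh on the side of the plane where the signed
#' distance `(v - point) . normal` is non-positive. Triangles crossing the
#' plane are cut exactly at the plane (Sutherland-Hodgman on each
#' triangle), never dropped, so clipping conserves the kept area.
#'
#' @param mesh a `surface_mesh`.
#' @param point a point on the clipping plane (mm).
#' @param normal plane normal; the side it points to is removed.
#' @param tol on-plane tolerance (mm); vertices within it are kept.
#' @return a `surface_mesh` (possibly with zero faces, see
#'   [split_ligament()] for the error contract).
#' @export
clip_mesh_halfspace <- function(mesh, point, normal, tol = 1e-9) {
  point <- vec3(point, "plane point")
  nrm <- unit3(vec3(normal, "plane normal"))
  v <- mesh$vertices
  d <- as.numeric(sweep(v, 2L, point, "-") %*% nrm)
  f <- mesh$faces
  d1 <- d[f[, 1L]]; d2 <- d[f[, 2L]]; d3 <- d[f[, 3L]]
  dmax <- pmax(d1, d2, d3); dmin <- pmin(d1, d2, d3)
  keep_all <- dmax <= tol
  drop_all <- !keep_all & dmin >= -tol
  crossing <- which(!keep_all & !drop_all)

  newv <- list(); newf <- list()
  nv0 <- nrow(v)
  nadd <- 0L
  for (fi in crossing) {
    tri <- f[fi, ]
    pd <- d[tri]
    poly <- matrix(numeric(0), 0L, 3L)
    for (k in 1:3) {
      a <- tri[k]; b <- tri[if (k == 3L) 1L else k + 1L]
      da <- d[a]; db <- d[b]
      if (da <= tol) poly <- rbind(poly, v[a, ])
      if ((da <= tol) != (db <= tol)) {
        t <- da / (da - db)
        poly <- rbind(poly, v[a, ] + t * (v[b, ] - v[a, ]))
      }
    }
    if (nrow(poly) >= 3L) {
      for (k in 2:(nrow(poly) - 1L)) {
        newv[[length(newv) + 1L]] <- poly[c(1L, k, k + 1L), , drop = FALSE]
        newf[[length(newf) + 1L]] <- nv0 + nadd + c(1L, 2L, 3L)
        nadd <- nadd + 3L
      }
    }
  }
  allv <- rbind(v, do.call(rbind, newv))
  allf <- rbind(f[keep_all, , drop = FALSE],
                do.call(rbind, lapply(newf, rbind)))
  if (is.null(allf) || nrow(allf) == 0L)
    return(surface_mesh(v[1:3, , drop = FALSE],
                        matrix(integer(0), 0L, 3L), mesh$name,
                        validate = FALSE))
  out <- surface_mesh(allv, allf, mesh$name, validate = FALSE)
  ## drop slivers created by cutting exactly along an edge
  a <- face_areas(out)
  out$faces <- out$faces[a > 1e-12, , drop = FALSE]
  compact_mesh(out)
}

## Drop vertices not referenced by any face.
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(map[mesh$faces], ncol = 3L),
               mesh$name, validate = FALSE)
}

#' Separate one ligament from the membrane mesh
#'
#' Cuts the membrane between two clipping planes. For the CB, AB and DOB
#' each plane contains one boundary fibre line (through `R_p`--`U_p` and
#' `R_d`--`U_d` respectively), with the plane normal taken as the component
#' of the radius axis orthogonal to that fibre direction -- the two planes
#' therefore fan with the fibres. For the DOAC, two parallel planes with
#' the same normal construction are placed symmetrically about the
#' mid-fibre line, separated by `2 * clip_half_width`. Boundary triangles
#' are cut at the planes, not discarded.
#'
#' @param iom membrane `surface_mesh`.
#' @param lm [landmark_set()] of the ligament.
#' @param radius_axis [bone_axis()] of the radius.
#' @param clip_half_width half-separation (mm) of the parallel DOAC
#'   planes; in the original annotation this is half the length of the
#'   surgical clips. Ignored for four-point ligaments.
#' @return a `surface_mesh` of the ligament, named `<ligament_id>`.
#' @export
split_ligament <- function(iom, lm, radius_axis, clip_half_width = NULL) {
  stopifnot(inherits(lm, "landmark_set"), inherits(radius_axis, "bone_axis"))
  a <- radius_axis$direction
  fv <- fibre_vectors(lm)
  plane_normal <- function(funit) {
    n <- a - sum(a * funit) * funit
    if (vnorm(n) < 1e-9)
      stopf("degeneracy error: fibre direction is parallel to the radius axis")
    unit3(n)
  }
  out <- iom
  if (lm$ligament_id == "DOAC") {
    if (is.null(clip_half_width) || clip_half_width <= 0)
      stopf("clip_half_width (mm) is required to separate the DOAC")
    n <- plane_normal(fv$m$unit)
    mid <- (fv$m$radial + fv$m$ulnar) / 2
    out <- clip_mesh_halfspace(out, mid + clip_half_width * n, n)
    if (nrow(out$faces) > 0L)
      out <- clip_mesh_halfspace(out, mid - clip_half_width * n, -n)
  } else {
    for (pos in c("p", "d")) {
      fvp <- fv[[pos]]
      other <- fv[[setdiff(c("p", "d"), pos)]]
      n <- plane_normal(fvp$unit)
      ref <- (other$radial + other$ulnar) / 2
      if (sum((ref - fvp$radial) * n) > 0) n <- -n  # keep the ligament side
      out <- clip_mesh_halfspace(out, fvp$radial, n)
      if (nrow(out$faces) == 0L) break
    }
  }
  if (nrow(out$faces) == 0L)
    stopf("empty-result error: clipping planes for %s do not bound any membrane triangles",
          lm$ligament_id)
  out$name <- lm$ligament_id
  out
}
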