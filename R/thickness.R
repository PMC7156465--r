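#' Cross-sectional thickness profile along a fibre
#'
#' Measures ligament thickness continuously along a fibre direction, the
#' way a cross-sectional cut through the membrane is read: a slab of total
#' width `cfg$slab_width` is centred on the plane that contains the fibre
#' line, surface points inside the slab are collected and binned along the
#' fibre at `cfg$station_step`, and the thickness at each station is the
#' maximum point-pair separation along the local "vertical" -- the unit
#' vector orthogonal to both the fibre direction and the slab-plane
#' normal (the dorso-palmar direction of the membrane). Stations with
#' fewer than two points are reported as missing, never zero.
#'
#' The slab-plane normal is the component of the `reference` direction
#' orthogonal to the fibre (the same construction as the clipping planes),
#' so the cut runs across the membrane sheet. Point collection combines
#' the exact intersection of the mesh with the central plane (triangle
#' edges interpolated at each station, coplanar triangles contributing
#' their edges) with all mesh vertices lying inside the slab.
#'
#' @param ligament `surface_mesh` of the separated ligament.
#' @param fibre a `fibre_vector` or a 3-vector: the direction along which
#'   stations run.
#' @param anchor 3D point on the fibre line (station 0).
#' @param cfg a [pipeline_config()].
#' @param reference a [bone_axis()] or 3-vector used to build the
#'   slab-plane normal; typically the radius axis for fibre-direction
#'   profiles and the mean fibre direction for axial profiles.
#' @param plane_normal optional explicit slab-plane normal, overriding the
#'   `reference` construction.
#' @param position label stored on the profile (`"p"`, `"m"`, `"d"`,
#'   `"axial"`, ...).
#' @return an object of class `thickness_profile`: strictly increasing
#'   `stations` (mm along the fibre, relative to the anchor) and
#'   `thickness` (mm, `NA` where the slab is empty).
#' @export
thickness_profile <- function(ligament, fibre, anchor, cfg = pipeline_config(),
                              reference = NULL, plane_normal = NULL,
                              position = "") {
  validate_surface_mesh(ligament)
  f <- if (inherits(fibre, "fibre_vector")) fibre$unit
       else unit3(vec3(fibre, "fibre direction"))
  anchor <- vec3(anchor, "anchor")
  if (is.null(plane_normal)) {
    if (is.null(reference))
      stopf("supply either a reference axis or an explicit plane_normal")
    r <- if (inherits(reference, "bone_axis")) reference$direction
         else unit3(vec3(reference, "reference direction"))
    n <- r - sum(r * f) * f
    if (vnorm(n) < 1e-9)
      stopf("reference direction is parallel to the fibre; supply plane_normal")
    n <- unit3(n)
  } else {
    n <- unit3(vec3(plane_normal, "plane normal"))
  }
  vert <- unit3(cross3(n, f))
  step <- cfg$station_step
  half <- cfg$slab_width / 2

  v <- ligament$vertices
  rel <- sweep(v, 2L, anchor, "-")
  dn <- as.numeric(rel %*% n)      # distance from the central plane
  ds <- as.numeric(rel %*% f)      # station coordinate
  dw <- as.numeric(rel %*% vert)   # vertical coordinate
  tol <- 1e-7

  ## segments: intersection of each triangle with the central plane, in
  ## (station, vertical) coordinates
  fidx <- ligament$faces
  t1 <- fidx[, 1L]; t2 <- fidx[, 2L]; t3 <- fidx[, 3L]
  fmin <- pmin(dn[t1], dn[t2], dn[t3])
  fmax <- pmax(dn[t1], dn[t2], dn[t3])
  cand <- which(fmin <= tol & fmax >= -tol)

  segs <- matrix(numeric(0), 0L, 4L)  # s1, w1, s2, w2
  if (length(cand)) {
    segs <- matrix(NA_real_, 3L * length(cand), 4L)
    nseg <- 0L
    for (fi in cand) {
      tri <- fidx[fi, ]
      dd <- dn[tri]
      onp <- abs(dd) <= tol
      if (all(onp)) {           # coplanar triangle: keep its edges
        for (k in 1:3) {
          a <- tri[k]; b <- tri[if (k == 3L) 1L else k + 1L]
          nseg <- nseg + 1L
          segs[nseg, ] <- c(ds[a], dw[a], ds[b], dw[b])
        }
      } else {
        pts_s <- numeric(0); pts_w <- numeric(0)
        for (k in 1:3) {
          a <- tri[k]; b <- tri[if (k == 3L) 1L else k + 1L]
          da <- dd[k]; db <- dd[if (k == 3L) 1L else k + 1L]
          if (abs(da) <= tol) {
            pts_s <- c(pts_s, ds[a]); pts_w <- c(pts_w, dw[a])
          } else if ((da < -tol && db > tol) || (da > tol && db < -tol)) {
            t <- da / (da - db)
            pts_s <- c(pts_s, ds[a] + t * (ds[b] - ds[a]))
            pts_w <- c(pts_w, dw[a] + t * (dw[b] - dw[a]))
          }
        }
        if (length(pts_s) >= 2L) {
          nseg <- nseg + 1L
          segs[nseg, ] <- c(pts_s[1L], pts_w[1L], pts_s[2L], pts_w[2L])
        }
      }
    }
    segs <- segs[seq_len(nseg), , drop = FALSE]
  }

  in_slab <- which(abs(dn) <= half)
  if (nrow(segs) == 0L && length(in_slab) == 0L)
    stopf("empty-profile error: the slab intersects no surface points")

  s_all <- c(segs[, 1L], segs[, 3L], ds[in_slab])
  k_lo <- ceiling(min(s_all) / step - 1e-9)
  k_hi <- floor(max(s_all) / step + 1e-9)
  if (k_hi < k_lo) { k_lo <- round(min(s_all) / step); k_hi <- k_lo }
  stations <- (k_lo:k_hi) * step
  ns <- length(stations)
  wmin <- rep(Inf, ns); wmax <- rep(-Inf, ns); cnt <- integer(ns)

  put <- function(ki, w) {
    ok <- ki >= 1L & ki <= ns
    ki <- ki[ok]; w <- w[ok]
    if (!length(ki)) return(invisible())
    for (u in seq_along(ki)) {
      i <- ki[u]
      if (w[u] < wmin[i]) wmin[i] <<- w[u]
      if (w[u] > wmax[i]) wmax[i] <<- w[u]
      cnt[i] <<- cnt[i] + 1L
    }
    invisible()
  }

  if (nrow(segs)) {
    for (si in seq_len(nrow(segs))) {
      s1 <- segs[si, 1L]; w1 <- segs[si, 2L]
      s2 <- segs[si, 3L]; w2 <- segs[si, 4L]
      lo <- min(s1, s2); hi <- max(s1, s2)
      ka <- ceiling(lo / step - 1e-9); kb <- floor(hi / step + 1e-9)
      if (kb >= ka) {
        sk <- (ka:kb) * step
        wk <- if (abs(s2 - s1) < 1e-12) rep((w1 + w2) / 2, length(sk))
              else w1 + (sk - s1) / (s2 - s1) * (w2 - w1)
        put((ka:kb) - k_lo + 1L, wk)
      }
      ## segment endpoints land in their nearest station bin
      put(round(c(s1, s2) / step) - k_lo + 1L, c(w1, w2))
    }
  }
  if (length(in_slab))
    put(round(ds[in_slab] / step) - k_lo + 1L, dw[in_slab])

  thickness <- ifelse(cnt >= 2L, wmax - wmin, NA_real_)
  structure(list(ligament_id = ligament$name, position = position,
                 stations = stations, thickness = thickness,
                 slab_width = cfg$slab_width, step = step,
                 fibre = f, normal = n, vertical = vert, anchor = anchor),
            class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  ok <- !is.na(x$thickness)
  cat(sprintf("<thickness_profile %s/%s: %d stations (%d measured), step %.2f mm, mean %.2f mm>\n",
              x$ligament_id, x$position, length(x$stations), sum(ok),
              x$step, mean(x$thickness[ok])))
  invisible(x)
}
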