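#' Default ligament layout for the forearm phantom
#'
#' Attachment spans (percent of bone length from the distal end), thickness
#' fields (mm) and, for the DOAC, the signed fan-out angle, at the
#' magnitudes observed in cadaveric forearms. The phantom membrane is a
#' single-layer sheet, so spans that overlap axially in a real forearm
#' (where ligaments lie at different dorso-palmar depths) are nudged apart:
#' the AB sits just distal to the CB and the DOAC just proximal to it,
#' within the anatomically observed ranges.
#'
#' @return list of per-ligament specifications accepted by [phantom_truth()].
#' @export
default_phantom_ligaments <- function() {
  list(
    list(id = "DOB", radial_span = c(10.0, 17.5), ulnar_span = c(11.0, 19.1),
         thickness = 6.95),
    list(id = "AB", radial_span = c(39.3, 48.6), ulnar_span = c(19.8, 28.5),
         thickness = 3.11),
    list(id = "CB", radial_span = c(51.7, 65.1), ulnar_span = c(32.9, 46.4),
         thickness = c(radial = 2, ulnar = 5)),
    list(id = "DOAC", radial_mid = 70.5, fan_out = -18.7, width = 9.2,
         thickness = 4.65)
  )
}

#' Ground truth of a parametric forearm phantom
#'
#' Defines two parallel cylindrical bones and a set of planar ruled
#' membrane patches (one per ligament) spanning the interosseous gap, with
#' every derived quantity -- landmark coordinates, fibre vectors, signed
#' fan-out angles, attachment widths, thickness field, patch surface areas
#' -- available in closed form. In the canonical frame both bone axes run
#' along +z with the distal ends at low z; the membrane mid-surface lies in
#' the y = 0 plane and thickness extends in y (the dorso-palmar direction).
#'
#' Each ligament is specified either by its radial and ulnar spans (percent
#' of the owning bone's length, distal to proximal), from which the fibre
#' fan-out angles follow, or -- for the narrow DOAC -- by a radial
#' mid-fibre position, a signed fan-out angle and a width in mm, from which
#' the ulnar position follows. The signed angle is positive when the
#' radial-to-ulnar fibre runs distally along the bone axis (CB/AB course)
#' and negative when it runs proximally (DOAC/DOB course).
#'
#' @param bone_lengths named vector, radius and ulna lengths (mm).
#' @param bone_radii named vector, shaft radii (mm).
#' @param gap interosseous distance between the two attachment lines (mm).
#' @param ulna_distal_offset axial offset of the ulna's distal end relative
#'   to the radius' distal end (mm).
#' @param ligaments list of per-ligament specs; see
#'   [default_phantom_ligaments()].
#' @return an object of class `phantom_truth`.
#' @export
phantom_truth <- function(bone_lengths = c(radius = 254.4, ulna = 271.5),
                          bone_radii = c(radius = 7.5, ulna = 7.5),
                          gap = 18,
                          ulna_distal_offset = 0,
                          ligaments = default_phantom_ligaments()) {
  L_R <- bone_lengths[["radius"]]; L_U <- bone_lengths[["ulna"]]
  r_R <- bone_radii[["radius"]]; r_U <- bone_radii[["ulna"]]
  if (L_R <= 0 || L_U <= 0 || r_R <= 0 || r_U <= 0 || gap <= 0)
    stopf("bone lengths, radii and gap must all be positive")
  x_R <- r_R                      # radial attachment line (radius surface)
  x_U <- r_R + gap                # ulnar attachment line (ulna surface)
  off <- ulna_distal_offset
  g <- gap

  ligs <- lapply(ligaments, function(sp) {
    id <- sp$id %||% stopf("each ligament spec needs an 'id'")
    thick <- sp$thickness %||% stopf("ligament %s: thickness missing", id)
    if (length(thick) == 1L) thick <- c(radial = thick, ulnar = thick)
    T_R <- unname(thick[1L]); T_U <- unname(thick[2L])
    if (T_R <= 0 || T_U <= 0) stopf("ligament %s: thickness must be > 0", id)

    if (id == "DOAC") {
      mid <- sp$radial_mid %||% stopf("DOAC spec needs 'radial_mid'")
      w <- sp$width %||% stopf("DOAC spec needs 'width' (mm)")
      z_Rm <- mid / 100 * L_R
      if (!is.null(sp$fan_out)) {
        th <- sp$fan_out
        if (abs(th) >= 90 || abs(th) < 1e-6)
          stopf("DOAC fan_out must be in (-90, 90) degrees and nonzero")
        dz <- -g / tan(th * pi / 180)
      } else {
        um <- sp$ulnar_mid %||% stopf("DOAC spec needs 'fan_out' or 'ulnar_mid'")
        dz <- (um / 100 * L_U + off) - z_Rm
      }
      z_Um <- z_Rm + dz
      um_pct <- (z_Um - off) / L_U * 100
      if (um_pct < 0 || um_pct > 100)
        stopf("DOAC configuration error: derived ulnar attachment at %.1f%% lies outside the ulna",
              um_pct)
      rs <- c(mid - w / 2 / L_R * 100, mid + w / 2 / L_R * 100)
      us <- c((z_Um - w / 2 - off) / L_U * 100, (z_Um + w / 2 - off) / L_U * 100)
      hR <- w; hU <- w
      z_Rd <- z_Rm - w / 2; z_Rp <- z_Rm + w / 2
      z_Ud <- z_Um - w / 2; z_Up <- z_Um + w / 2
      fan <- c(m = fan_angle_analytic(g, dz))
      landmarks <- landmark_set("DOAC", list(
        R_m = c(x_R, 0, z_Rm), U_m = c(x_U, 0, z_Um)))
      widths <- c(radial = w, ulnar = w)
      ell <- sqrt(g^2 + dz^2)
      clip_half_width <- w * g / ell / 2
    } else {
      rs <- sp$radial_span %||% stopf("ligament %s needs 'radial_span'", id)
      if (length(rs) != 2L || rs[1] >= rs[2] || rs[1] < 0 || rs[2] > 100)
        stopf("ligament %s: radial_span must satisfy 0 <= distal%% < proximal%% <= 100", id)
      z_Rd <- rs[1] / 100 * L_R; z_Rp <- rs[2] / 100 * L_R
      if (!is.null(sp$ulnar_span)) {
        us <- sp$ulnar_span
        if (length(us) != 2L || us[1] >= us[2] || us[1] < 0 || us[2] > 100)
          stopf("ligament %s: ulnar_span must satisfy 0 <= distal%% < proximal%% <= 100", id)
        z_Ud <- us[1] / 100 * L_U + off; z_Up <- us[2] / 100 * L_U + off
      } else {
        th <- sp$fan_out %||% stopf("ligament %s needs 'ulnar_span' or 'fan_out'", id)
        if (length(th) == 1L) th <- c(th, th)   # c(distal, proximal)
        z_Ud <- z_Rd + angle_to_dz(g, th[1])
        z_Up <- z_Rp + angle_to_dz(g, th[2])
        us <- c((z_Ud - off) / L_U * 100, (z_Up - off) / L_U * 100)
        if (any(us < 0 | us > 100) || us[1] >= us[2])
          stopf("ligament %s: fan-out angles imply an invalid ulnar span [%.1f, %.1f]%%",
                id, us[1], us[2])
      }
      hR <- z_Rp - z_Rd; hU <- z_Up - z_Ud
      fan <- c(p = fan_angle_analytic(g, z_Up - z_Rp),
               d = fan_angle_analytic(g, z_Ud - z_Rd))
      landmarks <- landmark_set(id, list(
        R_p = c(x_R, 0, z_Rp), R_d = c(x_R, 0, z_Rd),
        U_p = c(x_U, 0, z_Up), U_d = c(x_U, 0, z_Ud)))
      widths <- c(radial = hR, ulnar = hU)
      clip_half_width <- NA_real_
    }

    ## Closed-form surface area of the patch solid (all pieces planar):
    ## mid-surface trapezoid, two offset faces tilted by the thickness
    ## ramp, two bone-side walls, and two fibre-edge walls.
    A_mid <- g * (hR + hU) / 2
    sec <- sqrt(1 + ((T_U - T_R) / (2 * g))^2)
    ell_d <- sqrt(g^2 + (z_Ud - z_Rd)^2)
    ell_p <- sqrt(g^2 + (z_Up - z_Rp)^2)
    Tbar <- (T_R + T_U) / 2
    area <- 2 * A_mid * sec + hR * T_R + hU * T_U + (ell_d + ell_p) * Tbar

    list(id = id, radial_span = rs, ulnar_span = us,
         z = c(Rd = z_Rd, Rp = z_Rp, Ud = z_Ud, Up = z_Up),
         thickness = c(radial = T_R, ulnar = T_U),
         thickness_mean = (T_R + T_U) / 2,
         thickness_slope_fibre = (T_U - T_R) / sqrt(g^2 + ((z_Ud + z_Up) / 2 - (z_Rd + z_Rp) / 2)^2),
         fan_out = fan, widths = widths, landmarks = landmarks,
         area = area, clip_half_width = clip_half_width)
  })
  names(ligs) <- vapply(ligs, `[[`, "", "id")
  if (anyDuplicated(names(ligs))) stopf("duplicate ligament ids in phantom")

  ## Ligaments must not overlap axially on either bone: the phantom sheet
  ## is single-layered.
  for (bone in c("radial_span", "ulnar_span")) {
    iv <- t(vapply(ligs, function(l) l[[bone]], numeric(2)))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2] - 1e-9))
      stopf("configuration error: ligament attachment spans overlap on the %s",
            sub("_span", "", bone))
  }

  structure(list(bone_lengths = c(radius = L_R, ulna = L_U),
                 bone_radii = c(radius = r_R, ulna = r_U),
                 gap = gap, ulna_distal_offset = off,
                 attachment_x = c(radial = x_R, ulnar = x_U),
                 ligaments = ligs,
                 membrane_area = sum(vapply(ligs, `[[`, 0, "area"))),
            class = "phantom_truth")
}

## Signed fan-out angle (degrees) of a fibre crossing gap g with axial rise
## dz (ulnar z minus radial z): magnitude is the acute angle to the bone
## axis, sign positive for a distally-directed fibre (dz < 0).
fan_angle_analytic <- function(g, dz) {
  ang <- atan2(g, abs(dz)) * 180 / pi
  if (abs(dz) < 1e-9) return(90)
  if (dz < 0) ang else -ang
}

## Inverse: axial rise dz for a declared signed angle.
angle_to_dz <- function(g, theta_deg) {
  if (abs(theta_deg) > 90 || abs(theta_deg) < 1e-6)
    stopf("fan-out angle must be nonzero and within [-90, 90] degrees")
  if (abs(abs(theta_deg) - 90) < 1e-12) return(0)
  -g / tan(theta_deg * pi / 180)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth: radius %.1f mm, ulna %.1f mm, gap %.1f mm, %d ligament(s)>\n",
              x$bone_lengths[["radius"]], x$bone_lengths[["ulna"]], x$gap,
              length(x$ligaments)))
  for (l in x$ligaments)
    cat(sprintf("  %-5s radial [%.1f, %.1f]%%  ulnar [%.1f, %.1f]%%  fan-out %s deg  thickness %.2f mm\n",
                l$id, l$radial_span[1], l$radial_span[2],
                l$ulnar_span[1], l$ulnar_span[2],
                paste(sprintf("%.1f", l$fan_out), collapse = "/"),
                l$thickness_mean))
  invisible(x)
}

#' Generate a forearm phantom from ground truth
#'
#' Builds watertight triangle meshes for the two bones (capped cylinders
#' along their declared axes) and the membrane (one thin ruled solid per
#' ligament patch, concatenated into a single mesh), plus landmark sets
#' placed exactly at the analytic attachment points. Optionally the whole
#' phantom is posed by a seeded random rigid transform, which the truth
#' echo reflects, so that every measurement can be tested for rigid
#' invariance.
#'
#' @param truth a [phantom_truth()].
#' @param mesh_resolution scalar multiplier on mesh density (1 gives
#'   roughly 40 circumferential by 30 axial cylinder segments and 20 x 20
#'   patch grids).
#' @param pose `"canonical"` leaves the phantom in its construction frame;
#'   `"random"` applies a seeded random rotation and translation.
#' @param seed integer seed for the random pose.
#' @return an object of class `phantom`: list with `radius`, `ulna`,
#'   `membrane` (`surface_mesh`), `landmarks` (list of `landmark_set`),
#'   `axes` (list of `bone_axis` ground truth), `truth`, `pose`, and
#'   `counts` (declared vertex/face counts per mesh).
#' @export
make_phantom <- function(truth, mesh_resolution = 1,
                         pose = c("canonical", "random"), seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  pose <- match.arg(pose)
  res <- mesh_resolution
  n_theta <- max(16L, round(40 * res))
  n_axial <- max(8L, round(30 * res))
  n_grid <- max(6L, round(20 * res))

  L_R <- truth$bone_lengths[["radius"]]; L_U <- truth$bone_lengths[["ulna"]]
  r_R <- truth$bone_radii[["radius"]]; r_U <- truth$bone_radii[["ulna"]]
  off <- truth$ulna_distal_offset
  x_ulna_centre <- truth$attachment_x[["ulnar"]] + r_U

  radius <- cylinder_mesh(c(0, 0), 0, L_R, r_R, n_theta, n_axial, "radius")
  ulna <- cylinder_mesh(c(x_ulna_centre, 0), off, off + L_U, r_U,
                        n_theta, n_axial, "ulna")
  patches <- lapply(truth$ligaments, function(l)
    slab_patch_mesh(l, truth$attachment_x, n_grid))
  membrane <- concat_meshes(patches, "membrane")

  for (m in list(radius, ulna, membrane))
    if (nrow(m$faces) < 200L)
      stopf("mesh_resolution %.2f yields only %d faces for '%s'; need >= 200",
            res, nrow(m$faces), m$name)

  landmarks <- lapply(truth$ligaments, `[[`, "landmarks")
  axes <- list(
    radius = bone_axis(c(0, 0, 0), c(0, 0, 1), L_R),
    ulna = bone_axis(c(x_ulna_centre, 0, off), c(0, 0, 1), L_U))

  rot <- diag(3); tra <- c(0, 0, 0)
  if (pose == "random") {
    if (is.null(seed)) stopf("pose = 'random' requires a seed")
    with_seed(seed, {
      rot <- random_rotation()
      tra <- stats::runif(3, -100, 100)
    })
  }
  if (pose == "random") {
    radius <- transform_mesh(radius, rot, tra)
    ulna <- transform_mesh(ulna, rot, tra)
    membrane <- transform_mesh(membrane, rot, tra)
    landmarks <- lapply(landmarks, transform_landmarks, rotation = rot,
                        translation = tra)
    axes <- lapply(axes, function(a)
      bone_axis(as.numeric(rot %*% a$distal_point) + tra,
                as.numeric(rot %*% a$direction), a$length))
  }

  structure(list(
    radius = radius, ulna = ulna, membrane = membrane,
    landmarks = landmarks, axes = axes, truth = truth,
    pose = list(rotation = rot, translation = tra),
    counts = list(
      radius = c(vertices = nrow(radius$vertices), faces = nrow(radius$faces)),
      ulna = c(vertices = nrow(ulna$vertices), faces = nrow(ulna$faces)),
      membrane = c(vertices = nrow(membrane$vertices), faces = nrow(membrane$faces)))),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %d ligament(s); radius %d faces, ulna %d faces, membrane %d faces>\n",
              length(x$landmarks), nrow(x$radius$faces), nrow(x$ulna$faces),
              nrow(x$membrane$faces)))
  invisible(x)
}

## Watertight capped cylinder along +z, centre (cx, cy), from z0 to z1.
cylinder_mesh <- function(centre, z0, z1, r, n_theta, n_axial, name) {
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  zs <- seq(z0, z1, length.out = n_axial + 1L)
  ring_x <- centre[1] + r * cos(th)
  ring_y <- centre[2] + r * sin(th)
  v <- cbind(rep(ring_x, n_axial + 1L),
             rep(ring_y, n_axial + 1L),
             rep(zs, each = n_theta))
  v <- rbind(v, c(centre[1], centre[2], z0), c(centre[1], centre[2], z1))
  c0 <- (n_axial + 1L) * n_theta + 1L   # bottom cap centre
  c1 <- c0 + 1L                         # top cap centre
  id <- function(k, j) (k - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  f <- vector("list", n_axial + 2L)
  for (k in seq_len(n_axial)) {
    j <- seq_len(n_theta)
    a <- id(k, j); b <- id(k, j + 1L); cc <- id(k + 1L, j); d <- id(k + 1L, j + 1L)
    f[[k]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  j <- seq_len(n_theta)
  f[[n_axial + 1L]] <- cbind(id(1L, j + 1L), id(1L, j), c0)
  f[[n_axial + 2L]] <- cbind(id(n_axial + 1L, j), id(n_axial + 1L, j + 1L), c1)
  surface_mesh(v, do.call(rbind, f), name)
}

## Thin ruled solid for one ligament patch: mid-surface between the radial
## and ulnar attachment edges, offset by +-T(u)/2 in y, closed by four
## walls. u runs radial -> ulnar, v distal -> proximal.
slab_patch_mesh <- function(lig, attachment_x, n_grid) {
  nu <- n_grid; nv <- n_grid
  u <- seq(0, 1, length.out = nu + 1L)
  v <- seq(0, 1, length.out = nv + 1L)
  x_R <- attachment_x[["radial"]]; x_U <- attachment_x[["ulnar"]]
  z <- lig$z
  ## grids: rows index u, cols index v
  X <- matrix(x_R + u * (x_U - x_R), nu + 1L, nv + 1L)
  Zr <- z[["Rd"]] + outer(rep(1, nu + 1L), v) * (z[["Rp"]] - z[["Rd"]])
  Zu <- z[["Ud"]] + outer(rep(1, nu + 1L), v) * (z[["Up"]] - z[["Ud"]])
  Z <- (1 - u) * Zr + u * Zu
  Tu <- lig$thickness[["radial"]] +
    u * (lig$thickness[["ulnar"]] - lig$thickness[["radial"]])
  Y <- matrix(Tu / 2, nu + 1L, nv + 1L)
  top <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  bot <- cbind(as.vector(X), -as.vector(Y), as.vector(Z))
  nvert <- (nu + 1L) * (nv + 1L)
  idx <- function(i, j) (j - 1L) * (nu + 1L) + i   # column-major like as.vector
  faces <- vector("list", 6L)
  i <- rep(seq_len(nu), nv); j <- rep(seq_len(nv), each = nu)
  a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
  faces[[1L]] <- rbind(cbind(a, b, d), cbind(a, d, cc))                    # top
  faces[[2L]] <- rbind(cbind(a, d, b), cbind(a, cc, d)) + nvert            # bottom
  stitch <- function(loop) {
    n <- length(loop)
    s <- loop[-n]; e <- loop[-1L]
    rbind(cbind(s, e, e + nvert), cbind(s, e + nvert, s + nvert))
  }
  faces[[3L]] <- stitch(idx(1L, seq_len(nv + 1L)))            # radial wall
  faces[[4L]] <- stitch(idx(nu + 1L, seq_len(nv + 1L)))       # ulnar wall
  faces[[5L]] <- stitch(idx(seq_len(nu + 1L), 1L))            # distal wall
  faces[[6L]] <- stitch(idx(seq_len(nu + 1L), nv + 1L))       # proximal wall
  surface_mesh(rbind(top, bot), do.call(rbind, faces), lig$id)
}

## Concatenate meshes into one (multi-shell) surface_mesh.
concat_meshes <- function(meshes, name) {
  offs <- cumsum(c(0L, vapply(meshes, function(m) nrow(m$vertices), 0L)))
  v <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  f <- do.call(rbind, Map(function(m, o) m$faces + o, meshes,
                          offs[seq_along(meshes)]))
  surface_mesh(v, f, name)
}
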