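# Shared fixtures, all built in code.

# Unit tetrahedron as ASCII STL (4 vertices, 4 faces after merging).
write_tetra_stl <- function(path) {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  lines <- c("solid tetra")
  for (i in seq_len(nrow(f))) {
    tri <- v[f[i, ], , drop = FALSE]
    lines <- c(lines, "  facet normal 0 0 0", "    outer loop",
               sprintf("      vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
               "    endloop", "  endfacet")
  }
  writeLines(c(lines, "endsolid tetra"), path)
  path
}

tetra_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
               name = "tetra")
}

# Default phantom, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())
default_phantom <- function() {
  if (is.null(.fixture_cache$ph))
    .fixture_cache$ph <- make_phantom(phantom_truth())
  .fixture_cache$ph
}
phantom_axes <- function(ph) {
  key <- "axes"
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- list(
      radius = estimate_bone_axis(ph$radius, ph$axes$radius$distal_point),
      ulna = estimate_bone_axis(ph$ulna, ph$axes$ulna$distal_point))
  .fixture_cache[[key]]
}

# Seeded phantom truth with spans, angle and thickness fields jittered
# around the cadaveric table magnitudes (layout kept non-overlapping).
phantom_truth_jittered <- function(seed) {
  set.seed(seed)
  ligs <- list(
    list(id = "DOB", radial_span = c(10.0, 17.5) + runif(1, -0.3, 0.3),
         ulnar_span = c(11.0, 19.1) + runif(1, -0.3, 0.3),
         thickness = runif(1, 5, 7)),
    list(id = "AB", radial_span = c(39.3, 48.6) + runif(1, -0.3, 0.3),
         ulnar_span = c(19.8, 28.5) + runif(1, -0.3, 0.3),
         thickness = runif(1, 2, 4)),
    list(id = "CB", radial_span = c(51.7, 65.1) + runif(1, -0.3, 0.3),
         ulnar_span = c(32.9, 46.4) + runif(1, -0.3, 0.3),
         thickness = c(radial = runif(1, 1.5, 2.5), ulnar = runif(1, 4.5, 5.5))),
    list(id = "DOAC", radial_mid = 70.5 + runif(1, -1, 1),
         fan_out = -18.7 + runif(1, -2, 2), width = 9.2,
         thickness = runif(1, 3, 6)))
  phantom_truth(ligaments = ligs)
}

# Seeded feasible tensile truth spanning the tabulated tensile magnitudes.
random_tensile_truth <- function(seed, noise_frac = 0) {
  set.seed(seed)
  k <- runif(1, 22, 155)
  toe <- runif(1, 0.3, 0.8)
  lin_span <- runif(1, 1.5, 3.5)
  F_t <- 0.5 + k * toe / 2
  F1 <- F_t + k * lin_span
  Fu <- F1 * runif(1, 1.1, 2.2)
  d_u <- toe + lin_span + 0.3 + runif(1, 2, 8)
  strain <- runif(1, 1.3, 6.2)
  tensile_truth(stiffness = k, first_peak_force = F1, ultimate_force = Fu,
                ultimate_strain = strain, gauge_length = 100 * d_u / strain,
                toe_span = toe, noise_sd = noise_frac * Fu, seed = seed,
                ligament_id = "SYN", specimen_id = sprintf("s%03d", seed))
}

# Per-ligament recovery errors of one phantom against its own truth.
phantom_recovery_errors <- function(truth, seed, mesh_resolution = 1) {
  ph <- make_phantom(truth, mesh_resolution = mesh_resolution,
                     pose = "random", seed = seed)
  ra <- estimate_bone_axis(ph$radius, ph$axes$radius$distal_point)
  ua <- estimate_bone_axis(ph$ulna, ph$axes$ulna$distal_point)
  out <- list(angle = 0, pct = 0, width = 0, thickness = 0)
  for (id in names(truth$ligaments)) {
    tl <- truth$ligaments[[id]]
    rec <- measure_ligament(ph$membrane, ph$landmarks[[id]], ra, ua,
                            clip_half_width = tl$clip_half_width)
    att <- rec$attachment
    for (i in seq_len(nrow(att))) {
      pos <- att$position[i]
      out$angle <- max(out$angle, abs(att$fan_out_deg[i] - tl$fan_out[[pos]]))
      tr_r <- if (pos == "m") mean(tl$radial_span) else
        tl$radial_span[if (pos == "p") 2L else 1L]
      tr_u <- if (pos == "m") mean(tl$ulnar_span) else
        tl$ulnar_span[if (pos == "p") 2L else 1L]
      out$pct <- max(out$pct, abs(att$radial_pct[i] - tr_r),
                     abs(att$ulnar_pct[i] - tr_u))
    }
    if (id != "DOAC") {
      out$width <- max(out$width,
                       abs(rec$width_radial - tl$widths[["radial"]]),
                       abs(rec$width_ulnar - tl$widths[["ulnar"]]))
    }
    out$thickness <- max(out$thickness,
                         abs(rec$thickness_mean - tl$thickness_mean))
  }
  out
}
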