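test_that("bone axis of a z-aligned cylinder is recovered exactly", {
  ph <- default_phantom()
  ax <- estimate_bone_axis(ph$radius, c(0, 0, -10))
  expect_lt(abs(ax$length - 254.4), 0.5)
  expect_lt(acos(min(1, abs(sum(ax$direction * c(0, 0, 1))))) * 180 / pi, 0.01)
  expect_equal(unname(ax$distal_point[3]), 0, tolerance = 1e-9)
})

test_that("bone axis follows a known rigid rotation within 0.1 degree", {
  ph <- default_phantom()
  R <- rotation_about(c(1, 2, 0.5), 37)
  tra <- c(12, -7, 30)
  rotated <- transform_mesh(ph$radius, R, tra)
  hint <- as.numeric(R %*% c(0, 0, -10)) + tra
  ax <- estimate_bone_axis(rotated, hint)
  target <- as.numeric(R %*% c(0, 0, 1))
  ang <- acos(min(1, abs(sum(ax$direction * target)))) * 180 / pi
  expect_lt(ang, 0.1)
  expect_gt(sum(ax$direction * target), 0)  # distal->proximal orientation kept
})

test_that("a near-isotropic mesh is rejected as degenerate", {
  set.seed(1)
  th <- runif(600, 0, pi); phi <- runif(600, 0, 2 * pi)
  v <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  f <- t(vapply(seq_len(200), function(i) ((i - 1) * 3 + 1):((i - 1) * 3 + 3),
                integer(3)))
  sphere <- surface_mesh(v[as.vector(t(f)), ], matrix(seq_len(600), ncol = 3,
                                                      byrow = TRUE),
                         validate = FALSE)
  expect_error(estimate_bone_axis(sphere, c(0, 0, -2)), "degeneracy")
})

test_that("fibre vectors are ulnar minus radial with the role layout per ligament", {
  lm <- landmark_set("CB", list(R_p = c(0, 0, 0), R_d = c(0, 0, -5),
                                U_p = c(10, 0, 0), U_d = c(10, 0, -6)))
  fv <- fibre_vectors(lm)
  expect_named(fv, c("p", "d"))
  expect_equal(fv$p$vector, c(10, 0, 0))
  expect_equal(fv$p$unit, c(1, 0, 0))
  doac <- landmark_set("DOAC", list(R_m = c(0, 0, 0), U_m = c(3, 4, 0)))
  fm <- fibre_vectors(doac)
  expect_named(fm, "m")
  expect_equal(vnorm(fm$m$vector), 5)
})

test_that("fan-out angle magnitude and sign convention", {
  axis <- bone_axis(c(0, 0, 0), c(0, 0, 1), 100)
  expect_identical(fan_out_angle(c(0, 0, 2), axis), 0)       # parallel
  expect_equal(fan_out_angle(c(1, 0, -1), axis), 45)         # distal component
  expect_equal(fan_out_angle(c(1, 0, 1), axis), -45)         # proximal component
  expect_equal(fan_out_angle(c(1, 0, 0), axis), 90)          # perpendicular
  expect_error(fan_out_angle(c(0, 0, 0), axis), "degeneracy")
})

test_that("fan-out angle is invariant under common rigid transforms", {
  set.seed(42)
  for (i in 1:25) {
    v <- rnorm(3); a <- unit3(rnorm(3))
    base <- fan_out_angle(v, bone_axis(c(0, 0, 0), a, 50))
    R <- random_rotation(); tr <- runif(3, -20, 20)
    moved <- fan_out_angle(as.numeric(R %*% v),
                           bone_axis(tr, as.numeric(R %*% a), 50))
    expect_lt(abs(base - moved), 1e-9)
  }
})

test_that("attachment percentage projects on the axis and clamps with warning", {
  axis <- bone_axis(c(1, 2, 3), c(0, 0, 1), 200)
  expect_equal(attachment_percentage(c(1, 2, 3), axis), 0)
  expect_equal(attachment_percentage(c(1, 2, 203), axis), 100)
  expect_equal(attachment_percentage(c(5, -4, 103), axis), 50)
  expect_warning(p <- attachment_percentage(c(1, 2, 300), axis), "outside")
  expect_equal(p, 100)
})

test_that("attachment width is the axial projection (or chord on request)", {
  axis <- bone_axis(c(0, 0, 0), c(0, 0, 1), 100)
  expect_equal(attachment_width(c(0, 0, 40), c(5, 5, 40), axis), 0)
  expect_equal(attachment_width(c(0, 0, 73.9), c(0, 0, 40), axis), 33.9)
  expect_equal(attachment_width(c(3, 4, 12), c(0, 0, 0), axis,
                                mode = "euclidean"), 13)
})

test_that("attachment measures are invariant under common rigid transforms", {
  set.seed(7)
  axis <- bone_axis(c(0, 0, 0), c(0, 0, 1), 254.4)
  p1 <- c(7.5, 0, 165.6); p2 <- c(7.5, 0, 131.5)
  base_pct <- attachment_percentage(p1, axis)
  base_w <- attachment_width(p1, p2, axis)
  for (i in 1:10) {
    R <- random_rotation(); tr <- runif(3, -50, 50)
    ax2 <- bone_axis(tr, as.numeric(R %*% c(0, 0, 1)), 254.4)
    q1 <- as.numeric(R %*% p1) + tr; q2 <- as.numeric(R %*% p2) + tr
    expect_lt(abs(attachment_percentage(q1, ax2) - base_pct), 1e-9)
    expect_lt(abs(attachment_width(q1, q2, ax2) - base_w), 1e-9)
  }
})

test_that("clipping with planes outside the mesh preserves area; ligament pieces are disjoint and conservative", {
  ph <- default_phantom()
  tr <- ph$truth
  axes <- phantom_axes(ph)
  total <- mesh_area(ph$membrane)
  ## slab covering everything: no-clip identity
  far <- clip_mesh_halfspace(ph$membrane, c(0, 0, 1e4), c(0, 0, 1))
  expect_equal(mesh_area(far), total, tolerance = 1e-9)
  ## each clipped ligament matches its analytic patch area
  pieces <- lapply(names(tr$ligaments), function(id)
    split_ligament(ph$membrane, ph$landmarks[[id]], axes$radius,
                   clip_half_width = tr$ligaments[[id]]$clip_half_width))
  areas <- vapply(pieces, mesh_area, 0)
  truth_areas <- vapply(tr$ligaments, `[[`, 0, "area")
  expect_true(all(abs(areas / truth_areas - 1) < 0.02))
  expect_true(all(areas <= total + 1e-6))
  expect_lte(sum(areas), total * (1 + 1e-9))
  ## disjoint: pairwise shared area is zero because the pieces partition
  expect_lt(abs(sum(areas) - total), total * 0.02)
})

test_that("clipping planes that bound nothing raise an empty-result error", {
  ph <- default_phantom()
  lm <- landmark_set("DOAC", list(R_m = c(7.5, 0, 250), U_m = c(25.5, 0, 260)))
  expect_error(split_ligament(ph$membrane, lm, phantom_axes(ph)$radius,
                              clip_half_width = 0.5), "empty-result")
})

test_that("thickness profile errors when the slab misses the membrane", {
  ph <- default_phantom()
  ra <- phantom_axes(ph)$radius
  expect_error(thickness_profile(ph$membrane, c(1, 0, 0), c(0, 0, 5000),
                                 reference = ra), "empty-profile")
})

test_that("average thickness pools stations with population SD", {
  prof <- function(th) structure(list(thickness = th), class = "thickness_profile")
  a <- average_thickness(prof(c(2, 2, 2)))
  expect_equal(a$mean, 2); expect_equal(a$sd, 0); expect_equal(a$range, c(2, 2))
  b <- average_thickness(list(prof(c(1, NA)), prof(c(3))))
  expect_equal(b$mean, 2); expect_equal(b$sd, 1); expect_equal(b$range, c(1, 3))
  expect_error(average_thickness(prof(c(NA_real_, NA_real_))), "empty-data")
})

test_that("thickness against axial position fits the exact line", {
  fit <- thickness_axial_trend(data.frame(axial_pct = c(0, 50, 100),
                                          thickness = c(1, 2, 3)))
  expect_equal(unname(fit["slope"]), 0.02, tolerance = 1e-12)
  expect_equal(unname(fit["intercept"]), 1, tolerance = 1e-12)
  flat <- thickness_axial_trend(data.frame(axial_pct = c(0, 50, 100),
                                           thickness = c(2, 2, 2)))
  expect_equal(unname(flat["slope"]), 0)
  expect_error(thickness_axial_trend(data.frame(axial_pct = c(10, 10),
                                                thickness = c(1, 2))),
               "degeneracy")
})

test_that("thickness declines toward the proximal end when generated so", {
  ligs <- list(
    list(id = "DOB", radial_span = c(10, 17.5), ulnar_span = c(11, 19.1),
         thickness = 6),
    list(id = "CB", radial_span = c(51.7, 65.1), ulnar_span = c(32.9, 46.4),
         thickness = 4),
    list(id = "DOAC", radial_mid = 75, fan_out = -18.7, width = 9.2,
         thickness = 2))
  ph <- make_phantom(phantom_truth(ligaments = ligs))
  ra <- estimate_bone_axis(ph$radius, ph$axes$radius$distal_point)
  ua <- estimate_bone_axis(ph$ulna, ph$axes$ulna$distal_point)
  recs <- lapply(seq_along(ligs), function(i) {
    id <- ligs[[i]]$id
    measure_ligament(ph$membrane, ph$landmarks[[id]], ra, ua,
                     clip_half_width = ph$truth$ligaments[[id]]$clip_half_width)
  })
  df <- data.frame(
    axial_pct = vapply(recs, function(r) mean(r$attachment$radial_pct), 0),
    thickness = vapply(recs, function(r) r$thickness_mean, 0))
  fit <- thickness_axial_trend(df)
  expect_lt(unname(fit["slope"]), 0)
})

test_that("phantom parameter recovery stays within the measurement tolerances", {
  ## three seeded phantoms at cadaveric magnitudes under random rigid poses
  for (seed in c(101, 202, 303)) {
    err <- phantom_recovery_errors(phantom_truth_jittered(seed), seed)
    expect_lt(err$angle, 0.5)
    expect_lt(err$pct, 0.5)
    expect_lt(err$width, 0.1)
    expect_lt(err$thickness, 0.05)
  }
})
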