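test_that("phantom landmarks reproduce the declared attachment percentages exactly", {
  ph <- default_phantom()
  tr <- ph$truth
  axes <- phantom_axes(ph)
  cb <- tr$ligaments$CB
  lm <- ph$landmarks$CB
  expect_equal(attachment_percentage(lm$points$R_p, axes$radius),
               cb$radial_span[2], tolerance = 1e-9)
  expect_equal(attachment_percentage(lm$points$R_d, axes$radius),
               cb$radial_span[1], tolerance = 1e-9)
  expect_equal(attachment_percentage(lm$points$U_p, axes$ulna),
               cb$ulnar_span[2], tolerance = 1e-9)
  expect_equal(attachment_percentage(lm$points$U_d, axes$ulna),
               cb$ulnar_span[1], tolerance = 1e-9)
  ## CB spans at the cadaveric magnitudes: 51.7-65.1% radial, 32.9-46.4% ulnar
  expect_equal(cb$radial_span, c(51.7, 65.1))
  expect_equal(cb$ulnar_span, c(32.9, 46.4))
})

test_that("phantom generation is deterministic for a fixed seed and pose", {
  tr <- phantom_truth_jittered(11)
  a <- make_phantom(tr, pose = "random", seed = 5)
  b <- make_phantom(tr, pose = "random", seed = 5)
  expect_identical(a$membrane$vertices, b$membrane$vertices)
  expect_identical(a$landmarks$CB$points, b$landmarks$CB$points)
  c <- make_phantom(tr, pose = "random", seed = 6)
  expect_false(identical(a$membrane$vertices, c$membrane$vertices))
})

test_that("mesh surface areas match the generator's closed-form areas", {
  ph <- default_phantom()
  tr <- ph$truth
  patches <- vapply(tr$ligaments, `[[`, 0, "area")
  expect_equal(mesh_area(ph$membrane), sum(patches), tolerance = 1e-6)
})

test_that("overlapping attachment spans are a configuration error", {
  ligs <- list(
    list(id = "CB", radial_span = c(51.7, 65.1), ulnar_span = c(32.9, 46.4),
         thickness = 3),
    list(id = "AB", radial_span = c(60, 70), ulnar_span = c(10, 20),
         thickness = 3))
  expect_error(phantom_truth(ligaments = ligs), "overlap")
})

test_that("perpendicular-fibre slab of constant thickness recovers 1 mm at every station", {
  ## an ulnar span at the same axial heights as the radial span makes every
  ## fibre perpendicular to the bone axes (fan-out +90): the flat-slab case
  tr <- phantom_truth(ligaments = list(
    list(id = "CB", radial_span = c(40, 55),
         ulnar_span = c(40, 55) * 254.4 / 271.5, thickness = 1)))
  cb <- tr$ligaments$CB
  expect_lt(abs(cb$z[["Ud"]] - cb$z[["Rd"]]), 1e-9)
  expect_equal(unname(cb$fan_out[["d"]]), 90)
  ph <- make_phantom(tr)
  axes <- list(radius = estimate_bone_axis(ph$radius, ph$axes$radius$distal_point),
               ulna = estimate_bone_axis(ph$ulna, ph$axes$ulna$distal_point))
  fv <- fibre_vectors(ph$landmarks$CB)
  pr <- thickness_profile(ph$membrane, fv$d, (fv$d$radial + fv$d$ulnar) / 2,
                          reference = axes$radius)
  ok <- !is.na(pr$thickness)
  expect_gt(sum(ok), 50)
  expect_true(all(abs(pr$thickness[ok] - 1) <= 0.02))
})

test_that("a linear thickness ramp yields the analytic per-station profile", {
  tr <- phantom_truth(ligaments = list(
    list(id = "CB", radial_span = c(45, 60), ulnar_span = c(30, 44),
         thickness = c(radial = 1, ulnar = 3))))
  ph <- make_phantom(tr)
  ra <- estimate_bone_axis(ph$radius, ph$axes$radius$distal_point)
  fv <- fibre_vectors(ph$landmarks$CB)
  anchor <- (fv$d$radial + fv$d$ulnar) / 2
  pr <- thickness_profile(ph$membrane, fv$d, anchor, reference = ra)
  ## analytic field along the fibre: T grows linearly from 1 at the radial
  ## edge to 3 at the ulnar edge
  ell <- vnorm(fv$d$vector)
  expected <- 1 + clamp((pr$stations + ell / 2) / ell, 0, 1) * 2
  ok <- which(!is.na(pr$thickness))
  interior <- ok[ok > min(ok) + 2 & ok < max(ok) - 2]
  expect_true(all(abs(pr$thickness[interior] - expected[interior]) <= 0.05))
  ## fitted slope equals the declared ramp slope
  fit <- stats::coef(stats::lm(pr$thickness[ok] ~ pr$stations[ok]))
  expect_lt(abs(unname(fit[2]) - 2 / ell), 0.005)
})

test_that("synthetic tensile curves have the declared biphasic anatomy", {
  tr <- tensile_truth(stiffness = 43.53, first_peak_force = 68.81,
                      ultimate_force = 198.77, ultimate_strain = 3.36,
                      gauge_length = 300, toe_span = 0.4)
  cu <- make_tensile_curve(tr)
  d <- attr(cu, "truth")
  expect_equal(cu$force[1], tr$preload)
  expect_equal(max(cu$force), tr$ultimate_force, tolerance = 1e-6)
  iu <- which.max(cu$force)
  expect_lt(abs(cu$displacement[iu] - d$d_ultimate), 0.011)
  ## first peak then a drop of >= 10% before the ultimate
  i1 <- which.min(abs(cu$displacement - d$d_first_peak))
  expect_lt(abs(cu$force[i1] - tr$first_peak_force), 0.7)
  expect_lte(min(cu$force[i1:iu]), 0.9 * tr$first_peak_force)
  ## tail falls below 95% of the ultimate
  expect_lt(min(cu$force[iu:length(cu$force)]), 0.95 * tr$ultimate_force)
  ## linear segment has the declared slope
  seg <- cu$displacement > d$d_toe & cu$displacement < d$d_first_peak
  slopes <- diff(cu$force[seg]) / diff(cu$displacement[seg])
  expect_true(all(abs(slopes - 43.53) < 1e-6))
})

test_that("degenerate monophasic curve keeps first peak equal to ultimate", {
  tr <- tensile_truth(stiffness = 50, first_peak_force = 120,
                      ultimate_force = 120, ultimate_strain = 3,
                      gauge_length = 100)
  cu <- make_tensile_curve(tr)
  pk <- detect_peaks(preprocess_curve(cu))
  expect_equal(pk$first_peak_force, pk$ultimate_force)
})

test_that("same truth and seed give identical curves; config errors are caught", {
  tr <- random_tensile_truth(9, noise_frac = 0.02)
  a <- make_tensile_curve(tr)
  b <- make_tensile_curve(tr)
  expect_identical(a$force, b$force)
  ## ultimate inside the toe region is rejected
  expect_error(
    make_tensile_curve(tensile_truth(stiffness = 50, first_peak_force = 100,
                                     ultimate_force = 150,
                                     ultimate_strain = 0.3,
                                     gauge_length = 100, toe_span = 0.5)),
    "configuration error")
})

test_that("curve generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_tensile_curve(random_tensile_truth(5, noise_frac = 0.02)))
  set.seed(123)
  after <- runif(1)
  expect_identical(before, after)
})
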