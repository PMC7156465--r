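test_that("trapezoidal CSA formula and its limits", {
  expect_equal(trapezoid_csa(10, 10, 2), 20)
  ## DOB cross-table consistency: calliper widths with CCD-laser thickness
  expect_equal(trapezoid_csa(18.3, 28.2, 2.17), 50.4525)
  expect_lt(trapezoid_csa(5, 5, 1e-9), 1e-8)
  expect_error(trapezoid_csa(-1, 10, 2), "domain")
})

test_that("nominal stress is force over initial CSA", {
  expect_equal(nominal_stress(100, 50), 2)
  expect_equal(nominal_stress(0, 50), 0)
  expect_equal(nominal_stress(198.77, 130.00), 1.529, tolerance = 1e-3)
  expect_error(nominal_stress(10, 0), "domain")
})

test_that("preprocessing zeroes displacement at preload and truncates the tail", {
  cfg <- pipeline_config()
  ## curve already starting at the preload keeps its origin
  tr <- tensile_truth(stiffness = 40, first_peak_force = 80,
                      ultimate_force = 150, ultimate_strain = 4,
                      gauge_length = 200)
  cu <- make_tensile_curve(tr)
  pc <- preprocess_curve(cu, cfg)
  expect_equal(pc$displacement[1], 0)
  expect_equal(pc$force[1], cu$force[1])
  ## truncation lands at the generator's analytic 95% crossing
  d <- attr(cu, "truth")
  expect_lt(abs(max(pc$displacement) - d$d_stop95), 2 * d$sample_step)
  expect_gte(min(pc$force[pc$displacement >= d$d_ultimate]),
             0.95 * tr$ultimate_force - 1e-9)
  ## force never reaching the preload is an error
  flat <- suppressWarnings(tensile_curve(seq(0, 1, 0.1), rep(0, 11), 30))
  expect_error(preprocess_curve(flat, cfg), "insufficient-load")
})

test_that("an exact line is fit with slope 40, r2 = 1, over the full pre-peak span", {
  x <- seq(0, 5, by = 0.01)
  cu <- suppressWarnings(tensile_curve(x, 40 * x, 100))
  lin <- detect_linear_region(cu)
  expect_equal(lin$slope, 40, tolerance = 1e-9)
  expect_equal(lin$r2, 1, tolerance = 1e-9)
  expect_equal(lin$strain_lo, 0)
  expect_equal(lin$strain_hi, 5, tolerance = 1e-9)
})

test_that("stiffness is linear in force and invariant to force offsets", {
  tr <- tensile_truth(stiffness = 27.71, first_peak_force = 132.60,
                      ultimate_force = 196.57, ultimate_strain = 3.80,
                      gauge_length = 300)
  cu <- make_tensile_curve(tr)
  pc <- preprocess_curve(cu)
  k1 <- stiffness(pc)
  expect_equal(k1, 27.71, tolerance = 5e-3)
  double <- tensile_curve(pc$displacement, 2 * pc$force, pc$gauge_length)
  expect_equal(stiffness(double), 2 * k1, tolerance = 1e-9)
  shift <- tensile_curve(pc$displacement, pc$force + 5, pc$gauge_length)
  expect_equal(stiffness(shift), k1, tolerance = 1e-9)
})

test_that("a linear region placed at 1-3% strain is recovered there", {
  gauge <- 150
  toe <- 0.01 * gauge
  k <- 43.53
  F_t <- 0.5 + k * toe / 2
  F1 <- F_t + k * (0.02 * gauge)      # linear segment spans 1% to 3% strain
  tr <- tensile_truth(stiffness = k, first_peak_force = F1,
                      ultimate_force = 1.6 * F1, ultimate_strain = 6,
                      gauge_length = gauge, toe_span = toe)
  lin <- detect_linear_region(preprocess_curve(make_tensile_curve(tr)))
  expect_gte(lin$strain_lo, 0.8)
  expect_lte(lin$strain_hi, 3.2)
  expect_equal(lin$slope, k, tolerance = 5e-3)
})

test_that("biphasic peaks and ultimate strain are recovered; monophasic degenerates", {
  tr <- tensile_truth(stiffness = 33.09, first_peak_force = 68.81,
                      ultimate_force = 198.77, ultimate_strain = 3.36,
                      gauge_length = 320)
  cu <- make_tensile_curve(tr)
  pk <- detect_peaks(preprocess_curve(cu))
  step_force <- max(abs(diff(cu$force)))
  expect_lt(abs(pk$first_peak_force - 68.81), step_force)
  expect_lt(abs(pk$ultimate_force - 198.77), step_force)
  expect_lt(abs(pk$ultimate_strain - 3.36), 100 * 0.01 / 320 + 1e-9)
  ## monotone rise then terminal drop: first peak equals ultimate
  x <- seq(0, 10, by = 0.05)
  y <- ifelse(x <= 8, 10 * x, 80 - 30 * (x - 8))
  mono <- tensile_curve(x, y, 250)
  pk2 <- detect_peaks(mono)
  expect_equal(pk2$first_peak_force, pk2$ultimate_force)
  ## arithmetic: ultimate at 1.008 mm on a 30 mm gauge is 3.36% strain
  xx <- seq(0, 1.2, by = 0.001)
  yy <- 100 - 500 * (xx - 1.008)^2
  arith <- tensile_curve(xx, yy, 30)
  expect_equal(detect_peaks(arith)$ultimate_strain, 3.36, tolerance = 1e-9)
  expect_error(detect_peaks(suppressWarnings(tensile_curve(c(0, 1, 2), c(0, 1, 2), 30))),
               "insufficient-data")
})

test_that("scale equivariance of the tensile measures", {
  tr <- random_tensile_truth(21)
  cu <- preprocess_curve(make_tensile_curve(tr))
  base <- list(k = stiffness(cu), pk = detect_peaks(cu))
  kf <- 2.5
  fscaled <- tensile_curve(cu$displacement, kf * cu$force, cu$gauge_length)
  expect_equal(stiffness(fscaled), kf * base$k, tolerance = 1e-9)
  pkf <- detect_peaks(fscaled)
  expect_equal(pkf$first_peak_force, kf * base$pk$first_peak_force, tolerance = 1e-9)
  expect_equal(pkf$ultimate_force, kf * base$pk$ultimate_force, tolerance = 1e-9)
  expect_equal(nominal_stress(kf * 10, 5), kf * nominal_stress(10, 5))
  kd <- 1.7
  dscaled <- tensile_curve(kd * cu$displacement, cu$force, cu$gauge_length)
  expect_equal(stiffness(dscaled), base$k / kd, tolerance = 1e-9)
  expect_equal(detect_peaks(dscaled)$ultimate_strain,
               kd * base$pk$ultimate_strain, tolerance = 1e-9)
})

test_that("noise-free recovery across seeded truths is sharp", {
  for (seed in 1:12) {
    tr <- random_tensile_truth(seed)
    cu <- make_tensile_curve(tr)
    res <- analyse_tensile_curve(cu)
    step_force <- max(abs(diff(cu$force)))
    expect_lt(abs(res$stiffness / tr$stiffness - 1), 0.005)
    expect_lt(abs(res$first_peak_force - tr$first_peak_force), step_force)
    expect_lt(abs(res$ultimate_force - tr$ultimate_force), step_force)
    expect_lt(abs(res$ultimate_strain - tr$ultimate_strain),
              100 * 0.01 / tr$gauge_length + 1e-9)
    expect_true(res$first_peak_force <= res$ultimate_force + 1e-9)
  }
})

test_that("with 2% force noise stiffness is recovered within 5% in most runs", {
  ok <- 0L
  n <- 20L
  for (seed in seq_len(n)) {
    tr <- random_tensile_truth(1000 + seed, noise_frac = 0.02)
    res <- suppressWarnings(analyse_tensile_curve(make_tensile_curve(tr)))
    if (abs(res$stiffness / tr$stiffness - 1) < 0.05) ok <- ok + 1L
  }
  expect_gte(ok / n, 0.9)
})
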