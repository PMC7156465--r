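test_that("aggregate reproduces the printed CB stiffness mean and SD", {
  k <- c(33.09, 27.71, 43.48, 34.02, 79.33)
  st <- aggregate_stats(k)
  expect_equal(round_half_up(st$mean, 2), 43.53)
  expect_equal(round_half_up(st$sd, 2), 18.61)
  ## the sample-SD (n - 1) convention demonstrably does not match
  expect_equal(round_half_up(stats::sd(k), 2), 20.80)
  expect_false(isTRUE(all.equal(round_half_up(stats::sd(k), 2), 18.61)))
})

test_that("single-value and tiny samples follow the table conventions", {
  one <- aggregate_stats(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  two <- aggregate_stats(c(1, 3))
  expect_equal(two$mean, 2)
  expect_equal(two$sd, 1)
  expect_equal(c(two$min, two$max), c(1, 3))
  expect_error(aggregate_stats(numeric(0)), "empty-data")
})

test_that("aggregate is permutation-invariant and translation-equivariant", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(7, 50, 10)
    a <- aggregate_stats(x)
    b <- aggregate_stats(sample(x))
    expect_equal(a$mean, b$mean); expect_equal(a$sd, b$sd)
    sh <- aggregate_stats(x + 13.7)
    expect_equal(sh$mean, a$mean + 13.7)
    expect_equal(sh$sd, a$sd, tolerance = 1e-9)
  }
})

test_that("the published per-forearm rows reproduce the printed summary rows", {
  ref <- reference_tensile_results()
  tab <- make_table(ref, values = c("csa", "first_peak_force",
                                    "ultimate_force", "stiffness",
                                    "ultimate_strain"))
  get <- function(lig, q, col) tab[tab$ligament_id == lig & tab$quantity == q, col]
  expect_equal(get("CB", "csa", "mean"), 136.19)
  expect_equal(get("CB", "first_peak_force", "mean"), 127.80)
  expect_equal(get("CB", "ultimate_force", "mean"), 187.93)
  expect_equal(get("CB", "stiffness", "mean"), 43.53)
  expect_equal(get("CB", "stiffness", "sd"), 18.61)
  expect_equal(get("CB", "ultimate_force", "sd"), 53.97)
  expect_equal(get("AB", "csa", "mean"), 60.48)
  expect_equal(get("AB", "ultimate_force", "mean"), 101.77)
  expect_equal(get("DOAC", "csa", "mean"), 35.30)
  ## strain means print at one decimal
  expect_equal(round_half_up(get("CB", "ultimate_strain", "mean"), 1), 4.4)
  expect_equal(round_half_up(get("AB", "ultimate_strain", "mean"), 1), 2.3)
  ## the single-forearm DOB row has empty SD and range
  expect_true(is.na(get("DOB", "csa", "sd")))
  expect_true(is.na(get("DOB", "csa", "min")))
})

test_that("make_table rejects mixed record types and warns on empty input", {
  a <- data.frame(ligament_id = "CB", x = 1)
  b <- data.frame(ligament_id = "CB", y = 1)
  expect_error(make_table(list(a, b)), "mixed record types")
  expect_warning(empty <- make_table(list()), "no records")
  expect_equal(nrow(empty), 0L)
})
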