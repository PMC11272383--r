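test_that("perturbation columns are permutations of the same log grid", {
  p <- baseline_parameters()
  b <- sample_parameter_sets(3, p, seed = 5)
  for (j in colnames(b$factors))
    expect_equal(sort(b$factors[, j]), c(0.1, 1, 10), tolerance = 1e-12)
  expect_identical(colnames(b$factors),
                   c(dampsim:::.perturbed_baseline))
  expect_error(sample_parameter_sets(1, p, seed = 5), "at least 2")
})

test_that("sampling is reproducible from the seed and marginally seed-invariant", {
  b1 <- sample_parameter_sets(50, seed = 7)
  b2 <- sample_parameter_sets(50, seed = 7)
  b3 <- sample_parameter_sets(50, seed = 8)
  expect_identical(b1$factors, b2$factors)
  expect_false(identical(b1$factors, b3$factors))
  for (j in colnames(b1$factors))
    expect_equal(sort(b1$factors[, j]), sort(b3$factors[, j]),
                 tolerance = 1e-12)
})

test_that("a collapsed perturbation range reproduces the baseline exactly", {
  b <- sample_parameter_sets(2, seed = 3, range = c(1, 1))
  expect_true(all(b$factors == 1))
  b <- evaluate_batch("A", b)
  expect_true(all(b$outcomes$complete))
  sw <- run_glucose_sweep("A")
  base <- loglog_slope(sw$final_density, sw$mutation_rate)
  # the batch evaluator samples a sparser output grid, so agreement is to
  # solver accuracy rather than bitwise
  expect_equal(b$outcomes$slope, rep(base$slope, 2), tolerance = 1e-4)
  filt <- apply_filters(b)
  expect_true(all(filt$pass$f5))
})

test_that("variant batches carry the variant extra constants", {
  b <- sample_parameter_sets(4, seed = 2, variant = "D")
  expect_true(all(c("ROSC2", "kdiff") %in% colnames(b$factors)))
  expect_identical(b$baseline[["O2"]], 40)
})

test_that("filters reject engineered failure modes stage by stage", {
  dens_ok <- matrix(rep(10^seq(7.5, 9, length.out = 5), each = 4), nrow = 4)
  rates_ok <- matrix(rep(10^seq(-9.4, -9.8, length.out = 5), each = 4),
                     nrow = 4)
  batch <- list(
    outcomes = data.frame(complete = rep(TRUE, 4),
                          slope = rep(-0.4, 4), r2 = rep(0.99, 4)),
    densities = dens_ok, rates = rates_ok,
    stationary = matrix(TRUE, 4, 5))
  batch$stationary[1, 3] <- FALSE                  # fails stationarity
  batch$densities[2, 1] <- 1e6                     # below the density band
  batch$densities[3, ] <- rev(dens_ok[3, ])        # density not increasing
  batch$rates[4, 5] <- 3e-8                        # above the rate band
  rep <- apply_filters(batch)
  expect_identical(unname(rep$counts),
                   c(4L, 3L, 2L, 1L, 0L, 0L))
  expect_true(all(diff(rep$counts) <= 0))
  # verdicts are monotone: failing stage k excludes from k+1 onward
  pass <- as.matrix(rep$pass[, -1])
  expect_true(all(pass[, -1] <= pass[, -5]))
})

test_that("slope summaries use interpolated quartiles", {
  s <- summarize_slopes(c(1, 2, 3, 4, 5))
  expect_identical(s$median, 3)
  expect_identical(s$q1, 2)
  expect_identical(s$q3, 4)
  expect_identical(summarize_slopes(rep(0.5, 6))$q3 -
                     summarize_slopes(rep(0.5, 6))$q1, 0)
  expect_error(summarize_slopes(c(1, 2, 3)), "at least 4")
})

test_that("rank correlations recover exact monotone relationships", {
  n <- 12
  slopes <- seq(-0.5, 0.6, length.out = n)
  batch <- list(
    factors = cbind(up = rank(slopes) + 0.0,
                    down = max(slopes) - slopes,
                    flat = rep(1, n)),
    outcomes = data.frame(complete = TRUE, slope = slopes, r2 = 0.9),
    rates = matrix(rep(10^seq(-9, -10, length.out = n), 5), ncol = 5),
    densities = matrix(rep(10^seq(7.5, 9, length.out = 5), each = n),
                       ncol = 5),
    stationary = matrix(TRUE, n, 5),
    glucose_list = canonical_glucose_grid())
  filters <- apply_filters(batch)
  rc <- rank_correlations(batch, filters)
  expect_equal(rc$rho_slope[rc$parameter == "up"], 1)
  expect_equal(rc$rho_slope[rc$parameter == "down"], -1)
  expect_true(is.na(rc$rho_slope[rc$parameter == "flat"]))
  expect_identical(rc$parameter[1], "up")
})
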