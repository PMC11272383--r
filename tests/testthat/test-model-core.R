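test_that("initial state matches the published inoculum", {
  s <- initial_state("A", 3.1e-4)
  expect_identical(s[["eGlc"]], 3.1e-4)
  expect_identical(s[["wtCell"]], 8.5e-12)
  expect_identical(s[["cytVol"]], 2.25e-9)
  expect_identical(s[["ROS"]], 0)
  expect_true(all(s[setdiff(names(s), c("eGlc", "wtCell", "cytVol"))] == 0))
  # implied cell count in the 1 ml culture: wtCell * molML / GCperGen
  p <- baseline_parameters()
  cells <- s[["wtCell"]] * p[["molML"]] / p[["GCperGen"]]
  expect_equal(cells, 2175, tolerance = 0.005)
  expect_equal(density_cfu_per_ml(s, p), cells)
  expect_error(initial_state("A", 0), "eGlc0")
  expect_error(initial_state("A", -1e-3), "eGlc0")
})

test_that("model A derivatives at the inoculum match hand evaluation", {
  p <- baseline_parameters()
  s <- initial_state("A", 3.1e-4)
  d <- rhs("A", 0, s, p)
  uptake <- p[["U1"]] * 8.5e-12 * 3.1e-4 / (3.1e-4 + p[["Ks"]])
  expect_equal(d[["eGlc"]], -uptake, tolerance = 1e-12)
  expect_equal(d[["eGlc"]], -2.004e-12, tolerance = 1e-3)
  expect_equal(d[["iGlc"]], uptake / 2.25e-9, tolerance = 1e-12)
  # no internal metabolites yet, so every other flux is silent
  others <- setdiff(names(d), c("eGlc", "iGlc"))
  expect_true(all(d[others] == 0))
})

test_that("the all-zero state is absorbing except for external peroxide input", {
  for (v in variant_ids()) {
    s <- setNames(numeric(length(state_names(v))), state_names(v))
    s[grep("cytVol", names(s))] <- 2.25e-9
    d <- rhs(v, 0, s)
    if (v %in% c("D", "D_coculture")) {
      # the external pool keeps filling at the constant rate ROSC2 even in
      # an empty culture; every other flux is silent
      expect_equal(d[["ROSexternal"]], 6e-11, tolerance = 1e-12)
      d <- d[setdiff(names(d), "ROSexternal")]
    }
    expect_true(all(d == 0), label = paste("variant", v))
  }
})

test_that("variant C replaces the ROS state with the printed constant", {
  expect_false("ROS" %in% state_names("C"))
  s <- initial_state("C", 3.1e-4)
  s["dGTP"] <- 1e-5
  d <- rhs("C", 0, s)
  p <- variant_parameters("C")
  expect_equal(d[["odGTP"]], 1e-5 * 1.8e-7 * p[["O2"]], tolerance = 1e-12)
})

test_that("pinning ROS at the variant-C constant reduces model A to model C", {
  p <- baseline_parameters()
  sC <- initial_state("C", 1e-3)
  sC[c("iGlc", "dGTP", "DNA", "odGTP", "mDNA", "mCell")] <-
    c(2e-3, 9e-5, 1e-5, 8e-11, 1e-12, 1e-14)
  sA <- c(sC, ROS = 1.8e-7)[state_names("A")]
  pA <- p; pA[["r"]] <- 1e-300   # silence metabolic peroxide production
  dA <- rhs("A", 0, sA, pA)
  dC <- rhs("C", 0, sC, p)
  shared <- state_names("C")
  expect_equal(dA[shared], dC[shared], tolerance = 1e-10)
})

test_that("rhs sign structure holds at random admissible states", {
  set.seed(11)
  for (v in variant_ids()) {
    for (i in 1:20) {
      s <- random_state(v)
      d <- rhs(v, 0, s)
      expect_lte(d[["eGlc"]], 0)
      expect_gte(d[["wtCell"]], 0)
      expect_gte(d[["mCell"]], 0)
      expect_gte(d[["cytVol"]], 0)
    }
  }
})

test_that("template-strand growth obeys the frame conversion identity", {
  set.seed(12)
  p <- baseline_parameters()
  for (i in 1:20) {
    s <- random_state("A")
    d <- rhs("A", 0, s, p)
    expect_equal(d[["wtCell"]],
                 s[["cytVol"]] * (p[["D1"]] * s[["DNA"]] +
                                  p[["R2"]] * s[["mDNA"]]),
                 tolerance = 1e-12)
  }
})

test_that("rhs rejects inadmissible input", {
  s <- initial_state("A", 1e-3)
  s["ROS"] <- -1e-9
  expect_error(rhs("A", 0, s), "non-negative")
  expect_error(rhs("Q", 0, initial_state("A", 1e-3)), "unknown variant")
})

test_that("glucose unit conversion uses the molar mass of glucose", {
  expect_equal(glucose_mgL_to_molar(55), 55 / 1000 / 180.156)
  expect_equal(glucose_mgL_to_molar(55), 3.05e-4, tolerance = 0.002)
  expect_equal(glucose_mgL_to_molar(1100), 6.11e-3, tolerance = 0.002)
  expect_identical(glucose_mgL_to_molar(0), 0)
  expect_error(glucose_mgL_to_molar(-1), "non-negative")
  # canonical grid spans the published molar endpoints
  g <- canonical_glucose_grid()
  expect_length(g, 5L)
  expect_equal(g[1], 3.1e-4)
  expect_equal(g[5], 6.2e-3)
  expect_equal(diff(log10(g)), rep(diff(log10(g))[1], 4))
})

test_that("density readout is linear in template strands", {
  p <- baseline_parameters()
  s <- initial_state("A", 1e-3)
  s["wtCell"] <- 0
  expect_identical(density_cfu_per_ml(s, p), 0)
  s["wtCell"] <- 2e-9
  expect_equal(density_cfu_per_ml(s, p),
               2 * density_cfu_per_ml(replace(s, "wtCell", 1e-9), p))
})

test_that("mutation rate is the mutant fraction of template base pairs", {
  s <- initial_state("A", 1e-3)
  expect_identical(mutation_rate(s), 0)
  s["mCell"] <- s[["wtCell"]]
  expect_identical(mutation_rate(s), 0.5)
  s[c("wtCell", "mCell")] <- 0
  expect_error(mutation_rate(s), "undefined")
})
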