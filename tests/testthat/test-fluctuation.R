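test_that("clone-size law reduces to the classical form at neutral fitness", {
  q <- clone_size_distribution(1, 6, renormalise = FALSE)
  j <- 1:6
  expect_equal(q, 1 / (j * (j + 1)), tolerance = 1e-12)
  expect_equal(sum(clone_size_distribution(0.7, 50)), 1, tolerance = 1e-12)
  # unfit mutants (small relative fitness) leave mostly single-cell clones:
  # q_1 = rho / (rho + 1) with rho = 1/w
  q_unfit <- clone_size_distribution(0.1, 20, renormalise = FALSE)
  expect_equal(q_unfit[1], 10 / 11, tolerance = 1e-12)
  expect_gt(q_unfit[1], clone_size_distribution(1, 1, renormalise = FALSE))
  expect_error(clone_size_distribution(0, 5), "positive")
})

test_that("mutant-count pmf matches hand evaluation and truncation accounting", {
  expect_identical(ld_pmf(0, 1, 4), c(1, 0, 0, 0, 0))
  p <- ld_pmf(1, 1, 1)
  expect_equal(p[1], exp(-1), tolerance = 1e-12)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-12)
  for (m in c(0.5, 2)) {
    pm <- ld_pmf(m, 1, 200)
    expect_lte(sum(pm), 1 + 1e-12)
    expect_gt(sum(pm), 0.95)
  }
})

test_that("mutant-count pmf matches Monte-Carlo clone sampling", {
  # independent oracle: Poisson mutation numbers with floor(u^-1) clone sizes
  set.seed(17)
  n <- 2e5
  for (m in c(0.5, 1, 4)) {
    k <- rpois(n, m)
    sizes <- floor(runif(sum(k))^-1)
    counts <- numeric(n)
    got <- rowsum(sizes, rep.int(seq_len(n), k))
    counts[as.integer(rownames(got))] <- got
    p <- ld_pmf(m, 1, 10)
    for (x in 0:10) {
      obs <- mean(counts == x)
      se <- sqrt(p[x + 1] * (1 - p[x + 1]) / n)
      expect_lt(abs(obs - p[x + 1]), 3 * se + 1e-12,
                label = sprintf("m=%g count=%d", m, x))
    }
  }
})

test_that("assay simulation respects its boundary conditions", {
  a0 <- simulate_assay(50, 100, 1e8, 0, seed = 1)
  expect_true(all(a0$mutant_count == 0))
  ap <- simulate_assay(50, 100, 1e8, 5e-8, plating_fraction = 0, seed = 2)
  expect_true(all(ap$mutant_count == 0))
  # zero-mutant fraction matches exp(-m) within a 99% binomial interval
  m <- 1
  a <- simulate_assay(10000, 100, 1e8, m / (1e8 - 100), seed = 3)
  p0 <- mean(a$mutant_count == 0)
  se <- sqrt(exp(-m) * (1 - exp(-m)) / 10000)
  expect_lt(abs(p0 - exp(-m)), qnorm(0.995) * se)
  expect_equal(attr(a, "truth")$m, m, tolerance = 1e-12)
  expect_error(simulate_assay(10, 100, 1e8, 1e-8), "seed")
  expect_error(simulate_assay(10, 1e8, 1e8, 1e-8, seed = 1), "Nt > N0")
})

test_that("death thinning reduces the reported final population", {
  a <- simulate_assay(20, 100, 1e8, 2e-8, death_fraction = 0.25, seed = 9)
  expect_true(all(a$Nt == round(1e8 * 0.75)))
})

test_that("maximum-likelihood estimation recovers the generating m", {
  a <- simulate_assay(100, 100, 1e8, 2 / (1e8 - 100), w = 1, seed = 7)
  est <- estimate_m_ml(a$mutant_count, w_mode = 1)
  expect_lt(abs(est$m - 2), 3 * est$se)
  free <- estimate_m_ml(a$mutant_count, w_mode = "free")
  expect_lt(abs(free$m - 2), 3 * free$se)
  fixed59 <- estimate_m_ml(a$mutant_count, w_mode = 0.59)
  expect_true(is.finite(fixed59$m) && fixed59$m > 0)
  expect_identical(estimate_m_ml(rep(0L, 10))$m, 0)
  expect_error(estimate_m_ml(c(0.5, 1)), "integers")
})

test_that("estimator bias shrinks with the number of parallel cultures", {
  bias <- sapply(c(25, 400), function(nc) {
    err <- sapply(1:40, function(i) {
      a <- simulate_assay(nc, 100, 1e8, 1 / (1e8 - 100), seed = 1000 + i)
      estimate_m_ml(a$mutant_count, w_mode = 1)$m - 1
    })
    abs(mean(err))
  })
  expect_lt(bias[2], bias[1] + 0.02)
  expect_lt(bias[2], 0.05)
})

test_that("p0 estimation follows its printed applicability rule", {
  counts <- c(rep(0L, 10), rep(3L, 10))
  est <- estimate_m_p0(counts)
  expect_equal(est$m, log(2), tolerance = 1e-12)
  expect_error(estimate_m_p0(rep(0L, 5)), "inapplicable")
  expect_error(estimate_m_p0(rep(2L, 5)), "inapplicable")
  # agreement with the likelihood route on neutral-fitness data
  a <- simulate_assay(1000, 100, 1e8, 1 / (1e8 - 100), seed = 21)
  p0 <- estimate_m_p0(a$mutant_count)
  ml <- estimate_m_ml(a$mutant_count, w_mode = 1)
  expect_lt(abs(p0$m - 1), 3 * p0$se)
  expect_lt(abs(p0$m - ml$m), 3 * sqrt(p0$se^2 + ml$se^2))
})

test_that("study-like datasets are reproducible and carry truth separately", {
  ds1 <- generate_study_like_dataset(10, -0.4, seed = 5)
  ds2 <- generate_study_like_dataset(10, -0.4, seed = 5)
  expect_identical(ds1, ds2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(ds1$cultures, f1, row.names = FALSE)
  write.csv(ds2$cultures, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false("m" %in% names(ds1$cultures))
  expect_true(all(c("assay_id", "treatment", "N0", "Nt", "mutant_count")
                  %in% names(ds1$cultures)))
  expect_true(all(ds1$cultures$Nt >= ds1$cultures$N0))
  # null design: constant mutation rate recovers a slope near zero;
  # assays whose cultures carried no mutants are uninformative and dropped
  mhat <- estimate_dataset_m(generate_study_like_dataset(30, 0, seed = 6))
  mhat <- mhat[mhat$m_hat > 0, ]
  est <- damp_slope_from_events(mhat$Nt, mhat$m_hat)
  expect_lt(abs(est$slope), 2 * est$se)
})
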