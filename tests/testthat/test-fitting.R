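test_that("the multinomial kernel evaluates and degenerates correctly", {
  m <- all_variants$`2HT_classic`
  # p = (.5, .5) with counts (1, 1) in each of two cells of one tree
  pars <- c(do = 0, dn = 0, g1 = .5, g2 = .5, g3 = .5)
  counts <- matrix(0, 6, 2)
  counts[1, ] <- c(1, 1)
  expect_equal(negative_log_likelihood(m, pars, counts), -2 * log(.5),
               tolerance = 1e-12)
  expect_equal(-2 * log(.5), 1.3863, tolerance = 1e-4)
  # certainty branch with all mass observed: zero kernel
  pars1 <- c(do = 1, dn = 1, g1 = .5, g2 = .5, g3 = .5)
  counts1 <- matrix(c(10, 0, 0, 10), 6, 2, byrow = TRUE)
  expect_equal(negative_log_likelihood(m, pars1, counts1), 0)
  # impossible observation: infinite
  counts_bad <- counts1
  counts_bad[1, ] <- c(0, 5)
  expect_identical(negative_log_likelihood(m, pars1, counts_bad), Inf)
})

test_that("Pearson chi-squared follows its definition", {
  expect_equal(pearson_chi2(c(10, 0), c(5, 5)), 10)
  expect_equal(pearson_chi2(c(7, 3), c(7, 3)), 0)
  # scaling both O and E doubles the statistic
  o <- c(12, 5, 3); e <- c(10, 6, 4)
  expect_equal(pearson_chi2(2 * o, 2 * e), 2 * pearson_chi2(o, e))
  # E = 0, O = 0 contributes nothing; E = 0, O > 0 is infinite
  expect_equal(pearson_chi2(c(5, 0), c(5, 0)), 0)
  expect_warning(out <- pearson_chi2(c(5, 1), c(6, 0)), "infinite")
  expect_identical(out, Inf)
})

test_that("AICc adds the printed small-sample correction", {
  expect_equal(aicc(100, 5, 12), 110)
  for (p in c(2, 5, 9, 13, 21, 25))
    for (n in c(p + 2, 50, 300, 600))
      expect_equal(aicc(0, p, n), 2 * p * (p + 1) / (n - p - 1))
  expect_warning(expect_identical(aicc(10, 5, 6), Inf), "undefined")
})

test_that("the classic 2HT fit inverts the hit/false-alarm equations", {
  m <- all_variants$`2HT_classic`
  fit <- fit_mptdc(m, classic_2ht_counts, n_restarts = 4, seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates),
               c(.5, .5, .3, .5, .7), tolerance = 1e-3)
  expect_lt(fit$chisq, 1e-6)
  expect_lt(fit$gsq, 1e-6)
  expect_equal(fit$df, 6 * 1 - 5)
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$p)
  expect_equal(fit$aicc, fit$aic + 2 * 5 * 6 / (600 - 5 - 1))
  expect_true(all(fit$se >= 0, na.rm = TRUE))
})

test_that("fitting expected counts returns the generating parameters", {
  for (nm in names(all_variants)) {
    m <- all_variants[[nm]]
    truth <- reference_params(m)
    expected <- category_probabilities(m, truth) * 100
    fit <- suppressWarnings(fit_mptdc(m, expected, n_restarts = 2,
                                      seed = 7))
    expect_lt(max(abs(fit$estimates - truth)), 1e-4)
    expect_lt(fit$chisq, 1e-6)
  }
})

test_that("estimates are stable across restart seeds", {
  m <- all_variants$SDT_CL
  des <- simulation_design(m, reference_params(m), trials_per_tree = 100,
                           seed = 31)
  counts <- simulate_counts(des)[[1]]
  f1 <- suppressWarnings(fit_mptdc(m, counts, n_restarts = 4, seed = 11))
  f2 <- suppressWarnings(fit_mptdc(m, counts, n_restarts = 4, seed = 99))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-4)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("standard errors carry delta-method magnitudes and boundary NAs", {
  m <- all_variants$`2HT_classic`
  des <- simulation_design(m, reference_params(m), trials_per_tree = 200,
                           seed = 13)
  fit <- fit_mptdc(m, simulate_counts(des)[[1]], n_restarts = 2, seed = 5)
  expect_true(all(is.finite(fit$se)))
  expect_true(all(fit$se > 0 & fit$se < 0.5))
  # saturating counts push estimates onto a bound: SEs flagged NA
  sat <- matrix(c(100, 0, 0, 100), 6, 2, byrow = TRUE)
  expect_warning(fit_b <- fit_mptdc(m, sat, n_restarts = 2, seed = 5),
                 "bound")
  expect_true(anyNA(fit_b$se))
})

test_that("count layout mismatches are validation errors", {
  m <- all_variants$`2HT_classic`
  expect_error(fit_mptdc(m, matrix(1, 3, 2)), "trees")
  expect_error(negative_log_likelihood(m, reference_params(m),
                                       matrix(1, 6, 6)), "categories")
  empty_tree <- classic_2ht_counts
  empty_tree[2, ] <- 0
  expect_error(fit_mptdc(m, empty_tree), "at least one trial")
})
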