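test_that("count simulation is seeded, exact and conserves totals", {
  m <- all_variants$`2HT_classic`
  truth <- reference_params(m)
  des <- simulation_design(m, truth, n_subjects = 3, seed = 10)
  counts <- simulate_counts(des)
  expect_length(counts, 3L)
  # block design: .35 block has 35 old and 65 new trials, etc.
  expect_equal(unname(rowSums(counts[[1]])), c(35, 65, 50, 50, 65, 35))
  expect_identical(simulate_counts(des), counts)  # same seed, same tables
  # a certain branch puts all trials in one category
  sure <- truth
  sure[c("do", "dn")] <- 1
  sure[c("g1", "g2", "g3")] <- 0
  d1 <- simulation_design(m, sure, trials_per_tree = 100, seed = 1)
  cm <- simulate_counts(d1)[[1]]
  expect_equal(unname(cm[1, ]), c(100, 0))
  expect_equal(unname(cm[2, ]), c(0, 100))
})

test_that("empirical category frequencies converge to the probabilities", {
  m <- all_variants$SDT_CL
  truth <- reference_params(m)
  des <- simulation_design(m, truth, trials_per_tree = 10000, seed = 12)
  cm <- simulate_counts(des)[[1]]
  p <- category_probabilities(m, truth)
  freq <- cm / rowSums(cm)
  z <- abs(freq - p) / pmax(sqrt(p * (1 - p) / 10000), 1e-12)
  # per-cell 3-sigma binomial bound, allowing for the 36-cell multiplicity
  expect_gte(mean(z <= 3), 0.95)
  expect_true(all(z <= 4))
})

test_that("per-subject child seeds make subjects independently reproducible", {
  m <- all_variants$`2HT_CL`
  des3 <- simulation_design(m, reference_params(m), n_subjects = 3,
                            seed = 14)
  des2 <- simulation_design(m, reference_params(m), n_subjects = 2,
                            seed = 14)
  expect_identical(simulate_counts(des3)[1:2], simulate_counts(des2))
})

test_that("trial-level simulation emits valid records and branch RTs", {
  gen <- all_variants$`2HT_classic`
  em <- data.frame(class = c("do", "dn", "go", "gn"),
                   meanlog = c(-.5, -.5, .2, .2), sdlog = .4)
  des <- simulation_design(gen, reference_params(gen), n_subjects = 1,
                           trials_per_tree = 400, seed = 15,
                           rt_emission = em)
  trials <- simulate_trials(des)
  expect_equal(nrow(trials), 400 * 6)
  expect_true(all(trials$rt > 0))
  expect_true(all(trials$response %in% c("old", "new")))
  # detection RTs are located below guessing RTs, so after geometric-mean
  # binning the fitted fast-bin probability is larger for detection
  m_rt <- all_variants$`2HT_RT`
  counts <- aggregate_counts(trials, m_rt)
  fit <- suppressWarnings(fit_mptdc(m_rt, count_matrix(m_rt, counts),
                                    n_restarts = 3, seed = 2))
  expect_gt(fit$estimates["H_do"], fit$estimates["H_go"])
  expect_gt(fit$estimates["H_dn"], fit$estimates["H_gn"])
})

test_that("a shared RT distribution gives H near one half everywhere", {
  gen <- all_variants$`2HT_classic`
  em <- data.frame(class = c("do", "dn", "go", "gn"), meanlog = -0.2,
                   sdlog = 0.45)
  des <- simulation_design(gen, reference_params(gen),
                           trials_per_tree = 1500, seed = 16,
                           rt_emission = em)
  trials <- simulate_trials(des)
  m_rt <- all_variants$`2HT_RT`
  fit <- suppressWarnings(
    fit_mptdc(m_rt, count_matrix(m_rt, aggregate_counts(trials, m_rt)),
              n_restarts = 3, seed = 3))
  hs <- fit$estimates[c("H_do", "H_dn", "H_go", "H_gn")]
  expect_true(all(abs(hs - 0.5) < 0.06))
})

test_that("zero-trial requests and missing emission specs error cleanly", {
  gen <- all_variants$`2HT_classic`
  expect_error(simulation_design(gen, reference_params(gen),
                                 trials_per_tree = 0), "at least one")
  des <- simulation_design(gen, reference_params(gen), seed = 1)
  expect_error(simulate_trials(des), "rt_emission")
  expect_error(simulate_trials(
    simulation_design(all_variants$`2HT_RT`,
                      reference_params(all_variants$`2HT_RT`), seed = 1,
                      rt_emission = data.frame(class = "do", meanlog = 0,
                                               sdlog = 1))),
    "without RT bins")
})

test_that("recovery with a single candidate is trivially perfect", {
  m <- all_variants$`2HT_classic`
  des <- simulation_design(m, reference_params(m), n_subjects = 4,
                           trials_per_tree = 50, seed = 17)
  res <- recovery_study(list(d = des), list(m), n_restarts = 2, seed = 18)
  expect_equal(res$prop_true, 1)
  expect_equal(res$n_failed, 0L)
})

test_that("recovery improves with trials per tree", {
  m_sdt <- all_variants$SDT_CL
  m_2ht <- all_variants$`2HT_CL`
  props <- vapply(c(25, 400), function(n) {
    des <- simulation_design(m_sdt, reference_params(m_sdt),
                             n_subjects = 12, trials_per_tree = n,
                             seed = 19)
    recovery_study(list(d = des), list(m_sdt, m_2ht), n_restarts = 2,
                   seed = 20)$prop_true
  }, 0)
  expect_true(props[2] >= props[1])
  expect_gte(props[2], 0.8)
})
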