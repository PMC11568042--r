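test_that("free-parameter totals match the published model layout", {
  expected <- c(`2HT_classic` = 5, SDT_classic = 5,
                `2HT_CL` = 13, SDT_CL = 9,
                `2HT_RT` = 9, SDT_RT = 9,
                `2HT_CL_RT` = 25, SDT_CL_RT = 21)
  for (nm in names(expected))
    expect_identical(n_parameters(all_variants[[nm]]),
                     as.integer(expected[[nm]]), info = nm)
  # degenerate single-condition case
  expect_identical(n_parameters(mptdc_model("2HT", "classic", 1)), 3L)
  expect_error(mptdc_model("XHT"), "arg")
})

test_that("tree layout is 2 trees per condition and categories partition", {
  for (m in all_variants) {
    expect_equal(nrow(m$trees), 2L * m$n_conditions)
    expect_equal(sort(unique(m$trees$stimulus)), c("new", "old"))
    expect_equal(length(m$categories),
                 2L * m$n_cl_bins * m$n_rt_bins)
    # every branch lands in exactly one declared category
    for (b in m$branches) expect_true(b$category %in% m$categories)
  }
})

test_that("2HT classic probabilities follow the branch products", {
  m <- all_variants$`2HT_classic`
  p <- category_probabilities(m, c(do = .5, dn = .5, g1 = .3, g2 = .5,
                                   g3 = .7))
  # old trees: P(Hit) = do + (1 - do) g_j;  new trees: P(FA) = (1 - dn) g_j
  expect_equal(unname(p[c(1, 3, 5), "old"]), .5 + .5 * c(.3, .5, .7))
  expect_equal(unname(p[c(2, 4, 6), "old"]), .5 * c(.3, .5, .7))
  # certainty case
  p1 <- category_probabilities(m, c(do = 1, dn = .5, g1 = .3, g2 = .5,
                                    g3 = .7), tree = 1)
  expect_equal(unname(p1), c(1, 0))
})

test_that("SDT classic probabilities are normal tail masses", {
  m <- all_variants$SDT_classic
  # symmetric null: d' = 0, c = 0 puts every probability at .5
  p0 <- category_probabilities(m, c(dprime = 0, sigma = 1, c1 = 0, c2 = 0,
                                    c3 = 0))
  expect_equal(unname(as.vector(p0)), rep(.5, 12))
  # FA rate at c = 1.645 is the standard-normal upper tail
  p <- category_probabilities(m, c(dprime = 1, sigma = 1, c1 = 1.645,
                                   c2 = 0, c3 = 0), tree = 2)
  expect_equal(unname(p["old"]), pnorm(1.645, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(p["old"]), 0.05, tolerance = 1e-3)
})

test_that("probabilities are in [0,1] and sum to 1 for random draws", {
  set.seed(101)
  for (m in all_variants) {
    draws <- random_params(m, 200)
    for (i in seq_len(nrow(draws))) {
      p <- category_probabilities(m, draws[i, ])
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)
    }
  }
})

test_that("2HT structural zeros hold: no detect-wrong branches", {
  for (v in c("2HT_classic", "2HT_CL", "2HT_RT", "2HT_CL_RT")) {
    m <- all_variants[[v]]
    for (b in m$branches) {
      stim <- m$trees$stimulus[b$tree]
      if (stim == "old") expect_false(b$state == "dn", info = v)
      if (stim == "new") expect_false(b$state == "do", info = v)
    }
    # with full detection and no guessing-old, new trees never answer old
    pars <- reference_params(m)
    pars[c("do", "dn")] <- 1
    p <- category_probabilities(m, pars)
    old_cols <- grepl("^old", m$categories)
    expect_equal(sum(p[m$trees$stimulus == "new", old_cols]), 0)
  }
})

test_that("SDT-CL interval masses match Gaussian quadrature", {
  m <- all_variants$SDT_CL
  set.seed(202)
  draws <- random_params(m, 20)
  for (i in seq_len(nrow(draws))) {
    th <- draws[i, ]
    crit <- th["c1"] + cumsum(c(0, th[c("dc2", "dc3", "dc4", "dc5")]))
    edges <- c(-Inf, unname(crit), Inf)
    p <- category_probabilities(m, th, tree = 1)  # .35 old tree
    # regions low -> high familiarity map to new.high ... old.high
    region_cat <- c("new.high", "new.medium", "new.low",
                    "old.low", "old.medium", "old.high")
    for (r in 1:6) {
      mass <- integrate(dnorm, edges[r], edges[r + 1], mean = th["dprime"],
                        sd = th["sigma"], rel.tol = 1e-12)$value
      expect_equal(unname(p[region_cat[r]]), mass, tolerance = 1e-8)
    }
  }
})

test_that("P(Hit) increases in d' and decreases in the criterion", {
  m <- all_variants$SDT_classic
  hit <- function(dp, c1) category_probabilities(
    m, c(dprime = dp, sigma = 1, c1 = c1, c2 = 0, c3 = 0), tree = 1)["old"]
  dgrid <- seq(-1, 3, by = .25)
  expect_true(all(diff(vapply(dgrid, hit, 0, c1 = .5)) > 0))
  cgrid <- seq(-2, 2, by = .25)
  expect_true(all(diff(vapply(cgrid, function(cc) hit(1, cc), 0)) < 0))
})

test_that("confidence and RT terms nest as L and H products", {
  m <- all_variants$`2HT_CL_RT`
  th <- reference_params(m)
  p <- category_probabilities(m, th, tree = 1)
  # detect-old + guess-old mass through the high-CL fast bin
  manual <- th["do"] * th["L_do1"] * th["H_do_high"] +
    (1 - th["do"]) * th["g1"] * th["L_go1"] * th["H_go_high"]
  expect_equal(unname(p["old.high.fast"]), unname(manual), tolerance = 1e-14)
  # medium bin carries (1 - L1) L2, slow bin carries 1 - H
  manual2 <- th["do"] * (1 - th["L_do1"]) * th["L_do2"] *
    (1 - th["H_do_medium"]) +
    (1 - th["do"]) * th["g1"] * (1 - th["L_go1"]) * th["L_go2"] *
    (1 - th["H_go_medium"])
  expect_equal(unname(p["old.medium.slow"]), unname(manual2),
               tolerance = 1e-14)
})

test_that("out-of-bounds or incomplete parameters are rejected", {
  m <- all_variants$`2HT_classic`
  expect_error(category_probabilities(m, c(do = 1.2, dn = .5, g1 = .5,
                                           g2 = .5, g3 = .5)),
               "out of bounds")
  expect_error(category_probabilities(m, c(do = .5)), "missing parameter")
  ms <- all_variants$SDT_CL
  th <- reference_params(ms)
  th["dc2"] <- -0.1
  expect_error(category_probabilities(ms, th), "out of bounds")
})

test_that("model specs survive a bit-stable JSON round trip", {
  for (m in all_variants[c("2HT_CL_RT", "SDT_CL", "SDT_classic")]) {
    js <- model_to_json(m)
    m2 <- model_from_json(js)
    expect_identical(as.character(model_to_json(m2)), as.character(js))
    expect_identical(m2$params, m$params)
    th <- reference_params(m)
    expect_equal(category_probabilities(m2, th),
                 category_probabilities(m, th))
  }
})
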