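test_that("point-null priors give BF10 = 1 exactly", {
  expect_equal(corr_bf10(0.3, 50, registry[["null (rho)"]])$bf10, 1)
  rec <- study_record("s", "ttest", design = "paired", t = 2.1, n1 = 30)
  expect_equal(ttest_bf10(rec, registry[["null (delta)"]])$bf10, 1)
})

test_that("a point alternative reduces to the likelihood ratio", {
  rec <- study_record("s", "ttest", design = "one_sample", t = 2.5, n1 = 24)
  d0 <- 0.6
  b <- ttest_bf10(rec, prior_spec("point", value = d0))
  direct <- stats::dt(2.5, 23, ncp = d0 * sqrt(24)) / stats::dt(2.5, 23)
  expect_equal(b$bf10, direct, tolerance = 1e-12)
  expect_equal(b$method, "closed_form")
})

test_that("record validation rejects out-of-range inputs", {
  expect_error(study_record("s", "correlation", r = 1, n = 50), "\\|r\\|")
  expect_error(study_record("s", "correlation", r = 0.5, n = 3), "n >= 4")
  expect_error(study_record("s", "ttest", design = "independent", t = 2,
                            n1 = 10), "n2")
  expect_error(corr_bf10(0.3, 50, registry[["Expert 2 (t)"]]),
               "\\[0, 1\\]")
  expect_error(posterior_prob_h1(-2), "positive")
})

test_that("bf10 and log_bf10 stay consistent and ratios are transitive", {
  b4 <- corr_bf10(0.3, 260, registry[["Expert 4 (beta)"]], "s1")
  b6 <- corr_bf10(0.3, 260, registry[["Expert 6 (beta)"]], "s1")
  b1 <- corr_bf10(0.3, 260, registry[["Expert 1 (beta)"]], "s1")
  for (b in list(b4, b6, b1)) expect_equal(b$bf10, exp(b$log_bf10))
  expect_equal(bf_ratio(b4, b4), 1)
  expect_equal(bf_ratio(b4, b6) * bf_ratio(b6, b1), bf_ratio(b4, b1),
               tolerance = 1e-12)
  other <- corr_bf10(0.3, 260, registry[["Expert 6 (beta)"]], "s2")
  expect_error(bf_ratio(b4, other), "different studies")
})

test_that("posterior model probabilities follow the odds form", {
  expect_equal(posterior_prob_h1(1), 0.5)
  expect_equal(posterior_prob_h1(3), 0.75)
  expect_equal(posterior_prob_h1(3, prior_odds = 1 / 3), 0.5)
})

test_that("Monte Carlo oracle is seeded and exact for point priors", {
  rec <- study_record("s", "correlation", r = 0.2, n = 100)
  o1 <- mc_marginal_oracle(rec, registry[["Expert 5 (beta)"]], 1e4, 99)
  o2 <- mc_marginal_oracle(rec, registry[["Expert 5 (beta)"]], 1e4, 99)
  expect_identical(o1$bf10, o2$bf10)
  op <- mc_marginal_oracle(rec, prior_spec("point", value = 0.2))
  expect_equal(op$se, 0)
  expect_equal(op$bf10, corr_bf10(0.2, 100, prior_spec("point",
                                                       value = 0.2))$bf10)
})

test_that("quadrature agrees with the Monte Carlo oracle", {
  # correlation engine, spec's cross-check cases
  cases <- list(
    list(r = 0.3, n = 260, prior = registry[["default (rho)"]]),
    list(r = 0.2, n = 100, prior = registry[["Expert 5 (beta)"]])
  )
  for (cs in cases) {
    q <- corr_bf10(cs$r, cs$n, cs$prior)$bf10
    rec <- study_record("s", "correlation", r = cs$r, n = cs$n)
    o <- mc_marginal_oracle(rec, cs$prior, 1e5, 17)
    expect_lt(abs(q - o$bf10), 3 * o$se, label = cs$prior$label)
  }
  # t-test engine, default Cauchy prior
  rec <- study_record("s", "ttest", design = "one_sample", t = 2.5,
                      n1 = 24)
  q <- ttest_bf10(rec, registry[["default (delta)"]])$bf10
  o <- mc_marginal_oracle(rec, registry[["default (delta)"]], 1e5, 17)
  expect_lt(abs(q - o$bf10), 3 * o$se)
})

test_that("corr BF is monotone in r and below one at r = 0", {
  for (lab in c("Expert 2 (beta)", "Expert 6 (beta)", "default (rho)")) {
    bfs <- vapply(seq(0, 0.9, by = 0.1), function(r)
      corr_bf10(r, 60, registry[[lab]])$log_bf10, numeric(1))
    expect_true(all(diff(bfs) > 0), label = lab)
    expect_lt(bfs[1], 0)  # r = 0: kernel < 1 for every rho > 0
  }
})

test_that("no prior can beat the maximum-likelihood oracle bound", {
  for (cs in list(c(r = 0.3, n = 260), c(r = 0.1, n = 40),
                  c(r = -0.2, n = 80))) {
    kmax <- corr_kernel_max(cs["r"], cs["n"])
    for (lab in c("Expert 1 (beta)", "Expert 4 (beta)", "default (rho)")) {
      lb <- corr_bf10(cs["r"], cs["n"], registry[[lab]])$log_bf10
      expect_lte(lb, kmax + 1e-9,
                 label = sprintf("%s at r=%.1f n=%g", lab, cs["r"],
                                 cs["n"]))
    }
  }
})

test_that("the Bayes factor rewards an expert's predictive accuracy", {
  # data at Expert 6's beta mode (0.402); Experts 1 and 2 have modes
  # >= 0.2 away and should show lower median evidence
  cfg <- generator_config("correlation", n_studies = 150,
                          effect_model = "fixed", effect_value = 0.402,
                          fixed_n = 100, seed = 11)
  db <- gen_correlation_db(cfg)
  bf <- compute_bf_table(db, registry[c("Expert 1 (beta)",
                                        "Expert 2 (beta)",
                                        "Expert 6 (beta)")])
  med <- tapply(bf$log_bf10, bf$prior_label, stats::median)
  expect_gt(med[["Expert 6 (beta)"]], med[["Expert 1 (beta)"]])
  expect_gt(med[["Expert 6 (beta)"]], med[["Expert 2 (beta)"]])
})

test_that("batch tables are long-format and skip bad rows with reasons", {
  db <- correlation_table(data.frame(
    study_id = c("a", "b", "c"), r = c(0.2, 0.4, 0.5), n = c(30, 3, 60)))
  bf <- compute_bf_table(db, registry[c("Expert 3 (beta)",
                                        "default (rho)")])
  expect_equal(nrow(bf), 4L)  # 2 valid studies x 2 priors
  expect_named(bf, c("study_id", "prior_label", "log_bf10", "bf10"))
  skipped <- attr(bf, "skipped")
  expect_equal(skipped$study_id, "b")
  expect_match(skipped$reason, "n >= 4")
})
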