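test_that("generator configs validate their inputs", {
  expect_error(generator_config("correlation"), "seed")
  expect_error(generator_config("ttest", seed = 1,
                                design_mix = c(one_sample = 0.5,
                                               paired = 0.2,
                                               independent = 0.2)),
               "sum to 1")
  expect_error(generator_config("correlation", effect_model = "fixed",
                                seed = 1), "effect_value")
  expect_error(generator_config("correlation", null_prop = 1.2, seed = 1),
               "null_prop")
})

test_that("correlation generator is seeded and null-calibrated", {
  cfg <- generator_config("correlation", n_studies = 30, seed = 5)
  a <- gen_correlation_db(cfg)
  b <- gen_correlation_db(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_s3_class(a, "correlation_table")
  expect_equal(nrow(a), 30L)
  expect_true(all(a$n1 >= 10 & a$n1 <= 500))

  # fixed rho = 0 at large n: mean r within 3 SE of zero
  null_cfg <- generator_config("correlation", n_studies = 2000,
                               effect_model = "fixed", effect_value = 0,
                               fixed_n = 500, seed = 6)
  rs <- gen_correlation_db(null_cfg)$r
  se <- stats::sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs)), 3 * se)

  # fixed rho = 0.5: median r within 3 SE of 0.5
  eff_cfg <- generator_config("correlation", n_studies = 1000,
                              effect_model = "fixed", effect_value = 0.5,
                              fixed_n = 400, seed = 7)
  rs <- gen_correlation_db(eff_cfg)$r
  med_se <- 1.2533 * stats::sd(rs) / sqrt(length(rs))
  expect_lt(abs(stats::median(rs) - 0.5), 3 * med_se)
})

test_that("t-test generator hits the design mix and null calibration", {
  cfg <- generator_config("ttest", n_studies = 855, seed = 8)
  db <- gen_ttest_db(cfg)
  counts <- table(db$design)
  expect_equal(counts[["one_sample"]], 85L)
  expect_equal(counts[["paired"]], 604L)
  expect_equal(counts[["independent"]], 166L)
  expect_true(all(db$n1 >= 2 & db$n1 <= 212))
  expect_identical(as.data.frame(gen_ttest_db(cfg)), as.data.frame(db))

  # all-null run: ~5% of |t| beyond the two-sided 5% critical value
  null_cfg <- generator_config("ttest", n_studies = 4000,
                               effect_model = "fixed", effect_value = 0,
                               fixed_n = 50, seed = 9)
  nd <- gen_ttest_db(null_cfg)
  df <- ifelse(nd$design == "independent", nd$n1 + nd$n2 - 2, nd$n1 - 1)
  rej <- mean(abs(nd$t) > stats::qt(0.975, df))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("effects drawn from a prior propagate to the sample d scale", {
  e2 <- registry[["Expert 2 (t)"]]
  cfg <- generator_config("ttest", n_studies = 1500,
                          effect_model = "from_prior", effect_prior = e2,
                          fixed_n = 50, seed = 10)
  db <- gen_ttest_db(cfg)
  n_eff <- ifelse(db$design == "independent",
                  db$n1 * db$n2 / (db$n1 + db$n2), db$n1)
  d <- db$t / sqrt(n_eff)
  prior_mean <- stats::integrate(function(x) x * prior_pdf(e2, x),
                                 0, 5)$value
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - prior_mean), 3 * se)
})

test_that("the size model median lands on its target", {
  cfg <- generator_config("ttest", n_studies = 4000, seed = 12)
  db <- gen_ttest_db(cfg)
  expect_lt(abs(stats::median(db$n1) - 24), 3)
})

test_that("elicitation-grid generation round-trips through fitting", {
  u <- prior_spec("uniform", lower = 0, upper = 1)
  g <- gen_elicitation_grid(u, 100, mode = "deterministic")
  expect_equal(g$chips, rep(10, 10))

  b <- prior_spec("beta", alpha = 5, beta = 15)
  g1 <- gen_elicitation_grid(b, 80, mode = "multinomial", seed = 4)
  g2 <- gen_elicitation_grid(b, 80, mode = "multinomial", seed = 4)
  expect_identical(g1$chips, g2$chips)
  expect_equal(sum(g1$chips), 80)

  fit <- fit_prior_to_grid(gen_elicitation_grid(b, 100,
                                                mode = "deterministic"),
                           "beta")
  expect_lt(abs(fit$params$alpha - 5) / 5, 0.15)
  expect_lt(abs(fit$params$beta - 15) / 15, 0.15)
})

test_that("the generating prior wins in mean evidence on its own data", {
  # two-component db: 50% nulls, effects from Expert 3's beta prior;
  # on the non-null subset the matching prior attains the highest mean
  # log BF among the registry priors (the expected log marginal
  # likelihood is maximized by the data-generating prior)
  cfg <- generator_config("correlation", n_studies = 400,
                          effect_prior = registry[["Expert 3 (beta)"]],
                          fixed_n = 100, seed = 9)
  db <- gen_correlation_db(cfg)
  truth <- attr(db, "truth")
  expect_named(truth, c("study_id", "rho_true", "is_null"))
  nonnull <- db[!truth$is_null, ]
  class(nonnull) <- class(db)
  bf <- compute_bf_table(nonnull, rho_priors)
  means <- tapply(bf$log_bf10, bf$prior_label, mean)
  expect_equal(names(which.max(means)), "Expert 3 (beta)")
})
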