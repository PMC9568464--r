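test_that("strong-bounds categorization uses strict thresholds", {
  expect_equal(as.character(categorize_bf(c(110157, 1, 10, 1 / 10, 0.05))),
               c("strong_H1", "inconclusive", "inconclusive",
                 "inconclusive", "strong_H0"))
  expect_error(categorize_bf(c(3, 0)), "positive")
})

test_that("jeffreys categories partition the positive axis", {
  js <- evidence_scheme("jeffreys")
  expect_equal(as.character(categorize_bf(c(0.05, 0.2, 0.5, 2, 5, 50),
                                          js)),
               c("strong_H0", "moderate_H0", "anecdotal_H0",
                 "anecdotal_H1", "moderate_H1", "strong_H1"))
  # edge values get the less extreme label
  expect_equal(as.character(categorize_bf(c(1 / 10, 10), js)),
               c("moderate_H0", "moderate_H1"))
})

test_that("direction agreement counts strict same-side pairs", {
  expect_equal(direction_agreement(c(2, 3), c(5, 0.5 + 0.6)), 1)
  expect_equal(direction_agreement(c(2, 0.5), c(0.5, 2)), 0)
  expect_equal(direction_agreement(c(2, 0.5, 3, 0.2), c(4, 2, 5, 0.9)),
               0.75)
  # BF exactly 1 has no direction: counts as disagreement
  expect_equal(direction_agreement(c(1, 2), c(1, 2)), 0.5)
  expect_error(direction_agreement(c(1, 2), c(1, 2, 3)), "misaligned")
})

test_that("category agreement compares labels pairwise", {
  expect_equal(category_agreement(c(11, 0.05), c(20, 0.01)), 1)
  expect_equal(category_agreement(c(11, 0.05), c(9, 0.2)), 0)
  expect_equal(category_agreement(c(11, 0.05, 2), c(20, 0.01, 0.5)), 1)
})

test_that("pairwise matrices match per-pair calls and are symmetric", {
  set.seed(500)
  tab <- expand.grid(study_id = paste0("s", 1:4),
                     prior_label = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  tab$log_bf10 <- stats::rnorm(12, 0, 2)
  tab$bf10 <- exp(tab$log_bf10)

  for (metric in c("direction", "category")) {
    m <- pairwise_matrix(tab, metric)
    expect_equal(dim(m), c(3L, 3L))
    expect_equal(diag(m), c(A = 1, B = 1, C = 1))
    expect_equal(unclass(m), t(unclass(m)))
    for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
      a <- tab$bf10[tab$prior_label == pair[1]]
      b <- tab$bf10[tab$prior_label == pair[2]]
      want <- if (metric == "direction") direction_agreement(a, b)
              else category_agreement(a, b)
      expect_equal(m[pair[1], pair[2]], want)
    }
  }

  single <- tab[tab$prior_label == "A", ]
  expect_equal(unclass(pairwise_matrix(single, "direction")),
               matrix(1, 1, 1, dimnames = list("A", "A")),
               ignore_attr = TRUE)
  expect_error(pairwise_matrix(tab[-1, ], "direction"), "missing cells")
})

test_that("identical BF columns give full agreement everywhere", {
  tab <- data.frame(study_id = rep(paste0("s", 1:3), 2),
                    prior_label = rep(c("A", "B"), each = 3),
                    bf10 = rep(c(5, 0.2, 40), 2))
  tab$log_bf10 <- log(tab$bf10)
  expect_true(all(pairwise_matrix(tab, "direction") == 1))
  expect_true(all(pairwise_matrix(tab, "category") == 1))
  rs <- ratio_summary(tab)
  expect_true(all(rs$ratios$ratio == 1))
})

test_that("ratio summaries are hand-checkable and reciprocal", {
  tab <- data.frame(study_id = rep(paste0("s", 1:3), 2),
                    prior_label = rep(c("A", "B"), each = 3),
                    log_bf10 = log(c(2, 8, 0.5, 4, 2, 0.25)))
  tab$bf10 <- exp(tab$log_bf10)
  rs <- ratio_summary(tab)
  ab <- rs$ratios[rs$ratios$prior_a == "A" & rs$ratios$prior_b == "B", ]
  expect_equal(ab$ratio, c(2 / 4, 8 / 2, 0.5 / 0.25))
  ba <- rs$ratios[rs$ratios$prior_a == "B" & rs$ratios$prior_b == "A", ]
  expect_equal(ba$ratio, 1 / ab$ratio)
  srow <- rs$summary[rs$summary$prior_a == "A" & rs$summary$prior_b == "B", ]
  expect_equal(srow$q50, 2)
  expect_equal(srow$prop_within_3, 2 / 3)  # ratio 4 falls outside [1/3, 3]
})

test_that("opposite strong evidence is flagged, not silently dropped", {
  clean <- data.frame(study_id = rep("s1", 2),
                      prior_label = c("A", "B"), bf10 = c(20, 5))
  clean$log_bf10 <- log(clean$bf10)
  expect_silent(out <- strong_conflicts(clean))
  expect_equal(nrow(out), 0L)

  bad <- data.frame(study_id = rep("s1", 2), prior_label = c("A", "B"),
                    bf10 = c(20, 0.05))
  bad$log_bf10 <- log(bad$bf10)
  expect_warning(out <- strong_conflicts(bad), "opposite")
  expect_equal(out$study_id, "s1")
  expect_equal(out$strong_h1_priors, "A")
  expect_equal(out$strong_h0_priors, "B")
})

test_that("priors agreeing on strong categories agree in direction there", {
  set.seed(501)
  bfa <- exp(stats::rnorm(50, 0, 4))
  bfb <- bfa * exp(stats::rnorm(50, 0, 0.1))
  cat_a <- categorize_bf(bfa); cat_b <- categorize_bf(bfb)
  strong <- cat_a != "inconclusive" & cat_a == cat_b
  if (any(strong))
    expect_equal(direction_agreement(bfa[strong], bfb[strong]), 1)
})
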