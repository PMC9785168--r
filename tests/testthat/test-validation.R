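test_that("bootstrap with a fixed seed is bit-reproducible", {
  co <- simulate_cohort(120, seed = 21)
  b1 <- bootstrap_auc(co$true_score, co$cmi_label, n_reps = 500, seed = 9)
  b2 <- bootstrap_auc(co$true_score, co$cmi_label, n_reps = 500, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_auc(co$true_score, co$cmi_label, n_reps = 500, seed = 10)
  expect_false(identical(b1$mean_auc, b3$mean_auc))
})

test_that("a perfectly separated cohort bootstraps to AUC 1 throughout", {
  s <- c(10, 9, 8, 3, 2, 1)
  l <- rep(c(TRUE, FALSE), each = 3)
  b <- bootstrap_auc(s, l, n_reps = 300, seed = 4)
  expect_equal(b$mean_auc, 1)
  expect_equal(b$min_auc, 1)
  expect_equal(b$max_auc, 1)
})

test_that("single-class resamples are skipped and counted", {
  s <- c(1, 2); l <- c(TRUE, FALSE)
  b <- bootstrap_auc(s, l, n_reps = 400, seed = 2)
  expect_lt(b$n_reps_effective, 400L)   # half the resamples are single-class
  expect_gt(b$n_reps_effective, 100L)
  bs <- bootstrap_auc(s, l, n_reps = 50, seed = 2, stratified = TRUE)
  expect_identical(bs$n_reps_effective, 50L)  # stratified keeps both classes
})

test_that("percent agreement counts exact score equality", {
  r1 <- c(rep(1, 201), rep(2, 41))
  r2 <- c(rep(1, 201), rep(3, 41))
  res <- percent_agreement(r1, r2)
  expect_identical(res$n_agree, 201L)
  expect_identical(res$n_total, 242L)
  expect_equal(res$percent_agreement, 100 * 201 / 242)  # 83.06, printed 83%
  expect_equal(percent_agreement(1:5, 1:5)$percent_agreement, 100)
  expect_equal(percent_agreement(c(1, 2), c(2, 1))$percent_agreement, 0)
  expect_error(percent_agreement(1:3, 1:4), class = "csi_validation_error")
})

test_that("Cohen's kappa reproduces hand-computed and reference values", {
  r1 <- rep(c(1, 1, 2, 2), c(20, 5, 10, 15))
  r2 <- rep(c(1, 2, 1, 2), c(20, 5, 10, 15))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$kappa, 0.40)          # p_o = 0.70, p_e = 0.50
  expect_equal(k$p_observed, 0.70)
  expect_equal(k$p_expected, 0.50)
  # SE and CI frozen from an independent reference implementation
  # (statsmodels cohens_kappa on the same 2x2 table)
  expect_equal(k$se, 0.12699606293110, tolerance = 1e-10)
  expect_equal(k$ci_low, 0.151092290477, tolerance = 1e-9)
  expect_equal(k$ci_high, 0.648907709523, tolerance = 1e-9)

  ident <- cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))
  expect_equal(ident$kappa, 1)
})

test_that("kappa degenerates are rejected and independence gives kappa near zero", {
  expect_error(cohen_kappa(rep(1, 10), rep(1, 10)),
               class = "csi_degenerate_error")
  set.seed(301)
  r1 <- sample(0:4, 4000, replace = TRUE)
  r2 <- sample(0:4, 4000, replace = TRUE)
  k <- cohen_kappa(r1, r2)
  expect_lt(abs(k$kappa), 3.5 * k$se)  # within sampling error of 0
})

test_that("kappa is invariant under a common relabeling of categories", {
  set.seed(302)
  r1 <- sample(0:3, 200, replace = TRUE)
  r2 <- ifelse(runif(200) < 0.7, r1, sample(0:3, 200, replace = TRUE))
  k1 <- cohen_kappa(r1, r2)
  relabel <- c(10, 30, 20, 40)  # order-scrambling injective map
  k2 <- cohen_kappa(relabel[r1 + 1], relabel[r2 + 1])
  expect_equal(k1$kappa, k2$kappa)
  expect_equal(k1$se, k2$se)
})

test_that("cross-tabulation reproduces printed-style group percentages", {
  grp <- rep(c("low", "high"), c(100, 142))
  cmi <- c(rep(c(TRUE, FALSE), c(11, 89)), rep(c(TRUE, FALSE), c(98, 44)))
  ct <- csi_crosstab(factor(grp, levels = c("low", "high")), cmi)
  expect_equal(unname(ct$percent["high"]), 100 * 98 / 142)  # prints as 69%
  expect_equal(unname(ct$percent["low"]), 100 * 11 / 100)   # prints as 11%
  expect_identical(ct$test, "pearson")
  expect_lt(ct$p_value, 0.001)
  # complement percentages: each row sums to 100
  expect_equal(unname(100 * ct$counts[, "no"] / ct$n_group + ct$percent),
               c(100, 100))
})

test_that("Fisher's exact test replaces chi-square for sparse tables", {
  grp <- rep(c("a", "b"), c(12, 12))
  attr_ <- c(rep(TRUE, 2), rep(FALSE, 10), rep(TRUE, 6), rep(FALSE, 6))
  ct <- csi_crosstab(grp, attr_)
  expect_identical(ct$test, "fisher")
  expect_true(ct$p_value >= 0 && ct$p_value <= 1)
  ext <- csi_crosstab(rep(c("a", "b"), each = 10),
                      rep(c(TRUE, FALSE), each = 10))
  expect_equal(unname(ext$percent), c(100, 0))
})

test_that("degenerate tables with an empty margin are rejected", {
  expect_error(csi_crosstab(rep(c("a", "b"), 5), rep(TRUE, 10)),
               class = "csi_degenerate_error")
  expect_error(csi_crosstab(rep("a", 10), rep(c(TRUE, FALSE), 5)),
               class = "csi_validation_error")
})
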