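test_that("rank-based AUC equals pairwise counting with ties worth one half", {
  expect_equal(auc_rank(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  expect_equal(auc_rank(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_rank(rep(5, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(0:10, n, replace = TRUE)  # heavy ties on purpose
    expect_equal(auc_rank(scores, labels), brute_auc(scores, labels))
  }
})

test_that("rank AUC is invariant under strictly increasing transforms", {
  set.seed(102)
  scores <- rnorm(60)
  labels <- runif(60) < 0.4
  a <- auc_rank(scores, labels)
  expect_equal(auc_rank(exp(scores), labels), a)
  expect_equal(auc_rank(rank(scores), labels), a)
  expect_equal(auc_rank(qlogis(plogis(scores)), labels), a)
})

test_that("single-class input is a degenerate-input error", {
  expect_error(auc_rank(1:5, rep(TRUE, 5)), class = "csi_degenerate_error")
  expect_error(bm_confint(1:5, rep(FALSE, 5)), class = "csi_degenerate_error")
  expect_error(roc_points(1:5, rep(TRUE, 5)), class = "csi_degenerate_error")
  expect_error(youden_cutoff(1:5, rep(FALSE, 5)), class = "csi_degenerate_error")
})

test_that("Brunner-Munzel interval matches the independently computed reference", {
  scores <- c(3, 4, 5, 6, 1, 2, 3, 4)
  labels <- rep(c(TRUE, FALSE), each = 4)
  est <- bm_confint(scores, labels, level = 0.95)
  # frozen from an independent rank-variance computation (cross-checked
  # against scipy.stats.brunnermunzel: statistic 3.0, Satterthwaite df 6)
  expect_equal(est$auc, 0.875)
  expect_equal(est$se, 0.125)
  expect_equal(est$df, 6)
  expect_equal(est$ci_low, 0.5691360186, tolerance = 1e-9)
  expect_equal(est$ci_high, 1)  # clamped at the boundary
  expect_lt(est$ci_low, est$auc)
  expect_equal(est$auc, auc_rank(scores, labels))
})

test_that("the interval collapses to the point estimate as the level goes to zero", {
  scores <- c(3, 4, 5, 6, 1, 2, 3, 4)
  labels <- rep(c(TRUE, FALSE), each = 4)
  est <- bm_confint(scores, labels, level = 1e-10)
  expect_equal(est$ci_low, est$auc, tolerance = 1e-6)
  expect_equal(est$ci_high, est$auc, tolerance = 1e-6)
  expect_error(bm_confint(scores, labels, level = 1.2),
               class = "csi_validation_error")
})

test_that("the upper endpoint is clamped at 1 near and at perfect separation", {
  # near-separation: one tied pair keeps the variance positive
  est <- bm_confint(c(100, 101, 1, 1, 2, 100), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_lt(est$auc, 1)
  expect_equal(est$ci_high, 1)
  expect_gt(est$auc + qt((1 + est$level) / 2, est$df) * est$se, 1) # was clamped
  # full separation: the rank variance vanishes and the interval degenerates
  expect_warning(
    sep <- bm_confint(c(100, 101, 99, 1, 2, 3),
                      c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
    "perfect separation")
  expect_equal(sep$auc, 1)
  expect_equal(sep$ci_high, 1)
  expect_equal(sep$ci_low, 1)
})

test_that("all-tied scores raise a degenerate-variance error", {
  expect_error(bm_confint(rep(5, 8), rep(c(TRUE, FALSE), 4)),
               class = "csi_degenerate_error")
})

test_that("ROC points count sensitivity and specificity at observed cut-offs", {
  scores <- c(8, 9, 10, 1, 2, 8)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pts <- roc_points(scores, labels)
  expect_identical(pts$cutoff, c(1, 2, 8, 9, 10))
  at8 <- pts[pts$cutoff == 8, ]
  expect_equal(at8$sensitivity, 1)
  expect_equal(at8$specificity, 2 / 3)
  # at the minimum observed cut-off everyone is called positive
  expect_equal(pts$sensitivity[1], 1)
  expect_equal(pts$specificity[1], 0)
})

test_that("Youden cut-off maximises J with ties broken toward the smaller value", {
  res <- youden_cutoff(c(8, 9, 10, 1, 2, 8), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$cutoff, 8)  # J = 2/3 tied with 9; smaller wins
  expect_equal(res$youden_j, 2 / 3)
  expect_equal(res$youden_j, res$sensitivity + res$specificity - 1)

  sep <- youden_cutoff(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$cutoff, 10)  # smallest candidate achieving J = 1

  flat <- youden_cutoff(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(flat$youden_j, 0)
})

test_that("Youden cut-off agrees with exhaustive search on random instances", {
  set.seed(103)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(0:12, n, replace = TRUE)
    got <- youden_cutoff(scores, labels)
    want <- oracle_youden(scores, labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden_j, want$youden_j)
  }
})

test_that("grid search recovers a perfectly separating equation and its ties", {
  set.seed(104)
  adm <- admissible_components()
  comp <- adm[sample(nrow(adm), 300, replace = TRUE), ]
  labels <- csi_score(comp) >= 8  # labels are a function of the default score
  res <- grid_search_weights(comp, labels, grid = 0:3)
  expect_equal(res$best_auc, 1)
  expect_identical(res$n_candidates, 4096L)
  expect_true(any(apply(res$ties, 1, function(w)
    all(w == c(1, 2, 1, 2, 1, 1)))))
  # argmax dominates the generating weights evaluated on the same sample
  expect_gte(res$best_auc, auc_rank(csi_score(comp), labels))
})

test_that("a single-candidate grid returns that candidate with its AUC", {
  set.seed(105)
  adm <- admissible_components()
  comp <- adm[sample(nrow(adm), 80, replace = TRUE), ]
  labels <- runif(80) < 0.5
  labels[1:2] <- c(TRUE, FALSE)
  res <- grid_search_weights(comp, labels, grid = list(1, 2, 1, 2, 1, 1))
  expect_identical(res$n_candidates, 1L)
  expect_identical(as.integer(res$best_weights), c(1L, 2L, 1L, 2L, 1L, 1L))
  expect_equal(res$best_auc, auc_rank(csi_score(comp), labels))
})

test_that("grid search is deterministic and permutation-invariant in patient order", {
  set.seed(106)
  adm <- admissible_components()
  comp <- adm[sample(nrow(adm), 120, replace = TRUE), ]
  labels <- plogis(scale(csi_score(comp))) > runif(120)
  labels[1:2] <- c(TRUE, FALSE)
  r1 <- grid_search_weights(comp, labels, grid = 0:2)
  r2 <- grid_search_weights(comp, labels, grid = 0:2)
  expect_identical(r1, r2)
  perm <- sample(120)
  r3 <- grid_search_weights(comp[perm, ], labels[perm], grid = 0:2)
  expect_identical(r1$best_weights, r3$best_weights)
  expect_equal(r1$best_auc, r3$best_auc)
  expect_identical(r1$ties, r3$ties)
})

test_that("tie-breaking prefers the minimal coefficient sum, then lexicographic order", {
  # components where only the CA columns vary: any weight vector with the
  # same (w1, w2) gives the same ranking, so ties abound
  comp <- cbind(c_extent = c(0, 1, 2, 3), c_grade = c(0, 1, 2, 3),
                s_extent = 0, s_grade = 0, i_extent = 0, i_grade = 0)
  labels <- c(FALSE, FALSE, TRUE, TRUE)
  res <- grid_search_weights(comp, labels, grid = 0:1)
  # every vector with w1 + w2 >= 1 separates perfectly; minimal sum is 1 and
  # the lexicographically smallest such vector is (0,1,0,0,0,0)
  expect_equal(res$best_auc, 1)
  expect_identical(as.integer(res$best_weights), c(0L, 1L, 0L, 0L, 0L, 0L))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(107)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(0:15, n, replace = TRUE)
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(labels, scores, direction = "<", quiet = TRUE))))
    expect_equal(auc_rank(scores, labels), ref)
  }
})
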