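test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(21)
  for (k in 1:15) {
    n <- sample(6:30, 1)
    n_pos <- sample(2:(n - 2), 1)
    labels <- factor(c(rep("case", n_pos), rep("control", n - n_pos)),
                     levels = c("case", "control"))
    scores <- sample(seq_len(8), n, replace = TRUE) + rnorm(n, sd = 0.01)
    res <- roc_analysis(scores, labels, positive = "case")
    auc_pairs <- oracle_auc(scores, labels == "case")
    # orientation: report the discriminating direction
    expect_equal(res$auc, max(auc_pairs, 1 - auc_pairs),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and separated score sets give the textbook AUCs", {
  lab <- factor(c("case", "case", "case", "control", "control"),
                levels = c("case", "control"))
  expect_equal(roc_analysis(c(2, 3, 4, 0, 1), lab)$auc, 1)
  expect_equal(roc_analysis(rep(1, 5), lab)$auc, 0.5)
  expect_error(roc_analysis(1:5, rep("case", 5)), "2 classes")
})

test_that("sign reversal flips the undirected concordance", {
  set.seed(22)
  scores <- rnorm(20)
  is_case <- rep(c(TRUE, FALSE), 10)
  expect_equal(oracle_auc(-scores, is_case),
               1 - oracle_auc(scores, is_case), tolerance = 1e-12)
  # after orientation correction the reported AUC is unchanged
  lab <- factor(ifelse(is_case, "case", "control"),
                levels = c("case", "control"))
  expect_equal(roc_analysis(scores, lab)$auc,
               roc_analysis(-scores, lab)$auc, tolerance = 1e-10)
})

test_that("Youden cut-off is invariant under monotone score transforms", {
  set.seed(23)
  scores <- c(rnorm(15, 1), rnorm(15))
  lab <- factor(rep(c("case", "control"), each = 15),
                levels = c("case", "control"))
  r1 <- roc_analysis(scores, lab)
  r2 <- roc_analysis(exp(scores), lab)
  expect_equal(r1$se_at_cutoff$estimate, r2$se_at_cutoff$estimate)
  expect_equal(r1$sp_at_cutoff$estimate, r2$sp_at_cutoff$estimate)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-10)
})

test_that("exact binomial intervals reproduce small-sample bounds", {
  expect_equal(round(clopper_pearson(30, 30)), c(88, 100))
  expect_equal(round(clopper_pearson(10, 10)), c(69, 100))
  expect_equal(round(clopper_pearson(20, 20)), c(83, 100))
  ci <- clopper_pearson(0, 1)
  expect_equal(ci[1], 0)
  expect_equal(ci[2], 97.5, tolerance = 0.01)
  # agrees with the beta-quantile closed form
  expect_equal(clopper_pearson(7, 25) / 100,
               c(qbeta(0.025, 7, 19), qbeta(0.975, 8, 18)),
               tolerance = 1e-9)
  expect_error(clopper_pearson(5, 0), "n must be")
})

test_that("diagnostic metrics follow the 2x2 table conventions", {
  m <- diagnostic_metrics(tp = 20, fp = 0, fn = 0, tn = 10)
  expect_equal(m$se$estimate, 100)
  expect_equal(m$sp$estimate, 100)
  expect_equal(m$lr_pos$estimate, Inf)
  expect_equal(m$lr_neg$estimate, 0)
  expect_true(is.nan(m$lr_neg$ci[2]))
  m2 <- diagnostic_metrics(tp = 19, fp = 3, fn = 1, tn = 7)
  expect_equal(m2$se$estimate, 95)
  expect_equal(m2$sp$estimate, 70)
  expect_equal(m2$ppv$estimate, 100 * 19 / 22)
  expect_gt(m2$lr_pos$ci[2], m2$lr_pos$estimate)
  expect_error(diagnostic_metrics(0, 0, 0, 0), "all-zero")
})

test_that("group comparison keeps its type-I error near nominal", {
  flagged <- vapply(1:50, function(k) {
    set.seed(3000 + k)
    v <- rnorm(24)
    g <- factor(rep(c("a", "b", "c", "d"), each = 6))
    any(group_compare(v, g)$pairwise$significant)
  }, logical(1))
  expect_gte(mean(!flagged), 0.9)
})

test_that("a strongly shifted group is flagged against every other", {
  set.seed(31)
  v <- c(rnorm(10), rnorm(10), rnorm(10), rnorm(10) + 5)
  g <- factor(rep(c("a", "b", "c", "d"), each = 10))
  res <- group_compare(v, g)
  pw <- res$pairwise
  d_pairs <- pw$group1 == "d" | pw$group2 == "d"
  expect_true(all(pw$significant[d_pairs]))
  expect_lt(res$p_value, 0.001)
  # the rank-based route flags them as well
  res2 <- group_compare(v, g, method = "kruskal_dunn")
  expect_true(all(res2$pairwise$significant[d_pairs]))
})

test_that("identical constant groups produce p = 1 and no flags", {
  v <- rep(2.5, 12)
  g <- factor(rep(c("a", "b"), each = 6))
  res <- group_compare(v, g)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_false(any(res$pairwise$significant))
  expect_error(group_compare(c(1, 2, 3), factor(c("a", "a", "b"))),
               ">= 2 values")
})
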