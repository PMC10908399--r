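test_that("AUROC matches the stated examples and the pairwise oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # 2 of 4 positive>negative pairs
  expect_equal(auroc(c(0.8, 0.3, 0.6, 0.5), c(1, 1, 0, 0)), 0.5)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "one class")
  set.seed(19)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
    expect_equal(auroc(scores, labels), pairwise_auroc(scores, labels))
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(4)
  scores <- runif(40); labels <- c(0, 1, rbinom(38, 1, 0.6))
  a <- auroc(scores, labels)
  expect_equal(auroc(qlogis(scores / 2 + 0.25), labels), a)
  expect_equal(auroc(scores^3 + 5, labels), a)
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(60); labels <- c(0, 1, rbinom(58, 1, 0.5))
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("confusion metrics count correctly at the 0.5 threshold", {
  m <- confusion_metrics(c(0.9, 0.4, 0.7, 0.2), c(1, 1, 0, 0))
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(1L, 1L, 1L, 1L))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity",
                          "ppv", "npv")]),
               c(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5,
                 ppv = 0.5, npv = 0.5))
  perfect <- confusion_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "ppv", "npv")]) == 1))
  # 61 positives (41 called), 24 negatives (12 called negative)
  scores <- c(rep(1, 41), rep(0, 20), rep(1, 12), rep(0, 12))
  labels <- c(rep(1, 61), rep(0, 24))
  m85 <- confusion_metrics(scores, labels)
  expect_identical(c(m85$tp, m85$tn), c(41L, 12L))
  expect_equal(m85$accuracy, 53 / 85)
  # a score exactly at the threshold is called positive
  expect_identical(confusion_metrics(0.5, 1)$tp, 1L)
  # undefined PPV reported as NA, not zero
  none_called <- confusion_metrics(c(0.1, 0.2), c(1, 0))
  expect_true(is.na(none_called$ppv))
})

test_that("metric identities hold on random instances", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    m <- confusion_metrics(runif(n), labels)
    expect_identical(m$tp + m$fn, sum(labels == 1))
    expect_identical(m$tn + m$fp, sum(labels == 0))
    expect_equal(m$accuracy,
                 (m$sensitivity * m$n_positive +
                    m$specificity * m$n_negative) / n)
  }
})

test_that("fold aggregation averages five folds and flags undefined metrics", {
  mk <- function(auc) confusion_metrics(c(auc, 1 - auc), c(1, 0))
  same <- replicate(5, confusion_metrics(c(0.9, 0.1), c(1, 0)),
                    simplify = FALSE)
  agg <- aggregate_folds(same)
  expect_equal(unname(agg$mean["accuracy"]), 1)
  folds <- lapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(a) {
    f <- confusion_metrics(c(0.9, 0.1), c(1, 0)); f$auroc <- a; f
  })
  expect_equal(unname(aggregate_folds(folds)$mean["auroc"]), 0.8)
  # one fold with undefined NPV: mean over the 4 defined, flagged
  folds[[3]]$npv <- NA_real_
  agg2 <- aggregate_folds(folds)
  expect_identical(unname(agg2$n_defined["npv"]), 4)
  expect_true("npv" %in% agg2$incomplete)
  expect_error(aggregate_folds(folds[1:4]), "exactly 5")
})

test_that("exact rank-sum enumeration matches wilcox.test and its examples", {
  expect_equal(compare_fold_scores(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 1.0)
  a <- c(0.9, 0.91, 0.92, 0.93, 0.94); b <- c(0.1, 0.11, 0.12, 0.13, 0.14)
  expect_equal(compare_fold_scores(a, b), 2 / 252)
  expect_equal(compare_fold_scores(a, b), compare_fold_scores(b, a))
  expect_error(compare_fold_scores(a, b[1:4]), "same number")
  # no-ties instances agree with the exact Wilcoxon rank-sum test
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(compare_fold_scores(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("Fisher's exact 2x2 has its symmetry and null properties", {
  # proportionally identical tables: p = 1
  expect_equal(fisher_2x2(10, 20, 5, 10), 1.0)
  # swapping the two groups leaves p unchanged
  expect_equal(fisher_2x2(36, 61, 19, 24), fisher_2x2(19, 24, 36, 61))
  # complementing successes/failures leaves p unchanged
  expect_equal(fisher_2x2(36, 61, 19, 24), fisher_2x2(25, 61, 5, 24))
  expect_equal(fisher_2x2(5, 61, 1, 24),
               fisher.test(matrix(c(5, 56, 1, 23), 2, byrow = TRUE))$p.value)
})

test_that("uncorrected chi-squared reproduces the printed alcohol-row p-values", {
  # the published cohort table's alcohol rows match Pearson chi-squared
  # without continuity correction at printed precision, not Fisher's exact
  expect_equal(round(fisher_2x2(38, 61, 18, 24, method = "chisq"), 3), 0.266)
  expect_equal(round(fisher_2x2(18, 61, 5, 24, method = "chisq"), 4), 0.4177)
  expect_equal(round(fisher_2x2(5, 61, 1, 24, method = "chisq"), 4), 0.5138)
})

test_that("cohort table summarizes by class with the documented layout", {
  meta <- as.data.frame(test_cohort())
  tab <- cohort_table(meta, continuous = c("age_years", "bmi"),
                      categorical = "alcohol_category")
  expect_s3_class(tab, "eus_cohort_table")
  expect_true(all(c("variable", "level", "positive", "negative",
                    "p_value") %in% names(tab)))
  expect_identical(tab$variable[1:2], c("age_years", "bmi"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  one_class <- meta; one_class$label <- 1L
  expect_error(cohort_table(one_class), "both classes")
})

test_that("ordered-vs-balanced comparison assembles per-metric p-values", {
  cv <- test_cv_run()
  cmp <- compare_modes(cv, cv)
  expect_true(all(cmp$p_values == 1, na.rm = TRUE))
  expect_named(cmp$p_values, c("auroc", "accuracy", "sensitivity",
                               "specificity", "ppv", "npv"))
})
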