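test_that("classification summary arithmetic is internally consistent", {
  s <- classification_summary(tp = 67, fn = 13, tn = 66, fp = 14)
  expect_equal(s$sensitivity, 100 * 67 / 80)
  expect_equal(s$specificity, 100 * 66 / 80)
  expect_equal(s$point_auc, (s$sensitivity + s$specificity) / 2)
  expect_equal(s$n_positive, 80)
  expect_equal(s$n_negative, 80)

  perfect <- classification_summary(10, 0, 12, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$point_auc, 100)

  expect_error(classification_summary(0, 0, 5, 5), "both classes")
  expect_error(classification_summary(-1, 2, 5, 5), "non-negative")
})

test_that("point AUC is the mean of sensitivity and specificity", {
  expect_equal(point_auc(0.8375, 0.8125), 0.8250)
  expect_equal(point_auc(0.7250, 0.8250), 0.7750)
  expect_equal(point_auc(1, 0), 0.5)
  expect_error(point_auc(1.2, 0.5), "\\[0, 1\\]")
})

test_that("summarize_outcomes reduces fold outcomes to counts and rates", {
  out <- data.frame(
    subject_id = sprintf("S%02d", 1:8),
    true = c(1, 1, 1, 1, -1, -1, -1, -1),
    predicted = c(1, 1, -1, 1, -1, -1, 1, -1),
    decision = c(2, 1.5, -0.2, 0.3, -1, -2, 0.1, -0.5))
  s <- summarize_outcomes(out)
  expect_equal(c(s$tp, s$fn, s$tn, s$fp), c(3, 1, 3, 1))
  expect_equal(s$sensitivity, 75)
  expect_equal(s$specificity, 75)
  expect_equal(s$point_auc, 75)
  expect_equal(s$rank_auc, 100 * rank_auc(out$decision, out$true))
  expect_error(summarize_outcomes(out[out$true == 1, ]), "both classes")
})

test_that("misclassification overlap does set arithmetic with rounding", {
  mk <- function(pred_pos, pred_neg) data.frame(
    subject_id = sprintf("S%03d", 1:20),
    true = rep(c(1, -1), each = 10),
    predicted = c(pred_pos, pred_neg))
  # A misses subjects 8:10 in the positive group; B misses 9:12
  a <- mk(c(rep(1, 7), rep(-1, 3)), rep(-1, 10))
  b <- mk(c(rep(1, 8), rep(-1, 2)), c(rep(-1, 10)))
  ov <- misclassification_overlap(a, b, group = 1)
  expect_equal(ov$n_missed_a, 3)
  expect_equal(ov$n_missed_b, 2)
  expect_equal(ov$n_overlap, 2)
  expect_equal(ov$percentage, 67)  # 2/3 -> 66.7 -> 67

  # identical and disjoint missed sets
  expect_equal(misclassification_overlap(a, a, 1)$percentage, 100)
  b2 <- mk(c(rep(-1, 3), rep(1, 7)), rep(-1, 10))  # misses 1:3
  a2 <- mk(c(rep(1, 7), rep(-1, 3)), rep(-1, 10))  # misses 8:10
  expect_equal(misclassification_overlap(a2, b2, 1)$n_overlap, 0)
  expect_equal(misclassification_overlap(a2, b2, 1)$percentage, 0)

  bad <- b; bad$subject_id[1] <- "ZZZ"
  expect_error(misclassification_overlap(a, bad, 1), "different subjects")
})

test_that("subgroup comparisons use the pooled t with central-t p values", {
  rec <- data.frame(v = c(1, 2, 3, 4, 5, 6))
  correct <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  tab <- subgroup_comparison(rec, correct, variables = "v")
  expect_equal(tab$t, -3.674, tolerance = 1e-3)
  expect_equal(tab$df, 4)
  expect_equal(tab$p, 0.0213, tolerance = 1e-3)

  # identical subgroup values: t = 0, p = 1
  rec2 <- data.frame(v = c(1, 2, 3, 1, 2, 3))
  tab2 <- subgroup_comparison(rec2, correct, variables = "v")
  expect_equal(tab2$t, 0)
  expect_equal(tab2$p, 1)

  # everywhere-constant variable: skipped with flag
  rec3 <- data.frame(v = rep(2, 6))
  expect_true(subgroup_comparison(rec3, correct, variables = "v")$skipped)
  # subgroup smaller than 2: skipped
  expect_true(subgroup_comparison(rec, c(FALSE, rep(TRUE, 5)),
                                  variables = "v")$skipped)
})
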