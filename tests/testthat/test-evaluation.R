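test_that("confusion counts match a brute-force pairwise tally", {
  truth <- c("positive", "positive", "positive", rep("negative", 90))
  pred <- c("positive", "positive", "negative", rep("negative", 90))
  cc <- confusion_counts(truth, pred)
  expect_equal(cc$TP, 2L)
  expect_equal(cc$FN, 1L)
  expect_equal(cc$FP, 0L)

  withr::with_seed(19, {
    for (i in 1:200) {
      n <- sample(2:40, 1)
      tr <- random_calls(n, runif(1))
      pr <- random_calls(n, runif(1))
      cc <- confusion_counts(tr, pr)
      # exhaustive per-pair tally
      tally <- table(factor(tr, c("positive", "negative")),
                     factor(pr, c("positive", "negative")))
      expect_equal(cc$TP, tally["positive", "positive"][[1]])
      expect_equal(cc$FN, tally["positive", "negative"][[1]])
      expect_equal(cc$FP, tally["negative", "positive"][[1]])
      expect_equal(cc$TN, tally["negative", "negative"][[1]])
      expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
    }
  })
  expect_error(confusion_counts(truth, pred[-1]), "lengths differ")
})

test_that("one misclassified of three positives gives balanced accuracy 83.3%", {
  cc <- confusion_counts(
    c(rep("positive", 3), rep("negative", 93)),
    c(rep("positive", 2), "negative", rep("negative", 93)))
  m <- accuracy_metrics(cc)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 1)
  expect_equal(m$balanced_accuracy, 5 / 6)
  expect_equal(round(100 * m$balanced_accuracy, 1), 83.3)
})

test_that("metrics handle perfection, zero denominators and failure flags", {
  perfect <- accuracy_metrics(confusion_counts(
    rep(c("positive", "negative"), 5), rep(c("positive", "negative"), 5)))
  expect_equal(perfect$FP + perfect$FN, 0L)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "PPV", "NPV",
                                "balanced_accuracy")]),
               c(sensitivity = 1, specificity = 1, PPV = 1, NPV = 1,
                 balanced_accuracy = 1))

  no_pos <- accuracy_metrics(confusion_counts(rep("negative", 5), rep("negative", 5)))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$PPV))
  expect_true(is.na(no_pos$balanced_accuracy))

  coin <- accuracy_metrics(confusion_counts(
    rep(c("positive", "negative"), each = 4),
    rep(c("positive", "negative"), 4)))
  expect_equal(coin$balanced_accuracy, 0.5)
  expect_equal(coin$flag, "failed_classification")
})

test_that("balanced accuracy is invariant under swapping the positive label", {
  withr::with_seed(23, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      tr <- random_calls(n)
      pr <- random_calls(n)
      a <- accuracy_metrics(confusion_counts(tr, pr, positive = "positive"))
      b <- accuracy_metrics(confusion_counts(tr, pr, positive = "negative"))
      expect_equal(a$balanced_accuracy, b$balanced_accuracy)
    }
  })
})

test_that("metrics agree with direct per-sample computation", {
  withr::with_seed(29, {
    for (i in 1:100) {
      n <- sample(5:60, 1)
      tr <- random_calls(n)
      pr <- random_calls(n)
      m <- accuracy_metrics(confusion_counts(tr, pr))
      pos <- tr == "positive"
      if (any(pos)) expect_equal(m$sensitivity, mean(pr[pos] == "positive"))
      if (any(!pos)) expect_equal(m$specificity, mean(pr[!pos] == "negative"))
    }
  })
})

test_that("ROC analysis matches concordance and known limits", {
  # perfectly separating posteriors
  perfect <- roc_pr_curves(c(0.9, 0.8, 0.2, 0.1),
                           c("positive", "positive", "negative", "negative"))
  expect_equal(perfect$auroc, 1)
  # constant posteriors carry no information
  flat <- roc_pr_curves(rep(0.5, 10), rep(c("positive", "negative"), 5))
  expect_equal(flat$auroc, 0.5)
  expect_error(roc_pr_curves(runif(5), rep("positive", 5)), "both classes")

  # pairwise-concordance oracle (ties counted half)
  auroc_oracle <- function(pp, truth) {
    pos <- pp[truth == "positive"]
    neg <- pp[truth != "positive"]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  withr::with_seed(37, {
    for (i in 1:60) {
      n <- sample(6:40, 1)
      truth <- c("positive", "negative", random_calls(n - 2))
      pp <- round(runif(n), 2)  # rounded: force ties
      r <- roc_pr_curves(pp, truth)
      expect_equal(r$auroc, auroc_oracle(pp, truth))
      # invariance under a strictly monotone transform
      expect_equal(roc_pr_curves(pp^3, truth)$auroc, r$auroc)
    }
  })
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    truth <- random_calls(80, 0.3)
    pp <- runif(80)
    r <- roc_pr_curves(pp, truth)
    ref <- pROC::roc(response = truth, predictor = pp, levels = c("negative", "positive"),
                     direction = "<", quiet = TRUE)
    expect_equal(r$auroc, as.numeric(pROC::auc(ref)))
  })
})

test_that("the published shared-model summaries are reproduced exactly", {
  tab <- model_transfer_accuracies(shared_only = TRUE)
  expect_equal(nrow(tab), 33L)

  s_fin <- summarize_balanced_accuracy(tab$ba_finnish_models_finnish_full)
  expect_equal(c(s_fin$median, s_fin$q1, s_fin$q3), c(0.999, 0.988, 1.000))

  s_transfer <- summarize_balanced_accuracy(tab$ba_finnish_models_danish_full)
  expect_equal(c(s_transfer$median, s_transfer$q1, s_transfer$q3),
               c(0.971, 0.916, 0.995))

  s_dk <- summarize_balanced_accuracy(tab$ba_danish_models_danish_full)
  expect_equal(c(s_dk$median, s_dk$q1, s_dk$q3), c(0.995, 0.965, 0.998))

  # with n = 33 the quartiles are the 9th, 17th and 25th order statistics
  v <- sort(tab$ba_finnish_models_danish_full)
  expect_equal(c(s_transfer$q1, s_transfer$median, s_transfer$q3),
               v[c(9, 17, 25)])

  one <- summarize_balanced_accuracy(0.42)
  expect_equal(c(one$median, one$q1, one$q3), rep(0.42, 3))
})

test_that("rank-sum comparison matches the pair-count oracle", {
  same <- compare_model_sets(1:20, 1:20)
  expect_gt(same$p_value, 0.9)

  u_oracle <- function(a, b) {
    s <- 0
    for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
    s
  }
  withr::with_seed(43, {
    for (i in 1:60) {
      a <- round(runif(sample(3:15, 1)), 1)
      b <- round(runif(sample(3:15, 1)), 1)
      expect_equal(compare_model_sets(a, b)$statistic, u_oracle(a, b))
    }
  })
})

test_that("cross-cohort model-set comparisons land at the published magnitudes", {
  tab <- model_transfer_accuracies(shared_only = TRUE)
  # same models, home cohort vs transfer cohort
  p1 <- compare_model_sets(tab$ba_finnish_models_finnish_full,
                           tab$ba_finnish_models_danish_full)$p_value
  expect_lt(p1, 1e-5)
  expect_gt(p1, 1e-8)
  # population-specific models beat transferred models on the same cohort
  p2 <- compare_model_sets(tab$ba_danish_models_danish_full,
                           tab$ba_finnish_models_danish_full)$p_value
  expect_lt(p2, 0.05)
  expect_gt(p2, 0.001)
})
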