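test_that("confusion matrix counts and class-swap symmetry", {
  truth <- c("a", "a", "b", "b", "b")
  pred <- c("a", "b", "b", "b", "a")
  cm <- confusion(truth, pred, positive = "a")
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]), c(tp = 1, fn = 1, tn = 2, fp = 1))
  # flipping the positive class swaps (tp,tn) and (fn,fp)
  cm2 <- confusion(truth, pred, positive = "b")
  expect_equal(cm2$tp, cm$tn); expect_equal(cm2$tn, cm$tp)
  expect_equal(cm2$fn, cm$fp); expect_equal(cm2$fp, cm$fn)
  # perfect and degenerate predictions
  expect_equal(confusion(truth, truth, "a")$fn, 0)
  all_neg <- confusion(truth, rep("b", 5), "a")
  expect_equal(all_neg$tp, 0); expect_equal(all_neg$fp, 0)
  expect_error(confusion("a", c("a", "b"), "a"), "equal length")
})

test_that("threshold metrics satisfy their identities and degenerate conventions", {
  set.seed(12)
  for (i in 1:25) {
    cm <- confusion_from_counts(tp = rpois(1, 20), fn = rpois(1, 5),
                                tn = rpois(1, 30), fp = rpois(1, 8))
    m <- metrics_from_cm(cm)
    expect_equal(m$bacc, (m$sn + m$sp) / 2)  # exact identity
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # MCC invariant under class swap; SN/SP exchange
    sw <- metrics_from_cm(confusion_from_counts(tp = cm$tn, fn = cm$fp,
                                                tn = cm$tp, fp = cm$fn))
    expect_equal(sw$mcc, m$mcc, tolerance = 1e-12)
    expect_equal(sw$sn, m$sp); expect_equal(sw$sp, m$sn)
  }
  expect_equal(metrics_from_cm(confusion_from_counts(0, 0, 5, 2))$mcc, 0)
})

test_that("published-style rates recover a unique integer confusion matrix", {
  cm <- recover_cm_from_rates(0.964, 0.951, 55, 263)
  expect_s3_class(cm, "grq_cm")  # unique
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]),
               c(tp = 53, fn = 2, tn = 250, fp = 13))
  cm2 <- recover_cm_from_rates(1.000, 0.905, 55, 263)
  expect_equal(unlist(cm2[c("tp", "fn", "tn", "fp")]),
               c(tp = 55, fn = 0, tn = 238, fp = 25))
  cm3 <- recover_cm_from_rates(1.0, 1.0, 10, 10)
  expect_equal(cm3$tp, 10); expect_equal(cm3$tn, 10)
  # impossible rate flags a table inconsistency
  expect_error(recover_cm_from_rates(0.123, 0.9, 10, 10), "inconsistency")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle", {
  # 4-point toy set by exhaustive pair counting
  r <- roc_pr_curves(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0), positive = 1)
  expect_equal(r$auc, 0.75)
  # random tie-free inputs vs the U-statistic
  set.seed(6)
  for (i in 1:10) {
    n <- 40
    s <- sample(seq_len(200), n)  # distinct scores
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y == 1], s[y == 0], ">")
    u_auc <- mean(pairs)
    expect_equal(roc_pr_curves(s, y, positive = 1)$auc, u_auc, tolerance = 1e-12)
  }
  expect_error(roc_pr_curves(1:3, c(1, 1, 1), positive = 1), "both classes")
})

test_that("curves agree with an independent ROC library and handle ties/extremes", {
  skip_if_not_installed("pROC")
  set.seed(8)
  n <- 150
  y <- rbinom(n, 1, 0.3)
  s <- round(runif(n), 2)  # deliberate ties
  ours <- roc_pr_curves(s, y, positive = 1)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
  expect_equal(ours$auc, ref, tolerance = 1e-10)
  # perfect separation
  perf <- roc_pr_curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), positive = 1)
  expect_equal(perf$auc, 1); expect_equal(perf$aupr, 1)
})

test_that("null scores give chance-level AUC and prevalence-level AUPR", {
  set.seed(14)
  n <- 2000
  y <- rep(c(1, 0), each = n / 2)
  s <- runif(n)
  r <- roc_pr_curves(s, y, positive = 1)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  expect_equal(r$aupr, 0.5, tolerance = 0.05)
  # imbalanced prevalence
  y2 <- c(rep(1, 200), rep(0, 1800))
  r2 <- roc_pr_curves(runif(2000), y2, positive = 1)
  expect_equal(r2$aupr, 0.1, tolerance = 0.05)
})

test_that("score_metrics ties thresholded and ranking views together", {
  y <- c(rep("inactive", 10), rep("active", 40))
  s <- c(runif(10, 0.6, 1), runif(40, 0, 0.4))
  m <- score_metrics(s, y, positive = "inactive")
  expect_equal(m$bacc, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$cm$tp, 10)
  tab <- metrics_table(list(run1 = m))
  expect_equal(tab$method, "run1")
  expect_equal(tab$bacc, 1)
})
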