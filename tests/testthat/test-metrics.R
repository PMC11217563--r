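test_that("confusion_from_rates recovers integer counts from rates", {
  cm <- confusion_from_rates(300, 405, 1.0, 0.975)
  expect_identical(unclass(cm)[c("TP", "FP", "TN", "FN")],
                   list(TP = 300, FP = 10, TN = 395, FN = 0))
  cm2 <- confusion_from_rates(10, 10, 0.5, 0.5)
  expect_true(all(unlist(cm2) == 5))
  cm3 <- confusion_from_rates(17, 23, 1.0, 1.0)
  expect_identical(cm3$FP + cm3$FN, 0)
  expect_error(confusion_from_rates(10, 10, 1.2, 0.5), "\\[0, 1\\]")
})

test_that("the published worked example is reproduced at three decimals", {
  rep <- compute_metrics(confusion_from_rates(300, 405, 1.0, 0.975))
  expect_equal(round_half_up(rep$sensitivity), 1.000)
  expect_equal(round_half_up(rep$specificity), 0.975)
  expect_equal(round_half_up(rep$f1_pos), 0.984)
  expect_equal(round_half_up(rep$mcc), 0.972)
  expect_equal(round_half_up(rep$accuracy), 0.986)
  expect_equal(round_half_up(rep$precision_pos), 0.968)
  expect_equal(round_half_up(rep$precision_neg), 1.000)
})

test_that("degenerate confusion matrices give closed-form metrics", {
  perfect <- compute_metrics(confusion_matrix(50, 0, 50, 0))
  for (f in c("sensitivity", "specificity", "precision_pos", "precision_neg",
              "f1_pos", "f1_neg", "mcc", "accuracy")) {
    expect_equal(perfect[[f]], 1.0, info = f)
  }
  chance <- compute_metrics(confusion_matrix(25, 25, 25, 25))
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "all-zero")
})

test_that("zero denominators yield explicit NA, never silent zero", {
  rep <- compute_metrics(confusion_matrix(0, 0, 10, 5))  # no predicted pos
  expect_true(is.na(rep$precision_pos))
  expect_true(is.na(rep$mcc))
  expect_equal(rep$specificity, 1.0)
})

test_that("metrics agree with a per-sample tally oracle on random vectors", {
  withr::with_seed(30, {
    for (trial in 1:250) {
      n <- sample(10:60, 1)
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      preds <- rbinom(n, 1, runif(1, 0.2, 0.8))
      # oracle: walk the samples one by one
      tp <- fp <- tn <- fn <- 0L
      for (i in seq_len(n)) {
        if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1L
        else if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1L
        else if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1L
        else fn <- fn + 1L
      }
      rep <- compute_metrics(confusion_matrix(tp, fp, tn, fn))
      acc_oracle <- mean(preds == labels)
      expect_equal(rep$accuracy, acc_oracle)
      if (tp + fn > 0) expect_equal(rep$sensitivity,
                                    sum(preds[labels == 1] == 1) / sum(labels == 1))
      if (tn + fp > 0) expect_equal(rep$specificity,
                                    sum(preds[labels == 0] == 0) / sum(labels == 0))
      if (!is.na(rep$mcc) && stats::sd(preds) > 0 && stats::sd(labels) > 0) {
        expect_equal(rep$mcc, suppressWarnings(stats::cor(preds, labels)),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("MCC is symmetric under a simultaneous class swap", {
  withr::with_seed(31, {
    for (i in 1:20) {
      cts <- sample(0:40, 4, replace = TRUE)
      if (sum(cts) == 0) next
      m1 <- compute_metrics(confusion_matrix(cts[1], cts[2], cts[3], cts[4]))
      # swap classes: TP<->TN and FP<->FN
      m2 <- compute_metrics(confusion_matrix(cts[3], cts[4], cts[1], cts[2]))
      expect_equal(m1$mcc, m2$mcc)
      expect_equal(m1$accuracy, m2$accuracy)
    }
  })
})

test_that("half-up rounding breaks ties upward at three decimals", {
  expect_equal(round_half_up(0.9865, 3), 0.987)
  expect_equal(round_half_up(0.0005, 3), 0.001)
  expect_equal(round_half_up(-0.0005, 3), -0.001)
})
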