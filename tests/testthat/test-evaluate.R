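# Small synthetic feature tables: classifier behaviour can be checked
# without any EEG machinery.
toy_features <- function(n_per_group = 5, epochs = 10, shift = 0, p = 4,
                         seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in c("epilepsy", "pnes")) for (i in seq_len(n_per_group)) {
    pid <- paste0(substr(g, 1, 2), i)
    for (e in seq_len(epochs)) {
      x <- rnorm(p)
      if (g == "epilepsy") x[1] <- x[1] + shift
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = paste0(pid, "_", e), patient_id = pid, group = g,
        t(stats::setNames(x, paste0("beta_f_", seq_len(p)))))
    }
  }
  do.call(rbind, rows)
}

test_that("the paired patient split enumerates all cross-group pairs", {
  pats <- data.frame(patient_id = c(paste0("E", 1:5), paste0("P", 1:5)),
                     group = rep(c("epilepsy", "pnes"), each = 5))
  scheme <- build_split_scheme(pats)
  expect_length(scheme, 25)
  for (fold in scheme) {
    expect_length(fold$train_patients, 8)
    expect_false(fold$test_epilepsy %in% fold$train_patients)
    expect_false(fold$test_pnes %in% fold$train_patients)
  }
  small <- data.frame(patient_id = c("a", "b", "x", "y", "z"),
                      group = c("epilepsy", "epilepsy", rep("pnes", 3)))
  expect_length(build_split_scheme(small), 6)
  expect_error(build_split_scheme(small[small$group == "pnes", ]),
               "non-empty")
})

test_that("confusion metrics follow their arithmetic definitions", {
  truth <- c(rep("epilepsy", 10), rep("pnes", 10))
  pred <- c(rep("epilepsy", 8), rep("pnes", 2), rep("pnes", 8),
            rep("epilepsy", 2))
  m <- compute_metrics(truth, pred)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$specificity, 0.8)

  perfect <- compute_metrics(truth, truth, scores = c(rep(1, 10), rep(0, 10)))
  expect_equal(unlist(perfect[c("precision", "recall", "accuracy",
                                "specificity", "auc")]),
               c(precision = 1, recall = 1, accuracy = 1, specificity = 1,
                 auc = 1))

  none <- compute_metrics(truth, rep("pnes", 20))
  expect_true(none$precision_undefined)
  expect_equal(none$precision, 0)
})

test_that("ROC/AUC match rank statistics and endpoints", {
  truth <- c(rep("epilepsy", 6), rep("pnes", 6))
  expect_equal(roc_curve(c(6:1 + 10, 6:1), truth)$auc, 1)
  expect_equal(roc_curve(c(6:1, 6:1 + 10), truth)$auc, 0)

  set.seed(5)
  scores <- rnorm(12)
  # Mann-Whitney oracle: AUC = U / (n_pos * n_neg)
  u <- sum(outer(scores[1:6], scores[7:12], ">")) +
    0.5 * sum(outer(scores[1:6], scores[7:12], "=="))
  expect_equal(roc_curve(scores, truth)$auc, u / 36, tolerance = 1e-12)

  # ties handled as in the rank statistic
  ts <- c(1, 1, 2, 3, 1, 2, 2, 3, 1, 3, 2, 1)
  ut <- sum(outer(ts[1:6], ts[7:12], ">")) +
    0.5 * sum(outer(ts[1:6], ts[7:12], "=="))
  expect_equal(roc_curve(ts, truth)$auc, ut / 36, tolerance = 1e-12)

  # null calibration at larger n
  set.seed(6)
  big_truth <- rep(c("epilepsy", "pnes"), each = 500)
  expect_lt(abs(roc_curve(rnorm(1000), big_truth)$auc - 0.5), 0.05)
  expect_error(roc_curve(rnorm(5), rep("epilepsy", 5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(11)
  scores <- rnorm(40)
  truth <- rep(c("epilepsy", "pnes"), 20)
  ours <- roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truth, levels = c("pnes", "epilepsy")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("the battery is chance-level on null features", {
  features <- toy_features(shift = 0, seed = 2)
  scheme <- build_split_scheme(unique(features[, c("patient_id", "group")]))
  res <- run_battery(features, scheme, c("random_forest", "svm_linear"),
                     seed = 3)
  # binomial 95% band around 0.5 for 100 subjects
  expect_true(all(abs(res$accuracy - 0.5) < 1.96 * sqrt(0.25 / 100)))
})

test_that("the battery detects a strongly planted group difference", {
  features <- toy_features(shift = 4, seed = 4)
  scheme <- build_split_scheme(unique(features[, c("patient_id", "group")]))
  res <- run_battery(features, scheme, default_classifiers(), seed = 3)
  expect_true(all(res$auc > 0.8))
  expect_true(all(res$accuracy > 0.8))
})

test_that("battery bookkeeping: fold count, determinism, validation", {
  features <- toy_features(shift = 1, seed = 5)
  scheme <- build_split_scheme(unique(features[, c("patient_id", "group")]))
  res <- run_battery(features, scheme, "decision_tree", seed = 9)
  pf <- attr(res, "per_fold")
  expect_identical(nrow(pf), 25L)
  expect_equal(res$accuracy, mean(pf$accuracy))
  res2 <- run_battery(features, scheme, "decision_tree", seed = 9)
  expect_identical(res, res2)

  # duplicated feature column leaves a deterministic tree unchanged
  dup <- features
  dup$beta_f_dup <- dup$beta_f_1
  res3 <- run_battery(dup, scheme, "decision_tree", seed = 9)
  expect_equal(res$accuracy, res3$accuracy)

  bad <- features; bad$beta_f_1[3] <- NaN
  expect_error(run_battery(bad, scheme, "decision_tree", 1), "non-finite")
})

test_that("leave-one-band-out pinpoints the informative band", {
  set.seed(8)
  features <- toy_features(shift = 3, seed = 8, p = 2)
  # add an uninformative second band
  features$alpha_f_1 <- rnorm(nrow(features))
  features$alpha_f_2 <- rnorm(nrow(features))
  scheme <- build_split_scheme(unique(features[, c("patient_id", "group")]))
  tab <- leave_one_band_out(features, scheme, "random_forest", seed = 2)
  acc <- stats::setNames(tab$accuracy, tab$setting)
  expect_lt(acc[["All-beta"]], acc[["All"]] - 0.2)
  expect_lt(abs(acc[["All-alpha"]] - acc[["All"]]), 0.1)
  # the All row equals a plain battery run at the same seed
  plain <- run_battery(features, scheme, "random_forest", seed = 2)
  expect_equal(acc[["All"]], plain$accuracy)
})

test_that("leave-one-feature-out drops constant features without effect", {
  features <- toy_features(shift = 2, seed = 10, p = 2)
  names(features)[4:5] <- c("beta_coverage_1", "beta_duration_1")
  features$beta_occurrence_1 <- 1 # constant
  scheme <- build_split_scheme(unique(features[, c("patient_id", "group")]))
  tab <- leave_one_feature_out(features, scheme, "decision_tree", seed = 4)
  expect_identical(tab$setting,
                   c("All", "All-occurrence", "All-duration",
                     "All-coverage"))
  acc <- stats::setNames(tab$accuracy, tab$setting)
  expect_equal(acc[["All-occurrence"]], acc[["All"]])
})
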