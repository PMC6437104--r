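# Confusion/validity arithmetic, AIC/MDL penalties, ROC and sensitivity.

test_that("confusion counts and row percentages are exact", {
  cm <- confusion(c(1, 1, -1, -1), c(1, 1, -1, -1))
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 0, 0, 2))
  expect_equal(unname(cm$row_percent[1, ]), c(100, 0))
  expect_equal(unname(cm$row_percent[2, ]), c(0, 100))

  truth <- c(rep(1, 10), rep(-1, 10))
  pred <- c(rep(1, 9), -1, rep(1, 2), rep(-1, 8))
  cm <- confusion(truth, pred)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(9, 1, 2, 8))
  expect_equal(unname(cm$row_percent[1, ]), c(90, 10))
  expect_equal(unname(cm$row_percent[2, ]), c(20, 80))

  all_pos <- confusion(truth, rep(1, 20))
  expect_equal(all_pos$fn, 0)
  expect_equal(all_pos$tn, 0)
  expect_error(confusion(numeric(0), numeric(0)), "empty")
})

test_that("row percentages of emitted confusion matrices sum to 100", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    cm <- confusion(truth, pred)
    sums <- rowSums(cm$row_percent)
    expect_true(all(abs(sums - 100) <= 0.01))
  }
})

test_that("validity metrics match their defining ratios", {
  cm <- confusion(c(rep(1, 10), rep(-1, 10)),
                  c(rep(1, 9), -1, rep(1, 2), rep(-1, 8)))
  v <- validity_metrics(cm)
  expect_equal(v$accuracy, 0.85)
  expect_equal(v$sensitivity, 0.90)
  expect_equal(v$effectiveness, 0.80)
  expect_equal(v$precision, 9 / 11, tolerance = 1e-12)

  perfect <- validity_metrics(confusion(c(1, -1), c(1, -1)))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "effectiveness",
                                "precision")]), c(accuracy = 1, sensitivity = 1,
                                effectiveness = 1, precision = 1))

  none_pos <- validity_metrics(confusion(c(1, -1), c(-1, -1)))
  expect_true(is.na(none_pos$precision))
  expect_true("precision" %in% none_pos$flags)
})

test_that("validity composed with confusion equals direct label formulas", {
  set.seed(22)
  for (i in 1:200) {
    n <- sample(6:50, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    v <- validity_metrics(confusion(truth, pred))
    expect_equal(v$accuracy, mean(truth == pred))
    expect_equal(v$sensitivity, mean(pred[truth == 1] == 1))
    expect_equal(v$effectiveness, mean(pred[truth == -1] == -1))
  }
})

test_that("performance metrics have their closed-form values and flags", {
  targets <- rep(c(1, -1), 10)
  perfect <- performance_metrics(targets, targets, model = 10)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$pct_error, 0)
  expect_true(perfect$degenerate)
  expect_equal(perfect$aic, -Inf)

  const <- performance_metrics(rep(0, 20), targets, model = 10)
  expect_equal(const$mse, 1)
  expect_equal(const$nmse, 1)
  expect_true(is.na(const$r))
})

test_that("AIC and MDL penalties increase strictly with parameter count", {
  for (mse in c(0.05, 0.29, 0.9)) {
    for (n in c(50, 187, 1000)) {
      s1 <- model_selection_scores(mse, 259, n)
      s2 <- model_selection_scores(mse, 819, n)
      expect_gt(s2$aic, s1$aic)
      expect_gt(s2$mdl, s1$mdl)
    }
  }
})

test_that("ROC endpoints, fixtures and the permutation null behave", {
  sep <- roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$tpr[1], 0); expect_equal(sep$fpr[1], 0)
  expect_equal(utils::tail(sep$tpr, 1), 1); expect_equal(utils::tail(sep$fpr, 1), 1)

  fix <- roc(c(0.9, 0.8, 0.7, 0.1), c(1, -1, 1, -1))
  expect_equal(fix$auc, 0.75)

  set.seed(23)
  scores <- stats::rnorm(2000)
  labels <- sample(c(-1, 1), 2000, replace = TRUE)
  null_auc <- roc(scores, labels)$auc
  expect_gt(null_auc, 0.45); expect_lt(null_auc, 0.55)

  expect_error(roc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals the exhaustive pair-count oracle, ties included", {
  set.seed(24)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)   # forces ties
    expect_equal(roc(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  scores <- stats::rnorm(300)
  labels <- ifelse(scores + stats::rnorm(300) > 0, 1, -1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(roc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("input sensitivity recovers linear response ratios and dead channels", {
  # near-linear single unit with weights (3, 1): tiny weights keep tanh linear
  lin <- structure(list(W = list(matrix(c(3e-4, 1e-4), 2, 1)), b = list(0)),
                   class = "mlp_model")
  set.seed(26)
  X <- scale(matrix(stats::rnorm(200), 100, 2))   # exactly unit-sd channels
  s <- input_sensitivity(lin, X)
  expect_lt(abs(s$sensitivity[1] / s$sensitivity[2] - 3), 0.03)
  expect_equal(s$rank[1], 1)

  dead <- structure(list(W = list(matrix(c(0, 1), 2, 1)), b = list(0)),
                    class = "mlp_model")
  s <- input_sensitivity(dead, X)
  expect_equal(unname(s$sensitivity[1]), 0)

  Xc <- X; Xc[, 2] <- 5
  s <- input_sensitivity(lin, Xc)
  expect_equal(unname(s$sensitivity[2]), 0)
  expect_equal(s$flags, 2L)
})

test_that("evaluation bundles cover both levels with majority voting", {
  set.seed(27)
  fm <- structure(list(
    X = matrix(stats::rnorm(18), 9, 2),
    y = c(1, 1, 1, -1, -1, -1, 1, 1, 1),
    subject_id = rep(c("A", "B", "C"), each = 3),
    laugh_id = sprintf("L%d", 1:9),
    schema = list(schema_id = "TEST", p = 2), legacy_layout = FALSE,
    excluded = data.frame()), class = "feature_matrix")
  # model predicting +1 iff x1 > 0; craft X so subject A gets 2 of 3 positive
  fm$X[, 1] <- c(1, 1, -1, -1, -1, -1, 1, 1, 1)
  strong <- structure(list(W = list(matrix(c(50, 0), 2, 1)), b = list(0)),
                      class = "mlp_model")
  rep_ <- evaluate_network(strong, fm, level = "both")
  expect_named(rep_, c("laugh", "subject"))
  expect_equal(rep_$subject$n, 3)
  # subject A: 2/3 laughs positive -> predicted depressed
  expect_equal(rep_$subject$confusion$tp, 2)
  expect_equal(rep_$subject$confusion$tn, 1)

  # a perfect classifier is perfect at both levels
  fm$X[, 1] <- fm$y
  rep2 <- evaluate_network(strong, fm, level = "both")
  expect_equal(rep2$laugh$validity$accuracy, 1)
  expect_equal(rep2$subject$validity$accuracy, 1)
  expect_equal(rep2$laugh$roc$auc, 1)
})
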