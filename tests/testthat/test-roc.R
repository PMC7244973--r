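test_that("perfect separation gives AUC 1 with a threshold in the gap", {
  r <- roc_curve(c(0.1, 0.2), c(5, 6))
  expect_equal(r$auc, 1)
  expect_equal(r$se_at_youden, 1)
  expect_equal(r$sp_at_youden, 1)
  expect_gt(r$youden_threshold, 0.2)
  expect_lt(r$youden_threshold, 5)
})

test_that("identical groups give AUC 0.5; identical scores are degenerate", {
  x <- c(1, 2, 3, 4)
  expect_equal(roc_curve(x, x)$auc, 0.5, tolerance = 1e-12)
  d <- roc_curve(rep(2, 5), rep(2, 3))
  expect_true(d$degenerate)
  expect_equal(d$auc, 0.5)
  expect_true(is.na(d$youden_threshold))
})

test_that("AUC equals exhaustive pair counting with half-weighted ties", {
  pair_auc <- function(mn, ma) {
    wins <- 0
    for (a in ma) for (n in mn) wins <- wins + (a > n) + 0.5 * (a == n)
    wins / (length(ma) * length(mn))
  }
  r <- roc_curve(c(1, 2, 3), c(2.5, 4))
  expect_equal(r$auc, pair_auc(c(1, 2, 3), c(2.5, 4)), tolerance = 1e-12)

  set.seed(41)
  for (i in 1:25) {
    mn <- round(rexp(sample(3:12, 1)), 1)  # rounding forces ties
    ma <- round(rexp(sample(3:12, 1)) + 0.3, 1)
    expect_equal(roc_curve(mn, ma)$auc, pair_auc(mn, ma), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:10) {
    mn <- rexp(30)
    ma <- rexp(25) + 0.5
    ours <- roc_curve(mn, ma)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = rep(c(0, 1), c(30, 25)), predictor = c(mn, ma),
      quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("swapping groups maps AUC to 1 - AUC; shifts move only the threshold", {
  set.seed(43)
  mn <- rnorm(40)
  ma <- rnorm(30, mean = 1)
  r <- roc_curve(mn, ma)
  expect_equal(roc_curve(ma, mn)$auc, 1 - r$auc, tolerance = 1e-12)

  r_shift <- roc_curve(mn + 10, ma + 10)
  expect_equal(r_shift$auc, r$auc, tolerance = 1e-12)
  expect_equal(r_shift$youden_threshold, r$youden_threshold + 10,
               tolerance = 1e-9)
  expect_equal(r_shift$se_at_youden, r$se_at_youden)
  expect_equal(r_shift$sp_at_youden, r$sp_at_youden)
})

test_that("classification is strict and consistent with the ROC operating point", {
  expect_identical(as.character(classify_md(c(1, 2, 3), 2)),
                   c("normal", "normal", "abnormal"))  # boundary is normal
  expect_true(all(classify_md(c(0.1, 0.5), 1) == "normal"))
  expect_error(classify_md(1, Inf), "finite")

  set.seed(44)
  mn <- rexp(50); ma <- rexp(40) + 1
  r <- roc_curve(mn, ma)
  pred <- classify_md(c(mn, ma), r$youden_threshold)
  truth <- rep(c("normal", "abnormal"), c(50, 40))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$sensitivity, r$se_at_youden, tolerance = 1e-12)
  expect_equal(m$specificity, r$sp_at_youden, tolerance = 1e-12)
})

test_that("confusion counts match a brute-force tally and the identities", {
  set.seed(45)
  truth <- sample(c("normal", "abnormal"), 60, replace = TRUE)
  pred <- sample(c("normal", "abnormal"), 60, replace = TRUE)
  m <- confusion_metrics(pred, truth)
  tp <- sum(pred == "abnormal" & truth == "abnormal")
  fn <- sum(pred == "normal" & truth == "abnormal")
  expect_equal(m$tp, tp)
  expect_equal(m$sensitivity, tp / (tp + fn))
  expect_equal(m$tp + m$fn, m$n_abnormal)
  expect_equal(m$tn + m$fp, m$n_normal)

  all_normal <- confusion_metrics(rep("normal", 60), truth)
  expect_equal(all_normal$sensitivity, 0)
  expect_equal(all_normal$tn, all_normal$n_normal)
  expect_error(confusion_metrics(pred, rep("normal", 60)), "both classes")

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
})

test_that("cross-validation is deterministic and perfect on separable data", {
  prof <- recovery_profile(shift = 8, n_normal = 80, n_abnormal = 80)
  pop <- generate_population(prof, seed = 46)
  cfg <- mts_config(cv_folds = 2, seed = 9)
  cv1 <- kfold_evaluate(pop$normal, pop$abnormal, config = cfg)
  cv2 <- kfold_evaluate(pop$normal, pop$abnormal, config = cfg)
  expect_identical(cv1$fold_normal, cv2$fold_normal)
  expect_equal(cv1$folds, cv2$folds)
  expect_equal(cv1$folds$sensitivity, c(1, 1))
  expect_equal(cv1$folds$specificity, c(1, 1))
  # stratified near-equal fold sizes
  expect_true(all(abs(cv1$folds$n_test_normal - 40) <= 1))
})
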