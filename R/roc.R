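#' ROC curve over Mahalanobis distances and the Youden-optimal threshold
#'
#' Builds the full ROC curve for the rule "call abnormal when MD > t".
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' pooled scores plus one sentinel below the minimum and one above the
#' maximum, so every achievable operating point appears exactly once. The AUC
#' is computed two ways — the trapezoidal rule over (FPR, TPR) and the
#' Mann-Whitney rank statistic U / (n1 * n2) with ties counted half — and the
#' two must agree; the trapezoidal value is reported. The diagnostic threshold
#' is the one maximizing the Youden index J = sensitivity + specificity - 1;
#' ties are broken toward the smallest threshold (favoring sensitivity).
#'
#' @param md_normal distances of the healthy group.
#' @param md_abnormal distances of the disease group.
#' @return An object of class `"mts_roc"`: list with `thresholds` (descending),
#'   `tpr`, `fpr`, `auc`, `youden_threshold`, `se_at_youden`, `sp_at_youden`,
#'   `j_max`, `degenerate` (TRUE when all pooled scores are identical, in which
#'   case `auc = 0.5` and the threshold is `NA`).
#' @examples
#' r <- roc_curve(c(0.1, 0.2), c(5, 6))
#' r$auc  # 1
#' @export
roc_curve <- function(md_normal, md_abnormal) {
  if (length(md_normal) == 0 || length(md_abnormal) == 0) {
    stop("both score vectors must be non-empty")
  }
  pooled <- sort(unique(c(md_normal, md_abnormal)))
  if (length(pooled) == 1L) {
    return(structure(list(thresholds = pooled + 1, tpr = 0, fpr = 0,
                          auc = 0.5, youden_threshold = NA_real_,
                          se_at_youden = NA_real_, sp_at_youden = NA_real_,
                          j_max = 0, degenerate = TRUE),
                     class = "mts_roc"))
  }
  mids <- (pooled[-1] + pooled[-length(pooled)]) / 2
  thresholds <- sort(c(pooled[1] - 1, mids, pooled[length(pooled)] + 1),
                     decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(md_abnormal > t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(md_normal > t), numeric(1))

  auc_trap <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  n1 <- length(md_abnormal); n2 <- length(md_normal)
  r <- rank(c(md_abnormal, md_normal))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc_rank <- u / (n1 * n2)
  if (abs(auc_trap - auc_rank) > 1e-9) {
    warning(sprintf("trapezoidal and rank AUC disagree (%.12f vs %.12f)",
                    auc_trap, auc_rank))
  }

  j <- tpr - fpr
  best <- which(j > max(j) - 1e-12)
  pick <- best[which.min(thresholds[best])]
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auc = auc_trap,
                 youden_threshold = thresholds[pick],
                 se_at_youden = tpr[pick],
                 sp_at_youden = 1 - fpr[pick],
                 j_max = j[pick],
                 degenerate = FALSE),
            class = "mts_roc")
}

#' @export
print.mts_roc <- function(x, ...) {
  if (x$degenerate) {
    cat("ROC: degenerate (all scores identical), AUC 0.5, threshold undefined\n")
    return(invisible(x))
  }
  cat(sprintf("ROC: AUC = %.4f\n", x$auc))
  cat(sprintf("Youden threshold = %.4f (Se %.3f, Sp %.3f, J %.3f)\n",
              x$youden_threshold, x$se_at_youden, x$sp_at_youden, x$j_max))
  invisible(x)
}

#' @export
plot.mts_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  if (!x$degenerate) {
    i <- which(x$thresholds == x$youden_threshold)[1]
    graphics::points(x$fpr[i], x$tpr[i], pch = 19, col = "firebrick")
  }
  invisible(x)
}

#' Classify subjects by Mahalanobis distance
#'
#' Strict decision rule: a subject is called `"abnormal"` when its distance
#' exceeds the threshold, `"normal"` otherwise (a score exactly at the
#' threshold is normal).
#'
#' @param md numeric vector of distances.
#' @param threshold finite decision threshold.
#' @return Factor with levels `c("normal", "abnormal")`.
#' @export
classify_md <- function(md, threshold) {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  factor(ifelse(md > threshold, "abnormal", "normal"),
         levels = c("normal", "abnormal"))
}

#' Sensitivity, specificity and confusion counts
#'
#' @param predicted factor/character vector of `"normal"`/`"abnormal"` calls.
#' @param truth same-length vector of true labels; both classes must occur.
#' @return An object of class `"mts_metrics"`: `sensitivity` (TP/(TP+FN)),
#'   `specificity` (TN/(TN+FP)), counts `tp`, `fn`, `tn`, `fp`, `n_normal`,
#'   `n_abnormal`.
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  bad <- setdiff(unique(c(predicted, truth)), c("normal", "abnormal"))
  if (length(bad) > 0) stop("labels must be 'normal'/'abnormal'; got: ",
                            paste(bad, collapse = ", "))
  if (!all(c("normal", "abnormal") %in% truth)) {
    stop("truth must contain both classes; a single-class truth leaves a metric undefined")
  }
  tp <- sum(predicted == "abnormal" & truth == "abnormal")
  fn <- sum(predicted == "normal" & truth == "abnormal")
  tn <- sum(predicted == "normal" & truth == "normal")
  fp <- sum(predicted == "abnormal" & truth == "normal")
  structure(list(sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 tp = tp, fn = fn, tn = tn, fp = fp,
                 n_normal = tn + fp, n_abnormal = tp + fn),
            class = "mts_metrics")
}

#' @export
print.mts_metrics <- function(x, ...) {
  cat(sprintf("Se = %.4f (%d/%d)   Sp = %.4f (%d/%d)\n",
              x$sensitivity, x$tp, x$n_abnormal,
              x$specificity, x$tn, x$n_normal))
  invisible(x)
}

#' Stratified k-fold cross-validated evaluation of the full pipeline
#'
#' The healthy and disease groups are each partitioned into `cv_folds`
#' near-equal folds with the seeded RNG (stratification keeps group
#' proportions stable, mirroring group-wise train/test counts). For each fold
#' the entire pipeline — correlation pruning, reference-space refinement,
#' orthogonal-array variable selection, refit, Youden threshold — is fit on
#' the training portion only and evaluated on the held-out subjects. A fold
#' whose training portion is too small to estimate the space is skipped with a
#' warning.
#'
#' @param normal,abnormal complete [feature_table()]s.
#' @param config an [mts_config()]; `cv_folds` and `seed` are taken from it.
#' @return An object of class `"mts_cv"`: list with `folds` (data frame: fold,
#'   test group sizes, n_selected, threshold, auc_train, sensitivity,
#'   specificity), `mean_sensitivity`, `mean_specificity`, `fold_normal`,
#'   `fold_abnormal` (the fold assignments).
#' @export
kfold_evaluate <- function(normal, abnormal, config = mts_config()) {
  normal <- as_feature_table(normal)
  abnormal <- as_feature_table(abnormal)
  k <- config$cv_folds
  if (nrow(normal$values) <= k || nrow(abnormal$values) <= k) {
    stop("each group must be larger than the number of folds")
  }
  set.seed(config$seed)
  f_n <- sample(rep_len(seq_len(k), nrow(normal$values)))
  f_a <- sample(rep_len(seq_len(k), nrow(abnormal$values)))

  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    train_n <- ft_rows(normal, which(f_n != fold))
    train_a <- ft_rows(abnormal, which(f_a != fold))
    test_n <- ft_rows(normal, which(f_n == fold))
    test_a <- ft_rows(abnormal, which(f_a == fold))
    res <- tryCatch({
      fit <- mts(train_n, train_a,
                 config = mts_config(
                   correlation_threshold = config$correlation_threshold,
                   refine_passes = config$refine_passes,
                   cv_folds = config$cv_folds,
                   seed = config$seed,
                   keep_policy = config$keep_policy,
                   md_scaled = config$md_scaled),
                 cv = FALSE)
      pred <- c(as.character(predict(fit, test_n, type = "class")),
                as.character(predict(fit, test_a, type = "class")))
      truth <- c(rep("normal", nrow(test_n$values)),
                 rep("abnormal", nrow(test_a$values)))
      m <- confusion_metrics(pred, truth)
      data.frame(fold = fold,
                 n_test_normal = nrow(test_n$values),
                 n_test_abnormal = nrow(test_a$values),
                 n_selected = length(fit$selected),
                 threshold = fit$roc$youden_threshold,
                 auc_train = fit$roc$auc,
                 sensitivity = m$sensitivity,
                 specificity = m$specificity)
    }, error = function(e) {
      warning(sprintf("fold %d skipped: %s", fold, conditionMessage(e)))
      data.frame(fold = fold,
                 n_test_normal = nrow(test_n$values),
                 n_test_abnormal = nrow(test_a$values),
                 n_selected = NA_integer_, threshold = NA_real_,
                 auc_train = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_)
    })
    rows[[fold]] <- res
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean_sensitivity = mean(folds$sensitivity, na.rm = TRUE),
                 mean_specificity = mean(folds$specificity, na.rm = TRUE),
                 fold_normal = f_n, fold_abnormal = f_a),
            class = "mts_cv")
}

#' @export
print.mts_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", nrow(x$folds)))
  print(x$folds, row.names = FALSE, digits = 4)
  cat(sprintf("Mean Se = %.4f   Mean Sp = %.4f\n",
              x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}
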