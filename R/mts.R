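#' Fit a Mahalanobis-Taguchi diagnostic system
#'
#' Runs the full MTS workflow on a healthy ("normal") and a disease
#' ("abnormal") biomarker table:
#'
#' 1. complete-case filtering of both groups ([drop_incomplete_rows()]);
#' 2. Pearson redundancy pruning fit on the healthy group and applied to both
#'    ([pearson_prune()]);
#' 3. reference-space construction from the healthy group with
#'    individuals/moving-range outlier screening ([refine_space()]);
#' 4. orthogonal-array screening of the pruned variables with
#'    larger-the-better SN ratios ([run_oa_experiment()]), keeping the
#'    positive-gain variables ([select_variables()]); if no gain is positive,
#'    all pruned variables are kept with a prominent warning;
#' 5. refit of the reference space on the selected variables;
#' 6. ROC over the training distances and the Youden-optimal diagnostic
#'    threshold ([roc_curve()]);
#' 7. optionally, stratified k-fold cross-validated sensitivity/specificity
#'    ([kfold_evaluate()]).
#'
#' The training ROC scores all complete healthy rows (not only the refinement
#' survivors) against the final space, so the reported specificity refers to
#' the whole healthy training group while the space itself is estimated from
#' the screened subset.
#'
#' @param normal healthy-group [feature_table()] (or matrix/data frame).
#' @param abnormal disease-group [feature_table()] (or matrix/data frame).
#' @param config an [mts_config()].
#' @param cv run cross-validated evaluation as well (uses `config$cv_folds`
#'   and `config$seed`).
#' @return An object of class `"mts"` with components `prune_report`,
#'   `refinement`, `sn_table`, `selected` (character), `selection_fallback`
#'   (logical), `space` (the final `mahalanobis_space`), `roc` (`mts_roc`),
#'   `cv` (`mts_cv` or `NULL`), `md_normal`, `md_abnormal`, `counts` (row
#'   ledger), `config`, `call`. Methods: [print.mts()], [summary.mts()],
#'   [coef.mts()] (SN-ratio gains), [predict.mts()], [plot.mts()].
#' @examples
#' \donttest{
#' pop <- generate_population(default_blood_profile(n_normal = 300,
#'                                                  n_abnormal = 120))
#' fit <- mts(pop$normal, pop$abnormal)
#' fit
#' }
#' @export
mts <- function(normal, abnormal, config = mts_config(), cv = FALSE) {
  stopifnot(inherits(config, "mts_config"))
  cl <- match.call()
  normal <- as_feature_table(normal, group = "normal")
  abnormal <- as_feature_table(abnormal, group = "abnormal")
  if (nrow(normal$values) == 0 || nrow(abnormal$values) == 0) {
    stop("both groups must be non-empty")
  }

  dn <- drop_incomplete_rows(normal)
  da <- drop_incomplete_rows(abnormal)
  pr <- pearson_prune(dn$table, threshold = config$correlation_threshold,
                      keep_policy = config$keep_policy)
  vars <- variables(pr$table)
  abnormal_p <- ft_vars(da$table, vars)

  rf <- refine_space(pr$table, vars, max_passes = max(1L, config$refine_passes))
  survivors <- ft_rows(pr$table,
                       setdiff(seq_len(nrow(pr$table$values)),
                               rf$refinement$removed))

  sn <- run_oa_experiment(survivors, abnormal_p, variables = vars)
  selected <- withCallingHandlers(
    select_variables(sn),
    warning = function(w) invokeRestart("muffleWarning"))
  fallback <- length(selected) == 0
  if (fallback) {
    warning("no variable had positive gain; falling back to all pruned variables")
    selected <- vars
  }

  space <- fit_space(survivors, selected)
  md_n <- compute_md(space, pr$table, scaled = config$md_scaled)
  md_a <- compute_md(space, abnormal_p, scaled = config$md_scaled)
  roc <- roc_curve(md_n, md_a)
  if (!roc$degenerate && roc$auc < 0.6) {
    warning(sprintf("training AUC is only %.3f; the groups are barely separable",
                    roc$auc))
  }

  cv_res <- NULL
  if (isTRUE(cv)) cv_res <- kfold_evaluate(dn$table, da$table, config = config)

  counts <- list(normal_in = nrow(normal$values),
                 abnormal_in = nrow(abnormal$values),
                 normal_removed_missing = dn$removed,
                 abnormal_removed_missing = da$removed,
                 normal_removed_refinement = length(rf$refinement$removed),
                 normal_construction = rf$refinement$n_final,
                 variables_in = ncol(normal$values),
                 variables_pruned = length(pr$report$dropped),
                 variables_selected = length(selected))

  structure(list(prune_report = pr$report,
                 refinement = rf$refinement,
                 sn_table = sn,
                 selected = selected,
                 selection_fallback = fallback,
                 space = space,
                 roc = roc,
                 cv = cv_res,
                 md_normal = md_n,
                 md_abnormal = md_a,
                 counts = counts,
                 config = config,
                 call = cl),
            class = "mts")
}

#' @export
print.mts <- function(x, ...) {
  cat("Mahalanobis-Taguchi diagnostic system\n\n")
  cat(sprintf("  %d healthy / %d disease subjects in; %d / %d incomplete removed\n",
              x$counts$normal_in, x$counts$abnormal_in,
              x$counts$normal_removed_missing, x$counts$abnormal_removed_missing))
  cat(sprintf("  variables: %d in -> %d after pruning -> %d selected%s\n",
              x$counts$variables_in,
              x$counts$variables_in - x$counts$variables_pruned,
              x$counts$variables_selected,
              if (x$selection_fallback) " (FALLBACK: no positive gain)" else ""))
  cat(sprintf("  reference space: %d of %d healthy rows after outlier screen (T = %.3f)\n",
              x$counts$normal_construction,
              x$counts$normal_construction + x$counts$normal_removed_refinement,
              x$refinement$threshold_T))
  cat(sprintf("  selected: %s\n", paste(x$selected, collapse = ", ")))
  if (x$roc$degenerate) {
    cat("  ROC degenerate: all distances identical\n")
  } else {
    cat(sprintf("  AUC = %.4f; threshold = %.4f (Se %.3f, Sp %.3f)\n",
                x$roc$auc, x$roc$youden_threshold,
                x$roc$se_at_youden, x$roc$sp_at_youden))
  }
  if (!is.null(x$cv)) {
    cat(sprintf("  %d-fold CV: mean Se %.4f, mean Sp %.4f\n",
                nrow(x$cv$folds), x$cv$mean_sensitivity, x$cv$mean_specificity))
  }
  invisible(x)
}

#' Summary of a fitted MTS
#' @param object an [mts()] fit.
#' @param ... unused.
#' @export
summary.mts <- function(object, ...) {
  print(object)
  cat("\nSN-ratio gains (dB):\n")
  print(round(sort(object$sn_table$gain, decreasing = TRUE), 3))
  cat("\nPruning:\n")
  print(object$prune_report)
  if (!is.null(object$cv)) {
    cat("\n")
    print(object$cv)
  }
  invisible(object)
}

#' SN-ratio gains of a fitted MTS
#'
#' The per-variable gains (level-1 minus level-2 mean SN ratio, dB) are the
#' model's variable-importance coefficients: positive gain means the variable
#' was selected.
#'
#' @param object an [mts()] fit.
#' @param ... unused.
#' @return Named numeric vector of gains, in pruned-variable order.
#' @export
coef.mts <- function(object, ...) object$sn_table$gain

#' Score or classify new subjects with a fitted MTS
#'
#' @param object an [mts()] fit.
#' @param newdata [feature_table()], matrix or data frame containing the
#'   selected variables.
#' @param type `"md"` for scaled Mahalanobis distances, `"class"` for
#'   normal/abnormal calls at the fitted Youden threshold.
#' @param ... unused.
#' @return Numeric vector of distances or a factor of calls.
#' @export
predict.mts <- function(object, newdata, type = c("md", "class"), ...) {
  type <- match.arg(type)
  md <- compute_md(object$space, as_feature_table(newdata),
                   scaled = object$config$md_scaled)
  if (type == "md") return(md)
  if (object$roc$degenerate) stop("threshold undefined: training ROC was degenerate")
  classify_md(md, object$roc$youden_threshold)
}

#' Plot a fitted MTS
#'
#' `which = "roc"` draws the training ROC curve with the Youden point;
#' `which = "md"` strip-plots the training distances of both groups on a log
#' scale with the diagnostic threshold.
#'
#' @param x an [mts()] fit.
#' @param which `"roc"` or `"md"`.
#' @param ... passed to the underlying plot.
#' @export
plot.mts <- function(x, which = c("roc", "md"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc, ...)
  } else {
    md <- c(x$md_normal, x$md_abnormal)
    grp <- rep(c(1, 2), c(length(x$md_normal), length(x$md_abnormal)))
    graphics::plot(jitter(grp, 0.3), md, log = "y", xaxt = "n", pch = 16,
                   cex = 0.4, col = c("steelblue", "firebrick")[grp],
                   xlab = "", ylab = "Scaled Mahalanobis distance",
                   xlim = c(0.5, 2.5), ...)
    graphics::axis(1, at = c(1, 2), labels = c("healthy", "disease"))
    if (!x$roc$degenerate) {
      graphics::abline(h = x$roc$youden_threshold, lty = 2)
    }
  }
  invisible(x)
}

#' Write / read a structured JSON run report
#'
#' Serializes the full pipeline result — pruned pairs with their correlations,
#' refinement summary, per-run SN ratios and gains, selected variables,
#' diagnostic threshold, training Se/Sp/AUC and (when present) per-fold CV
#' metrics — as a JSON document. `read_report()` restores the same field
#' values (plain lists, not the fitted object).
#'
#' @param fit an [mts()] fit.
#' @param path output path.
#' @return `write_report()` returns `path` invisibly; `read_report()` a named
#'   list.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "mts"))
  rep <- list(
    pruning = list(threshold = fit$prune_report$threshold,
                   pairs = fit$prune_report$pairs,
                   reserved = as.list(fit$prune_report$reserved),
                   dropped = fit$prune_report$dropped,
                   zero_variance = fit$prune_report$zero_variance),
    refinement = list(n_removed = length(fit$refinement$removed),
                      removed = fit$refinement$removed,
                      threshold_T = fit$refinement$threshold_T,
                      md_mean_mu = fit$refinement$md_mean_mu,
                      mean_moving_range_Rbar = fit$refinement$mean_moving_range_Rbar,
                      passes = fit$refinement$passes),
    sn = list(run_sn = fit$sn_table$run_sn,
              variables = names(fit$sn_table$gain),
              level1_mean = unname(fit$sn_table$level1_mean),
              level2_mean = unname(fit$sn_table$level2_mean),
              gain = unname(fit$sn_table$gain)),
    selected = fit$selected,
    selection_fallback = fit$selection_fallback,
    threshold = fit$roc$youden_threshold,
    auc = fit$roc$auc,
    se_train = fit$roc$se_at_youden,
    sp_train = fit$roc$sp_at_youden,
    counts = fit$counts,
    cv = if (!is.null(fit$cv)) {
      list(folds = fit$cv$folds,
           mean_sensitivity = fit$cv$mean_sensitivity,
           mean_specificity = fit$cv$mean_specificity)
    },
    external_classifiers = list()  # extension slot for benchmark metrics
  )
  ok <- try(jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                                 null = "null", dataframe = "rows"),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write report to ", path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
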