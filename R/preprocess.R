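#' Remove subjects with any missing measurement
#'
#' Complete-case filtering: every row containing at least one `NA` cell is
#' dropped. Listwise deletion is appropriate here because the reference-space
#' mathematics (correlation matrix, its inverse) requires complete rows and
#' the missingness pattern targeted is sparse and completely at random.
#'
#' @param ft a [feature_table()] (or coercible).
#' @return A list with `table` (the complete-case `feature_table`, row order
#'   preserved) and `removed` (number of rows deleted).
#' @examples
#' ft <- feature_table(cbind(A = c(1, NA, 3), B = c(4, 5, 6)))
#' drop_incomplete_rows(ft)$removed
#' @export
drop_incomplete_rows <- function(ft) {
  ft <- as_feature_table(ft)
  keep <- stats::complete.cases(ft$values)
  if (!any(keep)) stop("degenerate input: every row has a missing value")
  list(table = ft_rows(ft, which(keep)), removed = sum(!keep))
}

#' Default keep-list for pruning routine blood variables
#'
#' The ordered list of complete-blood-count variables preferred as the kept
#' member of a highly correlated pair: basophil count (BA#), eosinophil count
#' (EO#), lymphocyte ratio and count (LY, LY#), mean corpuscular hemoglobin
#' and its concentration (MCH, MCHC), monocyte ratio and count (MO, MO#),
#' mean platelet volume (MPV), platelet distribution width (PDW), platelet
#' count (PLT), red blood cell count (RBC), red cell distribution width (RDW)
#' and white blood cell count (WBC) — the 14-variable panel the reference
#' asthma workflow retains after pruning a 22-variable blood count.
#'
#' @return Character vector of 14 variable names.
#' @export
default_keep_list <- function() {
  c("BA#", "EO#", "LY", "LY#", "MCH", "MCHC", "MO", "MO#",
    "MPV", "PDW", "PLT", "RBC", "RDW", "WBC")
}

#' Prune highly correlated variables
#'
#' Computes the Pearson correlation matrix of the (complete) table and, for
#' every variable pair with |r| strictly above `threshold`, drops one member.
#' Flagged pairs are processed greedily in order of descending |r|; within a
#' pair the kept variable is the one appearing earlier in `keep_policy`,
#' falling back to the lower column index when neither (or both at equal rank)
#' is listed. Zero-variance variables make Pearson r undefined; they are
#' dropped with a warning and reported separately. Fit the pruning on the
#' healthy group only, then subset other groups to `variables(result$table)`.
#'
#' @param ft complete [feature_table()] with at least 3 subjects.
#' @param threshold prune when |r| > `threshold`; a fraction in (0, 1).
#' @param keep_policy ordered character vector of preferred survivors.
#' @return A list with `table` (pruned `feature_table`) and `report`, an object
#'   of class `"prune_report"` with components `pairs` (data frame of
#'   `var_a`, `var_b`, `r` for every flagged pair), `reserved` (named character
#'   vector: kept variable per acted-on pair `"A|B"`), `dropped` and
#'   `zero_variance` (character vectors).
#' @export
pearson_prune <- function(ft, threshold = 0.80, keep_policy = character()) {
  ft <- as_feature_table(ft)
  if (anyNA(ft$values)) stop("table contains missing values; run drop_incomplete_rows() first")
  if (nrow(ft$values) < 3) stop("Pearson correlation needs at least 3 subjects")
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")

  vn <- colnames(ft$values)
  sds <- apply(ft$values, 2L, stats::sd)
  zero_var <- vn[sds == 0]
  if (length(zero_var) > 0) {
    warning("zero-variance variable(s) dropped (correlation undefined): ",
            paste(zero_var, collapse = ", "))
  }
  live <- setdiff(vn, zero_var)
  cm <- stats::cor(ft$values[, live, drop = FALSE])

  flagged <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  pairs <- data.frame(var_a = live[flagged[, 1L]],
                      var_b = live[flagged[, 2L]],
                      r = cm[flagged],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(-abs(pairs$r), pairs$var_a, pairs$var_b), , drop = FALSE]
  rownames(pairs) <- NULL

  rank_of <- function(v) {
    i <- match(v, keep_policy)
    if (is.na(i)) Inf else i
  }
  kept <- live
  reserved <- character(0)
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$var_a[[i]]; b <- pairs$var_b[[i]]
      if (!(a %in% kept) || !(b %in% kept)) next
      ra <- rank_of(a); rb <- rank_of(b)
      keep_a <- if (ra != rb) ra < rb else match(a, vn) < match(b, vn)
      winner <- if (keep_a) a else b
      loser <- if (keep_a) b else a
      kept <- setdiff(kept, loser)
      reserved[paste(a, b, sep = "|")] <- winner
    }
  }
  dropped <- c(zero_var, setdiff(live, kept))
  report <- structure(list(pairs = pairs, reserved = reserved,
                           dropped = dropped, zero_variance = zero_var,
                           threshold = threshold),
                      class = "prune_report")
  list(table = ft_vars(ft, kept), report = report)
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("Correlation pruning at |r| > %.2f\n", x$threshold))
  if (nrow(x$pairs) == 0) {
    cat("  no variable pair exceeded the threshold\n")
  } else {
    for (i in seq_len(nrow(x$pairs))) {
      key <- paste(x$pairs$var_a[[i]], x$pairs$var_b[[i]], sep = "|")
      kept <- if (key %in% names(x$reserved)) x$reserved[[key]] else "(already resolved)"
      cat(sprintf("  %s ~ %s  r = %+.3f  kept: %s\n",
                  x$pairs$var_a[[i]], x$pairs$var_b[[i]], x$pairs$r[[i]], kept))
    }
  }
  if (length(x$zero_variance) > 0) {
    cat("  zero-variance dropped:", paste(x$zero_variance, collapse = ", "), "\n")
  }
  cat("  dropped:", if (length(x$dropped)) paste(x$dropped, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
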