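# number of set bits in a non-negative integer (vectorized)
popcount <- function(x) {
  out <- integer(length(x))
  while (any(x > 0)) {
    out <- out + (x %% 2L)
    x <- x %/% 2L
  }
  out
}

#' Generate a two-level orthogonal array
#'
#' Builds a two-level orthogonal array large enough for `n_factors` factors:
#' the number of runs is the smallest power of two strictly greater than
#' `n_factors`, giving `n_runs - 1` usable columns. Column `c` (1-based) of row
#' `r` (rows indexed 0 ... n_runs - 1) is `1 + parity(popcount(r AND c))` —
#' the Hadamard/Walsh construction, whose columns are pairwise orthogonal and
#' balanced: every column has equal counts of levels 1 and 2 and every column
#' pair shows each of the four level combinations exactly `n_runs / 4` times.
#'
#' The canonical Taguchi tables (L8, L16, ...) order columns differently, but
#' level means and gains depend only on balance, not on column order.
#'
#' @param n_factors number of two-level factors to accommodate (>= 1).
#' @return An object of class `"orthogonal_array"`: list with `levels`
#'   (`n_runs` x `n_columns` matrix of 1/2), `n_runs`, `n_columns`.
#' @examples
#' generate_oa(15)$n_runs  # 16
#' @export
generate_oa <- function(n_factors) {
  n_factors <- as.integer(n_factors)
  if (is.na(n_factors) || n_factors < 1) stop("'n_factors' must be >= 1")
  n_runs <- 2L^as.integer(ceiling(log2(n_factors + 1L)))
  if (n_runs <= n_factors) n_runs <- n_runs * 2L  # guard exact powers of two
  cols <- seq_len(n_runs - 1L)
  rows <- 0:(n_runs - 1L)
  levels <- outer(rows, cols, function(r, c) 1L + popcount(bitwAnd(r, c)) %% 2L)
  structure(list(levels = levels, n_runs = n_runs, n_columns = n_runs - 1L),
            class = "orthogonal_array")
}

#' @export
print.orthogonal_array <- function(x, ...) {
  cat(sprintf("Two-level orthogonal array: %d runs x %d columns\n",
              x$n_runs, x$n_columns))
  invisible(x)
}

#' Larger-the-better signal-to-noise ratio
#'
#' Taguchi's larger-the-better SN ratio, in decibels:
#' `-10 * log10(mean(1 / md^2))` is the classical form for a response y; for
#' Mahalanobis distances the MTS convention applies it to the distances
#' themselves, SN = -10 log10( (1/n) sum 1/md_i ). Higher values mean the
#' abnormal group sits uniformly farther from the healthy space.
#'
#' @param md vector of strictly positive distances of the abnormal group.
#' @return SN ratio in dB.
#' @examples
#' sn_larger_better(c(10, 10))  # 10 dB
#' @export
sn_larger_better <- function(md) {
  if (length(md) == 0) stop("empty distance vector")
  if (any(!is.finite(md)) || any(md <= 0)) {
    stop("all distances must be positive and finite for the larger-the-better SN ratio")
  }
  -10 * log10(mean(1 / md))
}

#' Level means and gains from per-run SN ratios
#'
#' Pure arithmetic on a completed orthogonal-array experiment: for each
#' variable (assigned to one OA column), the level-1 mean is the average SN
#' ratio over runs where the variable was included, the level-2 mean over runs
#' where it was excluded, and the gain is their difference. A positive gain
#' means including the variable improves abnormal/normal separation.
#'
#' @param run_sn numeric vector of SN ratios, one per OA run.
#' @param oa an [generate_oa()] array (or any object with a `levels` matrix
#'   of 1/2).
#' @param variables character vector of variable names assigned, in order, to
#'   the first `length(variables)` OA columns.
#' @return An object of class `"sn_table"`: list with `run_sn`, `assignment`
#'   (named column indices), `level1_mean`, `level2_mean`, `gain` (named
#'   vectors), `grand_mean`.
#' @export
compute_gains <- function(run_sn, oa, variables) {
  lv <- oa$levels
  if (length(run_sn) != nrow(lv)) {
    stop(sprintf("length(run_sn) = %d but the array has %d runs",
                 length(run_sn), nrow(lv)))
  }
  if (length(variables) > ncol(lv)) {
    stop("more variables than array columns")
  }
  assignment <- stats::setNames(seq_along(variables), variables)
  l1 <- vapply(assignment, function(j) mean(run_sn[lv[, j] == 1L]), numeric(1))
  l2 <- vapply(assignment, function(j) mean(run_sn[lv[, j] == 2L]), numeric(1))
  structure(list(run_sn = run_sn,
                 assignment = assignment,
                 level1_mean = l1,
                 level2_mean = l2,
                 gain = l1 - l2,
                 grand_mean = mean(run_sn)),
            class = "sn_table")
}

#' @export
print.sn_table <- function(x, digits = 2, ...) {
  cat(sprintf("Orthogonal-array SN experiment: %d runs, %d variables\n",
              length(x$run_sn), length(x$gain)))
  tab <- rbind(`SN level-1 mean` = x$level1_mean,
               `SN level-2 mean` = x$level2_mean,
               Gain = x$gain)
  print(round(tab, digits))
  invisible(x)
}

#' Run the orthogonal-array variable-screening experiment
#'
#' Assigns the candidate variables to the first columns of a two-level
#' orthogonal array. Each run defines an included subset (the variables at
#' level 1 in that row); the Mahalanobis space is refit on the healthy data
#' restricted to that subset, the abnormal subjects are scored, and the run's
#' larger-the-better SN ratio is recorded. Level means and gains then follow
#' from [compute_gains()].
#'
#' @param normal healthy [feature_table()] (typically the refinement
#'   survivors), complete on `variables`.
#' @param abnormal disease-group [feature_table()], complete on `variables`.
#' @param oa an orthogonal array with at least `length(variables)` columns;
#'   default generates one of the right size.
#' @param variables variables to screen; default all columns of `normal`.
#' @param cond_bound passed to [fit_space()].
#' @return An `"sn_table"` (see [compute_gains()]).
#' @export
run_oa_experiment <- function(normal, abnormal, oa = NULL, variables = NULL,
                              cond_bound = 1e10) {
  normal <- as_feature_table(normal)
  abnormal <- as_feature_table(abnormal)
  if (is.null(variables)) variables <- colnames(normal$values)
  if (is.null(oa)) oa <- generate_oa(length(variables))
  if (length(variables) > oa$n_columns) {
    stop("array has fewer columns than variables")
  }
  run_sn <- vapply(seq_len(oa$n_runs), function(run) {
    include <- variables[oa$levels[run, seq_along(variables)] == 1L]
    if (length(include) == 0) {
      stop(sprintf("run %d includes no variable; cannot score an empty subset", run))
    }
    sp <- fit_space(normal, include, cond_bound = cond_bound)
    sn_larger_better(compute_md(sp, abnormal))
  }, numeric(1))
  compute_gains(run_sn, oa, variables)
}

#' Select variables with positive gain
#'
#' Returns the variables whose SN-ratio gain is strictly positive, ordered by
#' descending gain — the subset that improves separation of the abnormal group
#' from the healthy reference space. Zero gain is not selected.
#'
#' @param sn_table an [compute_gains()] result.
#' @return Character vector of selected variable names (possibly empty, with a
#'   warning).
#' @export
select_variables <- function(sn_table) {
  stopifnot(inherits(sn_table, "sn_table"))
  g <- sn_table$gain
  sel <- names(g)[g > 0]
  if (length(sel) == 0) {
    warning("no variable has positive gain; selection is empty")
    return(character(0))
  }
  sel[order(-g[sel])]
}

#' Packaged worked example: a published 16-run screening experiment
#'
#' A complete, published orthogonal-array experiment from a clinical study of
#' asthma diagnosis from routine blood counts: the 16-run two-level design
#' over 14 blood variables together with the 16 per-run SN ratios obtained on
#' the study's (non-public) hospital data. It exercises [compute_gains()] and
#' [select_variables()] end to end — the study's gains (PDW 5.11, MPV 0.70,
#' ...) and its 7-variable selection are reproduced exactly from this fixture.
#' The per-run SN ratios cannot be recomputed without the clinical data, so
#' they are shipped as printed (2 decimals).
#'
#' @return List with `oa` (an `orthogonal_array`, 16 x 14), `variables`
#'   (14 names) and `run_sn` (16 SN ratios, dB).
#' @examples
#' ex <- blood_oa_example()
#' sn <- compute_gains(ex$run_sn, ex$oa, ex$variables)
#' round(sn$gain[["PDW"]], 2)  # 5.11
#' @export
blood_oa_example <- function() {
  path <- system.file("extdata", "oa16_blood_sn.tsv", package = "mtsdx",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, check.names = FALSE)
  vars <- setdiff(colnames(tab), c("run", "sn_ratio"))
  levels <- as.matrix(tab[, vars])
  storage.mode(levels) <- "integer"
  dimnames(levels) <- NULL
  oa <- structure(list(levels = levels, n_runs = nrow(levels),
                       n_columns = ncol(levels)),
                  class = "orthogonal_array")
  list(oa = oa, variables = vars, run_sn = tab$sn_ratio)
}
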