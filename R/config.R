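#' Run configuration for the MTS pipeline
#'
#' Bundles the tunable parameters of the diagnosis pipeline. Defaults follow
#' the method's reference workflow: redundancy pruning at |r| > 0.80, a single
#' control-chart refinement pass, 10-fold cross-validation, and the scaled
#' Mahalanobis distance (divided by the number of variables, so the healthy
#' average is close to 1).
#'
#' @param correlation_threshold prune one member of every variable pair whose
#'   absolute Pearson correlation exceeds this fraction; in (0, 1].
#' @param refine_passes maximum number of outlier-removal passes when refining
#'   the reference space; 1 reproduces the single-screen workflow, larger
#'   values iterate to convergence.
#' @param cv_folds number of folds for cross-validated evaluation (>= 2).
#' @param seed integer RNG seed controlling every stochastic step.
#' @param keep_policy ordered character vector of variable names preferred as
#'   the kept member of a highly correlated pair; see [default_keep_list()].
#' @param md_scaled logical; `TRUE` uses MD = z' R^-1 z / k (healthy mean
#'   approximately 1), `FALSE` the unscaled quadratic form.
#' @return An object of class `"mts_config"` (a validated named list).
#' @export
mts_config <- function(correlation_threshold = 0.80,
                       refine_passes = 1L,
                       cv_folds = 10L,
                       seed = 1L,
                       keep_policy = default_keep_list(),
                       md_scaled = TRUE) {
  if (!is.numeric(correlation_threshold) || length(correlation_threshold) != 1 ||
      correlation_threshold <= 0 || correlation_threshold > 1) {
    stop("'correlation_threshold' must be a single number in (0, 1]")
  }
  refine_passes <- as.integer(refine_passes)
  if (is.na(refine_passes) || refine_passes < 0) {
    stop("'refine_passes' must be a non-negative integer")
  }
  cv_folds <- as.integer(cv_folds)
  if (is.na(cv_folds) || cv_folds < 2) stop("'cv_folds' must be >= 2")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  if (!is.character(keep_policy)) stop("'keep_policy' must be character")
  if (!is.logical(md_scaled) || length(md_scaled) != 1) {
    stop("'md_scaled' must be TRUE or FALSE")
  }
  structure(list(correlation_threshold = correlation_threshold,
                 refine_passes = refine_passes,
                 cv_folds = cv_folds,
                 seed = seed,
                 keep_policy = keep_policy,
                 md_scaled = md_scaled),
            class = "mts_config")
}

#' @export
print.mts_config <- function(x, ...) {
  cat("MTS run configuration\n")
  cat(sprintf("  correlation threshold : |r| > %.2f\n", x$correlation_threshold))
  cat(sprintf("  refinement passes     : %d\n", x$refine_passes))
  cat(sprintf("  CV folds              : %d\n", x$cv_folds))
  cat(sprintf("  seed                  : %d\n", x$seed))
  cat(sprintf("  MD definition         : %s\n",
              if (x$md_scaled) "scaled (z'R^-1z / k)" else "unscaled (z'R^-1z)"))
  cat(sprintf("  keep policy           : %s\n",
              if (length(x$keep_policy)) paste(x$keep_policy, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Read / write a run configuration
#'
#' The on-disk format is a flat YAML document of `key: value` pairs using the
#' argument names of [mts_config()] (with `keep_policy` a YAML list). Keys
#' absent from the file take the package defaults.
#'
#' @param path path to a YAML file.
#' @return `read_mts_config()` returns an `mts_config`; `write_mts_config()`
#'   returns `path` invisibly.
#' @export
read_mts_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(mts_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$keep_policy)) raw$keep_policy <- as.character(raw$keep_policy)
  do.call(mts_config, raw)
}

#' @rdname read_mts_config
#' @param config an `mts_config`.
#' @export
write_mts_config <- function(config, path) {
  stopifnot(inherits(config, "mts_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
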