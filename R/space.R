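#' Fit a Mahalanobis reference space from healthy subjects
#'
#' The reference space ("Mahalanobis space") summarises the healthy group by
#' per-variable sample means and standard deviations (n - 1 denominator), the
#' Pearson correlation matrix of the standardized variables, and its inverse.
#' Distances of any subject from this space are computed by [compute_md()].
#'
#' When the correlation matrix is ill-conditioned (condition number above
#' `cond_bound`) or outright singular, the Moore-Penrose pseudo-inverse is
#' used instead of the plain inverse and the `pseudo_inverse` flag is set, with
#' a warning — collinear biomarker panels degrade gracefully rather than
#' failing silently.
#'
#' @param normal [feature_table()] of healthy subjects (complete rows).
#' @param variables variables to use; default all columns.
#' @param cond_bound condition-number bound above which the pseudo-inverse
#'   path is taken.
#' @return An object of class `"mahalanobis_space"`: list with `variables`,
#'   `means`, `sds`, `correlation`, `correlation_inverse`, `n` (construction
#'   sample size), `k` (number of variables), `pseudo_inverse` (logical).
#' @examples
#' ft <- feature_table(cbind(A = c(1, 2, 3)), group = "normal")
#' sp <- fit_space(ft)
#' sp$means  # 2
#' @export
fit_space <- function(normal, variables = NULL, cond_bound = 1e10) {
  normal <- as_feature_table(normal)
  if (is.null(variables)) variables <- colnames(normal$values)
  x <- ft_vars(normal, variables)$values
  if (anyNA(x)) stop("construction data contain missing values")
  n <- nrow(x); k <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance variable(s) in construction data: ",
         paste(variables[sds == 0], collapse = ", "))
  }
  if (n < k + 2) {
    warning(sprintf(
      "only %d subjects for %d variables; correlation matrix is singular or near-singular",
      n, k))
  }
  means <- colMeans(x)
  cm <- stats::cor(x)
  pseudo <- FALSE
  cinv <- NULL
  if (k == 1L) {
    cinv <- matrix(1, 1, 1)
  } else {
    cond <- tryCatch(kappa(cm, exact = TRUE), error = function(e) Inf)
    if (is.finite(cond) && cond <= cond_bound) {
      cinv <- tryCatch(solve(cm), error = function(e) NULL)
    }
    if (is.null(cinv)) {
      cinv <- MASS::ginv(cm)
      pseudo <- TRUE
      warning("correlation matrix ill-conditioned; using Moore-Penrose pseudo-inverse")
    }
  }
  dimnames(cm) <- list(variables, variables)
  dimnames(cinv) <- list(variables, variables)
  structure(list(variables = variables,
                 means = stats::setNames(means, variables),
                 sds = stats::setNames(sds, variables),
                 correlation = cm,
                 correlation_inverse = cinv,
                 n = n, k = k,
                 pseudo_inverse = pseudo),
            class = "mahalanobis_space")
}

#' @export
print.mahalanobis_space <- function(x, ...) {
  cat(sprintf("Mahalanobis space: %d variables, fit on %d subjects%s\n",
              x$k, x$n, if (x$pseudo_inverse) " (pseudo-inverse)" else ""))
  cat("Variables:", paste(x$variables, collapse = ", "), "\n")
  invisible(x)
}

#' Scaled Mahalanobis distance of subjects from a reference space
#'
#' Each subject is standardized with the space's means and SDs,
#' z = (x - mean) / sd, and scored as MD = z' R^-1 z / k where R is the
#' reference correlation matrix and k the number of variables. The 1/k scaling
#' makes the average distance of the healthy construction sample (n - 1)/n,
#' i.e. close to 1, which is the conventional diagnostic scale; `scaled =
#' FALSE` gives the raw quadratic form.
#'
#' @param space a [fit_space()] result.
#' @param table [feature_table()] (or matrix/data frame) containing all space
#'   variables; extra columns are ignored.
#' @param scaled divide by the number of variables (default) or not.
#' @return Numeric vector of non-negative distances, one per subject.
#' @export
compute_md <- function(space, table, scaled = TRUE) {
  stopifnot(inherits(space, "mahalanobis_space"))
  table <- as_feature_table(table)
  x <- ft_vars(table, space$variables)$values
  if (anyNA(x)) stop("table contains missing values on the space variables")
  z <- sweep(sweep(x, 2L, space$means, "-"), 2L, space$sds, "/")
  md <- rowSums((z %*% space$correlation_inverse) * z)
  if (scaled) md <- md / space$k
  # the quadratic form is non-negative up to roundoff; clamp tiny negatives
  md[md < 0 & md > -1e-10] <- 0
  if (any(!is.finite(md)) || any(md < 0)) {
    stop("non-finite or negative Mahalanobis distance (degenerate inverse?)")
  }
  md
}

#' Individuals/moving-range control limit for a distance series
#'
#' For a series of Mahalanobis distances in observation order, computes the
#' XmR-chart upper control limit T = mu + 2.66 * Rbar, where mu is the mean
#' of the series and Rbar the mean moving range (mean absolute difference of
#' successive values); 2.66 is the standard individuals-chart constant
#' (3 / d2 with d2 = 1.128 for ranges of 2).
#'
#' @param md numeric vector of distances, in the order observed.
#' @return List with `mu`, `rbar` and `threshold` (= `mu + 2.66 * rbar`).
#' @examples
#' xmr_threshold(c(1, 1, 1, 9))  # mu = 3, rbar = 8/3, T = 3 + 2.66 * 8/3
#' @export
xmr_threshold <- function(md) {
  if (length(md) < 2) stop("need at least 2 values for a moving range")
  mu <- mean(md)
  rbar <- mean(abs(diff(md)))
  list(mu = mu, rbar = rbar, threshold = mu + 2.66 * rbar)
}

#' Refine the reference space by control-chart outlier screening
#'
#' Fits the space on the healthy data, scores the construction rows
#' themselves, and removes every row whose distance strictly exceeds the
#' XmR upper limit T = mu + 2.66 * Rbar (see [xmr_threshold()]); the space is
#' then refit on the survivors. One pass reproduces the reference workflow; with
#' `max_passes > 1` the screen iterates until no row is removed or the budget
#' is exhausted. The construction set never grows, and the moving range is
#' taken over rows in their input order (inherent to individuals charts).
#'
#' @param normal [feature_table()] of healthy subjects (complete rows).
#' @param variables variables to use; default all.
#' @param max_passes maximum number of screening passes (>= 1).
#' @param cond_bound passed to [fit_space()].
#' @return List with `space` (the refined `mahalanobis_space`) and
#'   `refinement`, class `"mts_refinement"`: `threshold_T`, `md_mean_mu`,
#'   `mean_moving_range_Rbar` (from the last screening pass), `removed`
#'   (strictly increasing original row indices), `passes`, `n_input`,
#'   `n_final`.
#' @export
refine_space <- function(normal, variables = NULL, max_passes = 1L,
                         cond_bound = 1e10) {
  normal <- as_feature_table(normal)
  if (is.null(variables)) variables <- colnames(normal$values)
  max_passes <- as.integer(max_passes)
  if (max_passes < 1) stop("'max_passes' must be >= 1")

  keep <- seq_len(nrow(normal$values))  # original row indices still in play
  removed <- integer(0)
  passes <- 0L
  stats_last <- NULL
  space <- NULL
  repeat {
    passes <- passes + 1L
    current <- ft_rows(normal, keep)
    if (nrow(current$values) < length(variables) + 2) {
      stop("refinement error: fewer survivors than variables + 2; space no longer estimable")
    }
    space <- fit_space(current, variables, cond_bound = cond_bound)
    md <- compute_md(space, current)
    stats_last <- xmr_threshold(md)
    out <- md > stats_last$threshold
    if (!any(out) || passes >= max_passes) {
      if (any(out) && passes >= max_passes) {
        # budget exhausted with removals still pending: drop them, refit once more
        removed <- c(removed, keep[out])
        keep <- keep[!out]
        current <- ft_rows(normal, keep)
        if (nrow(current$values) < length(variables) + 2) {
          stop("refinement error: fewer survivors than variables + 2; space no longer estimable")
        }
        space <- fit_space(current, variables, cond_bound = cond_bound)
      }
      break
    }
    removed <- c(removed, keep[out])
    keep <- keep[!out]
  }
  refinement <- structure(list(threshold_T = stats_last$threshold,
                               md_mean_mu = stats_last$mu,
                               mean_moving_range_Rbar = stats_last$rbar,
                               removed = sort(removed),
                               passes = passes,
                               n_input = nrow(normal$values),
                               n_final = length(keep)),
                          class = "mts_refinement")
  list(space = space, refinement = refinement)
}

#' @export
print.mts_refinement <- function(x, ...) {
  cat(sprintf(
    "Reference-space refinement: %d of %d rows removed in %d pass(es)\n",
    length(x$removed), x$n_input, x$passes))
  cat(sprintf("  last control limit T = %.4f (mu = %.4f, Rbar = %.4f)\n",
              x$threshold_T, x$md_mean_mu, x$mean_moving_range_Rbar))
  invisible(x)
}

#' Serialize / restore a Mahalanobis space as JSON
#'
#' @param space a `mahalanobis_space`.
#' @param path file path.
#' @return `write_space()` returns `path` invisibly; `read_space()` the
#'   restored space.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "mahalanobis_space"))
  obj <- list(variables = space$variables,
              means = unname(space$means),
              sds = unname(space$sds),
              correlation = space$correlation,
              correlation_inverse = space$correlation_inverse,
              n = space$n, k = space$k,
              pseudo_inverse = space$pseudo_inverse)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vn <- obj$variables
  cm <- matrix(unlist(obj$correlation), nrow = obj$k, byrow = TRUE,
               dimnames = list(vn, vn))
  cinv <- matrix(unlist(obj$correlation_inverse), nrow = obj$k, byrow = TRUE,
                 dimnames = list(vn, vn))
  structure(list(variables = vn,
                 means = stats::setNames(obj$means, vn),
                 sds = stats::setNames(obj$sds, vn),
                 correlation = cm,
                 correlation_inverse = cinv,
                 n = as.integer(obj$n), k = as.integer(obj$k),
                 pseudo_inverse = isTRUE(obj$pseudo_inverse)),
            class = "mahalanobis_space")
}
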