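#' Define a synthetic two-group biomarker population
#'
#' Describes a multivariate-normal healthy population and a disease population
#' identical except for mean shifts (expressed in healthy-SD units). Optional
#' near-duplicate columns manufacture highly correlated pairs for exercising
#' redundancy pruning, and missing values can be injected completely at
#' random. The generator is the package's test bed: real blood counts are
#' skewed and heavier-tailed, but the reference-space mathematics uses only
#' first and second moments, and Gaussian data admit closed-form checks.
#'
#' @param variable_names character vector of variable names.
#' @param means,sds per-variable healthy means and (positive) SDs.
#' @param correlation symmetric correlation matrix with unit diagonal;
#'   eigenvalues must be >= -1e-10.
#' @param shift_sds per-variable disease mean shift in units of the healthy
#'   SD (0 = null variable).
#' @param n_normal,n_abnormal group sizes.
#' @param duplicate_pairs optional data frame with columns `name`, `source`,
#'   `noise_frac`: each row appends a column `name` = (1 - f) * source +
#'   f * independent noise (noise drawn with the source's mean and SD), giving
#'   an expected correlation (1-f) / sqrt((1-f)^2 + f^2) with its source.
#' @param missing_rate fraction of cells set missing, uniformly at random.
#' @param seed default RNG seed for [generate_population()].
#' @return An object of class `"synthetic_profile"`.
#' @export
synthetic_profile <- function(variable_names, means, sds, correlation,
                              shift_sds, n_normal, n_abnormal,
                              duplicate_pairs = NULL, missing_rate = 0,
                              seed = 1L) {
  p <- length(variable_names)
  stopifnot(length(means) == p, length(sds) == p, all(sds > 0),
            length(shift_sds) == p,
            is.matrix(correlation), nrow(correlation) == p,
            ncol(correlation) == p)
  if (max(abs(correlation - t(correlation))) > 1e-12 ||
      max(abs(diag(correlation) - 1)) > 1e-12) {
    stop("'correlation' must be symmetric with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf("'correlation' is not positive semi-definite (eigenvalue %.3e)",
                 min(ev)))
  }
  if (!is.null(duplicate_pairs)) {
    stopifnot(is.data.frame(duplicate_pairs),
              all(c("name", "source", "noise_frac") %in% names(duplicate_pairs)),
              all(duplicate_pairs$source %in% variable_names),
              all(duplicate_pairs$noise_frac > 0 & duplicate_pairs$noise_frac < 1))
  }
  stopifnot(missing_rate >= 0, missing_rate < 1, n_normal > 0, n_abnormal > 0)
  structure(list(variable_names = variable_names,
                 means = stats::setNames(means, variable_names),
                 sds = stats::setNames(sds, variable_names),
                 correlation = correlation,
                 shift_sds = stats::setNames(shift_sds, variable_names),
                 n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 duplicate_pairs = duplicate_pairs,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_profile")
}

#' @export
print.synthetic_profile <- function(x, ...) {
  cat(sprintf("Synthetic two-group profile: %d + %d subjects, %d variables\n",
              x$n_normal, x$n_abnormal, length(x$variable_names)))
  shifted <- names(x$shift_sds)[x$shift_sds != 0]
  cat("Shifted variables:",
      if (length(shifted)) paste(sprintf("%s (%+.1f SD)", shifted,
                                         x$shift_sds[shifted]), collapse = ", ")
      else "(none - null population)", "\n")
  if (!is.null(x$duplicate_pairs)) {
    cat("Near-duplicate columns:",
        paste(sprintf("%s ~ %s", x$duplicate_pairs$name,
                      x$duplicate_pairs$source), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default routine-blood-count-like profile
#'
#' A packaged profile emulating the study design the package targets: a large
#' healthy reference group and a smaller asthma-like group measured on the
#' 14-variable complete-blood-count panel of [default_keep_list()], with
#' physiologically plausible means/SDs, moderate positive correlations within
#' the leukocyte and platelet blocks, and disease shifts concentrated on the
#' 7 diagnostically useful variables (largest on the platelet indices PDW and
#' MPV, then WBC, EO#, LY/LY#, MCHC). A near-duplicate plateletcrit column
#' (`PCT`, r ~ 0.99 with PLT) is appended so that redundancy pruning always
#' has work to do, and a small completely-at-random missing rate exercises
#' complete-case filtering.
#'
#' @param n_normal,n_abnormal group sizes; defaults 1480 and 355.
#' @param seed default RNG seed.
#' @return A [synthetic_profile()].
#' @export
default_blood_profile <- function(n_normal = 1480, n_abnormal = 355, seed = 1L) {
  vn <- default_keep_list()
  means <- c(`BA#` = 0.03, `EO#` = 0.15, LY = 32, `LY#` = 2.1, MCH = 30,
             MCHC = 340, MO = 7, `MO#` = 0.45, MPV = 10.5, PDW = 13,
             PLT = 240, RBC = 4.7, RDW = 13, WBC = 6.3)
  sds <- c(`BA#` = 0.02, `EO#` = 0.12, LY = 7, `LY#` = 0.6, MCH = 2,
           MCHC = 10, MO = 1.8, `MO#` = 0.15, MPV = 0.9, PDW = 2,
           PLT = 55, RBC = 0.45, RDW = 1, WBC = 1.5)
  p <- length(vn)
  cm <- diag(p)
  dimnames(cm) <- list(vn, vn)
  set_r <- function(a, b, r) {
    cm[a, b] <<- r
    cm[b, a] <<- r
  }
  # leukocyte block
  set_r("LY", "LY#", 0.60); set_r("MO", "MO#", 0.60)
  set_r("WBC", "LY#", 0.50); set_r("WBC", "MO#", 0.40)
  set_r("WBC", "EO#", 0.25); set_r("WBC", "BA#", 0.20)
  set_r("LY", "MO", 0.20); set_r("LY#", "MO#", 0.30)
  # red-cell block
  set_r("MCH", "MCHC", 0.50); set_r("RBC", "MCH", -0.30)
  set_r("RBC", "RDW", 0.15); set_r("MCH", "RDW", -0.25)
  # platelet block
  set_r("MPV", "PDW", 0.70); set_r("PLT", "MPV", -0.35); set_r("PLT", "PDW", -0.25)
  shifts <- stats::setNames(numeric(p), vn)
  shifts[c("PDW", "MPV", "WBC", "EO#", "LY", "LY#", "MCHC")] <-
    c(2.5, 1.5, 1.0, 1.2, -0.8, 0.7, 0.5)
  synthetic_profile(vn, means, sds, cm, shifts,
                    n_normal = n_normal, n_abnormal = n_abnormal,
                    duplicate_pairs = data.frame(name = "PCT", source = "PLT",
                                                 noise_frac = 0.15,
                                                 stringsAsFactors = FALSE),
                    missing_rate = 1e-4, seed = seed)
}

#' Draw a synthetic two-group population
#'
#' Samples the healthy group from the profile's multivariate normal and the
#' disease group from the same distribution with means shifted by
#' `shift_sds * sds`. Near-duplicate columns and missing values are then
#' appended/injected per the profile. Fully reproducible: the same seed gives
#' byte-identical tables.
#'
#' @param profile a [synthetic_profile()].
#' @param seed RNG seed; defaults to the profile's.
#' @return List with `normal` and `abnormal` ([feature_table()]s) and
#'   `profile` (the configuration echoed back as ground truth).
#' @export
generate_population <- function(profile, seed = profile$seed) {
  stopifnot(inherits(profile, "synthetic_profile"))
  set.seed(seed)
  sigma <- diag(profile$sds) %*% profile$correlation %*% diag(profile$sds)
  draw <- function(n, mu) {
    x <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
    colnames(x) <- profile$variable_names
    x
  }
  xn <- draw(profile$n_normal, profile$means)
  xa <- draw(profile$n_abnormal,
             profile$means + profile$shift_sds * profile$sds)
  dp <- profile$duplicate_pairs
  if (!is.null(dp)) {
    for (i in seq_len(nrow(dp))) {
      src <- dp$source[[i]]; f <- dp$noise_frac[[i]]
      mk <- function(x) {
        e <- stats::rnorm(nrow(x), mean = profile$means[[src]],
                          sd = profile$sds[[src]])
        x <- cbind(x, (1 - f) * x[, src] + f * e)
        colnames(x)[ncol(x)] <- dp$name[[i]]
        x
      }
      xn <- mk(xn); xa <- mk(xa)
    }
  }
  if (profile$missing_rate > 0) {
    inject <- function(x) {
      hit <- stats::runif(length(x)) < profile$missing_rate
      x[hit] <- NA_real_
      x
    }
    xn <- inject(xn); xa <- inject(xa)
  }
  list(normal = feature_table(xn, group = "normal"),
       abnormal = feature_table(xa, group = "abnormal"),
       profile = profile)
}
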