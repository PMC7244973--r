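oa_is_balanced <- function(oa) {
  all(colSums(oa$levels == 1L) == oa$n_runs / 2)
}

oa_is_orthogonal <- function(oa) {
  k <- ncol(oa$levels)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      counts <- table(oa$levels[, i], oa$levels[, j])
      if (length(counts) != 4 || !all(counts == oa$n_runs / 4)) return(FALSE)
    }
  }
  TRUE
}

test_that("generated arrays have the right size, balance and orthogonality", {
  oa4 <- generate_oa(3)
  expect_equal(oa4$n_runs, 4)
  expect_true(oa_is_balanced(oa4))

  expect_equal(generate_oa(15)$n_runs, 16)
  expect_equal(generate_oa(14)$n_runs, 16)
  expect_equal(generate_oa(16)$n_runs, 32)

  # exhaustive pairwise check for every array size up to 64 runs
  for (nf in c(1, 3, 7, 15, 31, 63)) {
    oa <- generate_oa(nf)
    expect_equal(oa$n_columns, oa$n_runs - 1)
    expect_true(oa_is_balanced(oa))
    if (oa$n_columns > 1) expect_true(oa_is_orthogonal(oa))
  }
  expect_error(generate_oa(0), ">= 1")
})

test_that("larger-the-better SN ratio matches its closed forms", {
  expect_equal(sn_larger_better(rep(1, 5)), 0)
  expect_equal(sn_larger_better(c(10, 10)), 10)
  expect_equal(sn_larger_better(c(1, 0.1)), -10 * log10(5.5),
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    md <- rexp(17) + 0.01
    expect_equal(sn_larger_better(md), -10 * log10(mean(1 / md)),
                 tolerance = 1e-12)
  }
  expect_error(sn_larger_better(c(1, 0)), "positive")
  expect_error(sn_larger_better(numeric(0)), "empty")
})

test_that("gains equal an independent loop-based level-mean difference", {
  set.seed(22)
  oa <- generate_oa(9)
  vars <- paste0("V", 1:9)
  run_sn <- rnorm(oa$n_runs, 5, 2)
  sn <- compute_gains(run_sn, oa, vars)
  for (v in seq_along(vars)) {
    l1 <- l2 <- c()
    for (r in seq_len(oa$n_runs)) {
      if (oa$levels[r, v] == 1) l1 <- c(l1, run_sn[r]) else l2 <- c(l2, run_sn[r])
    }
    expect_equal(unname(sn$level1_mean[v]), mean(l1), tolerance = 1e-12)
    expect_equal(unname(sn$gain[v]), mean(l1) - mean(l2), tolerance = 1e-12)
  }
  # balance identity: level means average to the grand mean
  expect_equal(unname((sn$level1_mean + sn$level2_mean) / 2),
               rep(mean(run_sn), 9), tolerance = 1e-10)
  # constant SN vector gives zero contrast everywhere
  flat <- compute_gains(rep(3.3, oa$n_runs), oa, vars)
  expect_equal(unname(flat$gain), rep(0, 9), tolerance = 1e-12)
  expect_error(compute_gains(run_sn[-1], oa, vars), "runs")
})

test_that("compute_gains is equivariant under variable permutation", {
  set.seed(23)
  oa <- generate_oa(7)
  vars <- paste0("V", 1:7)
  run_sn <- rnorm(oa$n_runs)
  base <- compute_gains(run_sn, oa, vars)
  perm <- sample(7)
  oa_p <- oa
  oa_p$levels <- oa$levels[, perm, drop = FALSE]
  oa_p$n_columns <- 7L
  permuted <- compute_gains(run_sn, oa_p, vars[perm])
  expect_equal(permuted$gain[vars], base$gain[vars], tolerance = 1e-12)
})

test_that("the packaged 16-run worked example reproduces the published analysis", {
  ex <- blood_oa_example()
  expect_equal(ex$oa$n_runs, 16)
  expect_equal(length(ex$variables), 14)
  expect_true(oa_is_balanced(ex$oa))
  expect_true(oa_is_orthogonal(ex$oa))

  sn <- compute_gains(ex$run_sn, ex$oa, ex$variables)
  expect_lt(abs(sn$level1_mean[["PDW"]] - 8.16), 0.01)
  expect_lt(abs(sn$level2_mean[["PDW"]] - 3.05), 0.01)
  published <- c(`BA#` = -0.20, `EO#` = 0.31, LY = 0.25, `LY#` = 0.25,
                 MCH = -0.03, MCHC = 0.01, MO = -0.14, `MO#` = -0.43,
                 MPV = 0.70, PDW = 5.11, PLT = -0.27, RBC = -0.17,
                 RDW = -0.10, WBC = 0.39)
  # published gains are rounded from unrounded SN values; 2-dp inputs land
  # within half a unit of the last place plus rounding slack
  expect_lt(max(abs(sn$gain[names(published)] - published)), 0.02)
  key <- c("PDW", "MPV", "WBC", "EO#", "MO#")
  expect_lt(max(abs(sn$gain[key] - published[key])), 0.01)

  sel <- select_variables(sn)
  expect_equal(length(sel), 7)
  expect_setequal(sel, c("PDW", "MPV", "WBC", "EO#", "LY#", "LY", "MCHC"))
  expect_equal(sel[1:2], c("PDW", "MPV"))  # descending gain
  expect_false(is.unsorted(rev(sn$gain[sel])))
})

test_that("selection is strictly positive-gain, ordered by descending gain", {
  oa <- generate_oa(3)
  mk <- function(g) {
    sn <- compute_gains(rep(0, oa$n_runs), oa, c("A", "B", "C"))
    sn$gain <- g
    sn
  }
  expect_warning(empty <- select_variables(mk(c(A = -1, B = -0.1, C = 0))),
                 "empty")
  expect_length(empty, 0)
  tiny <- select_variables(mk(c(A = 1e-12, B = -1, C = 0)))
  expect_identical(tiny, "A")  # strict positivity, however small
})

test_that("a strongly shifted variable earns the largest gain; nulls hover near zero", {
  prof <- recovery_profile(shift = 0)
  prof$shift_sds["V5"] <- 3
  pop <- generate_population(prof, seed = 31)
  norm <- drop_incomplete_rows(pop$normal)$table
  abn <- drop_incomplete_rows(pop$abnormal)$table
  sn <- run_oa_experiment(norm, abn)
  expect_equal(names(which.max(sn$gain)), "V5")
  expect_gt(sn$gain[["V5"]], 0)

  # null experiment: identical distributions. The scaled MD gives every
  # column a common small positive gain offset (E[1/MD] shrinks as the
  # included-set size grows), so the null signature is exchangeability across
  # variables: no column stands out once the common offset is removed.
  null_prof <- recovery_profile(shift = 0)
  gains <- sapply(1:8, function(s) {
    p <- generate_population(null_prof, seed = 100 + s)
    run_oa_experiment(drop_incomplete_rows(p$normal)$table,
                      drop_incomplete_rows(p$abnormal)$table)$gain
  })
  m <- rowMeans(gains)
  expect_lt(max(abs(m)), 1.5)             # no diagnostic-scale gain appears
  expect_lt(max(abs(m - mean(m))), 0.6)   # and no variable stands out
})
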