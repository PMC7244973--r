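test_that("one-variable space reduces to mean/sd with trivial correlation", {
  sp <- fit_space(feature_table(cbind(A = c(1, 2, 3)), group = "normal"))
  expect_equal(unname(sp$means), 2)
  expect_equal(unname(sp$sds), 1)
  expect_equal(unname(sp$correlation), matrix(1, 1, 1), ignore_attr = TRUE)
  expect_equal(unname(sp$correlation_inverse), matrix(1, 1, 1),
               ignore_attr = TRUE)
})

test_that("rank-deficient correlation takes the pseudo-inverse path", {
  set.seed(1)
  a <- rnorm(20)
  ft <- feature_table(cbind(A = a, B = 2 * a + 1), group = "normal")
  expect_warning(sp <- fit_space(ft), "pseudo-inverse")
  expect_true(sp$pseudo_inverse)
  # the pseudo-inverse still satisfies the Moore-Penrose identity R R+ R = R
  expect_equal(sp$correlation %*% sp$correlation_inverse %*% sp$correlation,
               sp$correlation, tolerance = 1e-8)
})

test_that("fitted correlation matches an independent pairwise computation", {
  ft <- random_table(50, 4, seed = 6)
  sp <- fit_space(ft)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(sp$correlation[i, j],
                   pearson_two_pass(ft$values[, i], ft$values[, j]),
                   tolerance = 1e-10)
    }
  }
  expect_equal(diag(sp$correlation), setNames(rep(1, 4), variables(ft)))
  expect_equal(sp$correlation %*% sp$correlation_inverse, diag(4),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero-variance construction variables are rejected by name", {
  ft <- feature_table(cbind(A = rnorm(10), Z = rep(1, 10)), group = "normal")
  expect_error(fit_space(ft), "Z")
})

test_that("Mahalanobis distances obey the closed-form identities", {
  ft <- random_table(20, 3, seed = 12)
  sp <- fit_space(ft)
  # subject exactly at the mean vector has distance zero
  at_mean <- matrix(sp$means, 1, dimnames = list(NULL, sp$variables))
  expect_equal(compute_md(sp, at_mean), 0, tolerance = 1e-12)
  # univariate subject at mean + 2 sd has scaled MD 2^2 / 1 = 4
  sp1 <- fit_space(ft, "V1")
  x <- matrix(sp1$means + 2 * sp1$sds, 1, dimnames = list(NULL, "V1"))
  expect_equal(compute_md(sp1, x), 4, tolerance = 1e-12)
  # mean scaled MD over the construction sample is (n-1)/n
  expect_equal(mean(compute_md(sp, ft)), 19 / 20, tolerance = 1e-10)
})

test_that("MD is invariant to affine rescaling and variable permutation", {
  ft <- random_table(40, 4, seed = 13)
  test <- random_table(15, 4, seed = 14)
  md <- compute_md(fit_space(ft), test)

  resc <- ft$values; resc[, 2] <- resc[, 2] * 10 + 7
  test2 <- test$values; test2[, 2] <- test2[, 2] * 10 + 7
  md_resc <- compute_md(fit_space(feature_table(resc)), feature_table(test2))
  expect_equal(md_resc, md, tolerance = 1e-10)

  perm <- c(3, 1, 4, 2)
  md_perm <- compute_md(fit_space(feature_table(ft$values[, perm])),
                        feature_table(test$values[, perm]))
  expect_equal(md_perm, md, tolerance = 1e-10)
})

test_that("the XmR control limit follows the hand-computed arithmetic", {
  s <- xmr_threshold(c(1, 1, 1, 9))
  expect_equal(s$mu, 3)
  expect_equal(s$rbar, 8 / 3)
  expect_equal(s$threshold, 3 + 2.66 * 8 / 3)  # ~10.093, so 9 is NOT removed
  expect_lt(9, s$threshold)
  # constant series: zero moving range, limit equals the mean
  s0 <- xmr_threshold(rep(2.5, 6))
  expect_equal(s0$threshold, 2.5)
})

test_that("single-pass refinement removes exactly the rows above the limit", {
  ft <- random_table(60, 3, seed = 15)
  sp0 <- fit_space(ft)
  md0 <- compute_md(sp0, ft)
  lim <- xmr_threshold(md0)
  expected_removed <- which(md0 > lim$threshold)

  out <- refine_space(ft, max_passes = 1)
  expect_identical(out$refinement$removed, expected_removed)
  expect_equal(out$refinement$threshold_T,
               out$refinement$md_mean_mu +
                 2.66 * out$refinement$mean_moving_range_Rbar)
  expect_equal(out$refinement$n_final, 60 - length(expected_removed))
  expect_equal(out$space$n, out$refinement$n_final)
  expect_false(is.unsorted(out$refinement$removed, strictly = TRUE))
})

test_that("iterated refinement is monotone and terminates when nothing moves", {
  ft <- random_table(80, 3, seed = 16)
  one <- refine_space(ft, max_passes = 1)
  many <- refine_space(ft, max_passes = 10)
  expect_lte(many$refinement$n_final, one$refinement$n_final)
  expect_true(all(one$refinement$removed %in% many$refinement$removed))
  # after convergence no construction row exceeds the last limit
  survivors <- feature_table(ft$values[-many$refinement$removed, , drop = FALSE])
  md_final <- compute_md(many$space, survivors)
  expect_true(all(md_final <= xmr_threshold(md_final)$threshold))
})

test_that("refinement refuses spaces that are no longer estimable", {
  expect_error(refine_space(random_table(4, 3, seed = 17)), "estimable")
})

test_that("a space serializes to JSON and back without loss", {
  sp <- fit_space(random_table(30, 3, seed = 18))
  path <- withr::local_tempfile(fileext = ".json")
  write_space(sp, path)
  back <- read_space(path)
  expect_equal(back, sp)
  test <- random_table(5, 3, seed = 19)
  expect_equal(compute_md(back, test), compute_md(sp, test), tolerance = 1e-12)
})
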