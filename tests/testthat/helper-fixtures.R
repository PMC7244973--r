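# shared fixture builders (all data generated in code)

random_table <- function(n, k, seed = 1, group = "normal", prefix = "V") {
  set.seed(seed)
  m <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0(prefix, seq_len(k))))
  feature_table(m, group = group)
}

# correlated healthy table: k variables with exchangeable correlation rho
correlated_table <- function(n, k, rho = 0.3, seed = 1, group = "normal") {
  set.seed(seed)
  cm <- matrix(rho, k, k); diag(cm) <- 1
  x <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = cm)
  colnames(x) <- paste0("V", seq_len(k))
  feature_table(x, group = group)
}

# two-group shifted profile used in the recovery tests: 10 standard-normal
# variables, exchangeable correlation 0.2, shift on V1/V2/V3. The shifted
# subset sits on an XOR-closed column triple of the Hadamard array (1 ^ 2 = 3
# etc.), so two-factor interactions among the shifted variables alias onto
# other shifted columns rather than corrupting a null variable's gain.
recovery_profile <- function(shift = 3, n_normal = 200, n_abnormal = 200,
                             seed = 1) {
  k <- 10
  vn <- paste0("V", seq_len(k))
  cm <- matrix(0.2, k, k); diag(cm) <- 1
  shifts <- setNames(numeric(k), vn)
  shifts[c("V1", "V2", "V3")] <- shift
  synthetic_profile(vn, means = rep(0, k), sds = rep(1, k), correlation = cm,
                    shift_sds = shifts, n_normal = n_normal,
                    n_abnormal = n_abnormal, seed = seed)
}

# textbook two-pass Pearson correlation, independent of stats::cor
pearson_two_pass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
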