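# Shared fixtures and independent oracles for the test suite.

# Seeded random regression problem: X ~ N(0,1), y = b0 + X beta + noise.
make_regression <- function(n, k, beta = rep(1, k), b0 = 0, noise_sd = 0.5,
                            seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
  y <- drop(b0 + X %*% beta + rnorm(n, 0, noise_sd))
  list(X = X, y = y)
}

# Brute-force leave-one-out Q2 via base lm(), independent of q2_cv().
loo_q2_oracle <- function(X, y) {
  n <- length(y)
  pred <- vapply(seq_len(n), function(i) {
    df <- data.frame(y = y[-i], X[-i, , drop = FALSE], check.names = FALSE)
    f <- stats::lm(y ~ ., data = df)
    stats::predict(f, newdata = as.data.frame(X[i, , drop = FALSE]))
  }, numeric(1))
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

# Explicit hat matrix H = X (X'X)^-1 X' (intercept-augmented).
hat_diag_oracle <- function(X) {
  Xa <- cbind(1, X)
  diag(Xa %*% solve(crossprod(Xa)) %*% t(Xa))
}

# Write a qsar_dataset-shaped CSV by hand (independent of
# write_descriptor_table) for I/O tests.
write_raw_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
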