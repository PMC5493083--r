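test_that("OLS reproduces exact fits and matches the normal equations", {
  x <- cbind(a = c(0, 1, 2, 3))
  m <- fit_ols(x, 2 * c(0, 1, 2, 3) + 1)
  expect_equal(m$intercept, 1)
  expect_equal(unname(coef(m)), 2)
  expect_equal(m$r2_c, 1)
  expect_equal(m$se, 0)

  r <- make_regression(n = 30, k = 3, beta = c(2, -1, 0.5), b0 = 3, seed = 5)
  m <- fit_ols(r$X, r$y)
  Xa <- cbind(1, r$X)
  beta_oracle <- solve(crossprod(Xa), crossprod(Xa, r$y))
  expect_lt(max(abs(c(m$intercept, coef(m)) - drop(beta_oracle))), 1e-10)
  # residuals orthogonal to intercept and every column
  expect_lt(max(abs(crossprod(Xa, residuals(m)))), 1e-8)
})

test_that("OLS rejects rank-deficient and undersized designs", {
  set.seed(2)
  x <- rnorm(10)
  X <- cbind(a = x, b = x)
  expect_error(fit_ols(X, rnorm(10)), "rank-deficient.*b")
  expect_error(fit_ols(matrix(rnorm(6), 3, 2), rnorm(3)), "n > k")
  expect_error(fit_ols(cbind(a = rnorm(5)), rep(1, 5)), "zero-variance")
})

test_that("model predictions are consistent and guarded", {
  m <- list(intercept = 1, coefficients = c(a = 2))
  class(m) <- "qsar_model"
  expect_equal(predict(m, cbind(a = c(0, 0.5))), c(1, 2))
  expect_error(predict(m, cbind(b = 1)), "missing descriptor.*a")

  r <- make_regression(25, 2, seed = 3)
  fit <- fit_ols(r$X, r$y)
  expect_equal(cor(predict(fit, r$X), r$y)^2, fit$r2_c)
  # intercept-only model predicts a constant
  m0 <- fit_ols(r$X[, integer(0), drop = FALSE], r$y)
  expect_equal(predict(m0, r$X), rep(mean(r$y), 25))
})

test_that("stepwise selects the planted predictor first and prunes noise", {
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- drop(3 + 2 * X[, 1] + rnorm(n, 0, 0.05))
  m <- stepwise_mlr(X, y)
  expect_true("x1" %in% names(coef(m)))
  expect_identical(names(coef(m))[1], "x1")   # entered first
  # oracle: x1 has the largest single-variable F of all candidates
  rss1 <- apply(X, 2, function(col) sum(.lm.fit(cbind(1, col), y)$residuals^2))
  expect_identical(unname(which.min(rss1)), 1L)
  expect_identical(m$method, "STEPWISE_MLR")

  # pure noise with a stringent entry threshold: intercept-only model
  set.seed(11)
  yn <- rnorm(n)
  m0 <- stepwise_mlr(X, yn, p_enter = 1e-6, p_remove = 1e-5)
  expect_length(coef(m0), 0)
  # oracle: no single-variable partial F reaches the threshold
  pmin_oracle <- min(vapply(seq_len(10), function(j) {
    f <- .lm.fit(cbind(1, X[, j]), yn)
    rss1 <- sum(f$residuals^2)
    rss0 <- sum((yn - mean(yn))^2)
    pf((rss0 - rss1) / (rss1 / (n - 2)), 1, n - 2, lower.tail = FALSE)
  }, numeric(1)))
  expect_gt(pmin_oracle, 1e-6)

  expect_error(stepwise_mlr(X, y, p_enter = 0.10, p_remove = 0.05),
               "p_enter must be <")
})

test_that("stepwise selection is invariant to column permutation", {
  set.seed(12)
  n <- 50
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- drop(1 + 1.5 * X[, 2] - 1.2 * X[, 5] + rnorm(n, 0, 0.4))
  sel1 <- sort(names(coef(stepwise_mlr(X, y))))
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  sel2 <- sort(names(coef(stepwise_mlr(X[, perm], y))))
  expect_identical(sel1, sel2)
})

test_that("stepwise honours the max_terms cap", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("x", 1:12)))
  y <- drop(X %*% rep(1, 12) + rnorm(n, 0, 0.2))
  m <- stepwise_mlr(X, y, max_terms = 3)
  expect_lte(length(coef(m)), 3)
})
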