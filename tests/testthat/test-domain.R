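test_that("leverages match closed forms and the hat-matrix diagonal", {
  x <- cbind(v = c(1, 2, 3))
  h <- leverages(x)
  expect_equal(h, c(1/3 + 0.5, 1/3, 1/3 + 0.5), tolerance = 1e-12)
  # query at the training mean has leverage 1/n
  expect_equal(leverages(x, cbind(v = 2)), 1/3, tolerance = 1e-12)

  r <- make_regression(n = 25, k = 4, seed = 50)
  expect_lt(max(abs(leverages(r$X) - hat_diag_oracle(r$X))), 1e-12)
  # trace of the hat matrix and bounds
  h <- leverages(r$X)
  expect_lt(abs(sum(h) - 5), 1e-10)
  expect_true(all(h > 0 & h <= 1))
  expect_error(leverages(cbind(a = rep(1, 5))), "rank-deficient")
})

test_that("warning leverage follows 3(k+1)/n", {
  expect_equal(warning_leverage(6, 50), 0.42)
  expect_equal(warning_leverage(2, 9), 1.0)
  expect_equal(round(warning_leverage(6, 41), 4), 0.5122)
  expect_error(warning_leverage(-1, 10), "k >= 0")
})

test_that("Williams table flags response and structural outliers", {
  set.seed(51)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(sprintf("c%02d", 1:n),
                                                  c("a", "b")))
  y <- drop(4 + X %*% c(1, -1) + rnorm(n, 0, 0.4))
  y[7] <- y[7] + 6 * 0.4   # corrupt one activity by +6 noise SD
  m <- fit_ols(X, y)
  wt <- williams_table(m, X, y)
  expect_true(wt$response_outlier[wt$compound_id == "c07"])
  expect_lt(sum(wt$response_outlier), 3)
  # standardized residuals really are residual / calibration SD
  s <- attr(wt, "residual_sd")
  expect_equal(wt$std_residual, residuals(m) / s, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s, sqrt(mean((residuals(m) - mean(residuals(m)))^2)))
})

test_that("a perfect-fit model yields all-zero standardized residuals", {
  X <- cbind(a = as.numeric(1:8))
  y <- 2 + 3 * X[, 1]
  m <- fit_ols(X, y)
  wt <- williams_table(m, X, y)
  expect_equal(wt$std_residual, rep(0, 8))
  expect_false(any(wt$response_outlier))
})

test_that("outlier flags are monotone in their thresholds", {
  set.seed(52)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 1, -1) + rnorm(n))
  m <- fit_ols(X[1:32, ], y[1:32])
  lo <- williams_table(m, X[1:32, ], y[1:32], X[33:40, ], y[33:40],
                       residual_limit = 2.0)
  hi <- williams_table(m, X[1:32, ], y[1:32], X[33:40, ], y[33:40],
                       residual_limit = 3.0)
  expect_true(all(hi$response_outlier <= lo$response_outlier))
  # smaller n convention raises h* and can only remove structural outliers
  all_n <- williams_table(m, X[1:32, ], y[1:32], X[33:40, ], y[33:40],
                          h_star_n = "all")
  cal_n <- williams_table(m, X[1:32, ], y[1:32], X[33:40, ], y[33:40],
                          h_star_n = "calibration")
  expect_gt(attr(cal_n, "h_star"), attr(all_n, "h_star"))
  expect_true(all(cal_n$structural_outlier <= all_n$structural_outlier))
  # validation rows present and labelled
  expect_identical(sum(lo$role == "validation"), 8L)
  # a centroid query is never a structural outlier for n > 3(k+1)
  centre <- matrix(colMeans(X[1:32, ]), 1, dimnames = list("mid", c("a", "b", "c")))
  wt <- williams_table(m, X[1:32, ], y[1:32], centre, mean(y[1:32]))
  expect_false(wt$structural_outlier[wt$compound_id == "mid"])
})

test_that("the residual scale options agree with their formulas", {
  r <- make_regression(n = 20, k = 2, seed = 53)
  m <- fit_ols(r$X, r$y)
  res <- residuals(m)
  wt_u <- williams_table(m, r$X, r$y, residual_scale = "unbiased")
  expect_equal(attr(wt_u, "residual_sd"), sqrt(sum(res^2) / (20 - 2 - 1)))
  # PLS models default to the 3.0 SD limit
  mp <- fit_pls(r$X, r$y, n_components = 2)
  wt_p <- williams_table(mp, r$X, r$y)
  expect_equal(attr(wt_p, "residual_limit"), 3.0)
  expect_equal(attr(williams_table(m, r$X, r$y), "residual_limit"), 2.5)
})
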