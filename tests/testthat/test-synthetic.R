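test_that("noiseless generation is exactly identifiable", {
  g <- generate_qsar_data(n = 30, p = 10, n_informative = 3, noise_sd = 0,
                          seed = 80)
  expect_equal(g$truth$achieved_signal_r2, 1.0)
  m <- fit_ols(g$dataset$X[, g$truth$informative_names], g$dataset$activities)
  expect_lt(max(abs(coef(m)[names(g$truth$true_coefficients)] -
                      g$truth$true_coefficients)), 1e-8)
  expect_lt(abs(m$intercept - g$truth$true_intercept), 1e-8)
})

test_that("generation is deterministic and respects feasibility guards", {
  a <- generate_qsar_data(n = 20, p = 15, n_informative = 3, noise_sd = 1,
                          n_collinear_pairs = 2, n_constant = 2, seed = 81)
  b <- generate_qsar_data(n = 20, p = 15, n_informative = 3, noise_sd = 1,
                          n_collinear_pairs = 2, n_constant = 2, seed = 81)
  expect_identical(a$dataset$X, b$dataset$X)
  expect_identical(a$dataset$activities, b$dataset$activities)
  expect_error(generate_qsar_data(n = 20, p = 4, n_informative = 3,
                                  noise_sd = 1, n_collinear_pairs = 2,
                                  n_constant = 2),
               "<= p")
  expect_error(generate_qsar_data(n = 5, p = 10, n_informative = 3,
                                  noise_sd = 1),
               "n > n_informative")
  # informative, child and constant sets are disjoint
  expect_length(intersect(a$truth$informative_names,
                          c(a$truth$collinear_pairs$child,
                            a$truth$constant_names)), 0)
  expect_length(intersect(a$truth$collinear_pairs$child,
                          a$truth$constant_names), 0)
})

test_that("planted collinear pairs achieve their target correlation", {
  hits <- replicate(50, {
    g <- generate_qsar_data(n = 200, p = 15, n_informative = 3, noise_sd = 1,
                            n_collinear_pairs = 5, collinear_r = 0.95,
                            seed = sample.int(1e6, 1))
    with(g$truth$collinear_pairs,
         abs(diag(cor(g$dataset$X[, parent], g$dataset$X[, child]))))
  })
  expect_true(all(hits > 0.85 & hits < 0.995))
})

test_that("activity moments match intercept and signal-plus-noise variance", {
  g <- generate_qsar_data(n = 5000, p = 8, n_informative = 4, noise_sd = 1.2,
                          seed = 83)
  y <- g$dataset$activities
  expect_lt(abs(mean(y) - g$truth$true_intercept), 0.1)
  expect_lt(abs(var(y) - (sum(g$truth$true_coefficients^2) + 1.2^2)) /
              var(y), 0.1)
})

test_that("stored signal R2 is recomputable from the stored truth", {
  g <- study_instance(seed = 4)
  m <- fit_ols(g$dataset$X[, g$truth$informative_names], g$dataset$activities)
  expect_lt(abs(m$r2_c - g$truth$achieved_signal_r2), 1e-10)
  expect_equal(g$truth$achieved_signal_r2, 0.775)
})

test_that("the study-shaped instance has the documented structure", {
  g <- study_instance(seed = 2)
  expect_identical(dim(g$dataset), c(50L, 300L))
  expect_length(g$truth$informative_names, 6)
  expect_identical(nrow(g$truth$collinear_pairs), 20L)
  expect_length(g$truth$constant_names, 10)
  pre <- drop_invariant(g$dataset)
  expect_true(all(g$truth$constant_names %in% pre$report$dropped_constant))
})

test_that("child proxies map back to their informative parents", {
  g <- generate_qsar_data(n = 40, p = 20, n_informative = 3, noise_sd = 1,
                          n_collinear_pairs = 4, seed = 84)
  tr <- g$truth
  inf_children <- tr$collinear_pairs$child[
    tr$collinear_pairs$parent %in% tr$informative_names]
  expect_gt(length(inf_children), 0)
  rec <- recovered_descriptors(tr, inf_children[1])
  expect_identical(rec,
                   tr$collinear_pairs$parent[tr$collinear_pairs$child ==
                                               inf_children[1]])
  expect_setequal(recovered_descriptors(tr, tr$informative_names),
                  tr$informative_names)
})
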