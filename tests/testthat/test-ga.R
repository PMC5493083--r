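test_that("GA-PLS recovers a planted subset and its history is monotone", {
  b <- generate_qsar_data(n = 40, p = 20, n_informative = 4,
                          signal_r2 = 0.85, signal_r2_exact = TRUE, seed = 70)
  g <- ga_pls(b$dataset, population_size = 24, n_generations = 15, seed = 70,
              max_subset_size = 8)
  expect_gte(length(recovered_descriptors(b$truth, g$best_descriptors)), 3)
  expect_true(all(diff(g$history$best_fitness) >= 0))
  expect_lte(length(g$best_descriptors), 8)
  expect_gt(g$best_fitness, 0.5)
  # deterministic for a given seed
  g2 <- ga_pls(b$dataset, population_size = 24, n_generations = 15, seed = 70,
               max_subset_size = 8)
  expect_identical(g$best_genes, g2$best_genes)
  expect_identical(g$history, g2$history)
})

test_that("a frozen GA (no variation, full elitism) leaves the population invariant", {
  b <- generate_qsar_data(n = 25, p = 10, n_informative = 2,
                          signal_r2 = 0.8, seed = 71)
  g <- ga_pls(b$dataset, population_size = 10, n_generations = 6,
              crossover_rate = 0, mutation_rate = 0, elitism = 10, seed = 71)
  expect_true(all(g$history$best_fitness == g$history$best_fitness[1]))
  expect_true(all(g$history$mean_fitness == g$history$mean_fitness[1]))
})

test_that("the subset-size cap is enforced through fitness", {
  b <- generate_qsar_data(n = 25, p = 12, n_informative = 2,
                          signal_r2 = 0.8, seed = 72)
  g <- ga_pls(b$dataset, population_size = 12, n_generations = 8,
              max_subset_size = 2, seed = 72)
  expect_lte(length(g$best_descriptors), 2)
  expect_true(is.finite(g$best_fitness))
  expect_error(ga_pls(b$dataset$X[, integer(0)], b$dataset$activities),
               "no columns")
})

test_that("pure-noise fitness stays near or below zero", {
  set.seed(73)
  X <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(NULL, paste0("d", 1:30)))
  y <- rnorm(60)
  g <- ga_pls(X, y, population_size = 20, n_generations = 10, seed = 73)
  expect_lte(g$best_fitness, 0.3)
})

test_that("GA recall beats size-matched random subsets on planted signal", {
  seeds <- 1:20
  recall <- numeric(0); random_expect <- numeric(0)
  for (s in seeds) {
    b <- generate_qsar_data(n = 40, p = 20, n_informative = 4,
                            signal_r2 = 0.85, signal_r2_exact = TRUE,
                            seed = 200 + s)
    g <- ga_pls(b$dataset, population_size = 16, n_generations = 10,
                max_subset_size = 8, seed = s)
    hits <- length(intersect(g$best_descriptors, b$truth$informative_names))
    recall <- c(recall, hits / 4)
    # expected recall of a uniform random subset of the same size
    random_expect <- c(random_expect, length(g$best_descriptors) * (4 / 20) / 4)
  }
  expect_gt(mean(recall), mean(random_expect))
})

test_that("leave-three-out fitness runs and is seeded", {
  b <- generate_qsar_data(n = 30, p = 12, n_informative = 3,
                          signal_r2 = 0.8, seed = 74)
  g1 <- ga_pls(b$dataset, population_size = 10, n_generations = 5,
               fitness_leave_out = 3, seed = 9)
  g2 <- ga_pls(b$dataset, population_size = 10, n_generations = 5,
               fitness_leave_out = 3, seed = 9)
  expect_identical(g1$best_fitness, g2$best_fitness)
})
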