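#' Genetic-algorithm descriptor selection with PLS fitness (GA-PLS)
#'
#' Searches descriptor subsets with a generational genetic algorithm.
#' Each chromosome is a bit vector over the descriptors (1 = included);
#' its fitness is the cross-validated Q2 of a PLS model on the selected
#' columns, using leave-`fitness_leave_out`-out folds and the component
#' count (up to `min(6, rank)`) that maximizes that Q2. Selection is by
#' tournament, recombination by uniform crossover, variation by per-gene
#' bit flips; the top `elitism` chromosomes are copied unchanged each
#' generation, so the best-ever fitness is non-decreasing. Chromosomes
#' that are empty or exceed `max_subset_size` get fitness `-Inf` and are
#' never elected. Fitness values are cached by gene vector. The whole
#' run is deterministic for a given `seed`.
#'
#' Default settings (population 50, 100 generations, tournament size 2,
#' crossover 0.9, mutation 1/p per gene, elitism 2, subset cap 10) are
#' conventional GA-PLS choices scaled to the ~100-descriptor matrices the
#' workflow produces; leave-3-out fitness is available alongside the
#' default leave-one-out.
#'
#' @param X numeric descriptor matrix (preprocessed: no constant
#'   columns) or a [qsar_dataset()].
#' @param y activity vector; defaults to the dataset's activities when
#'   `X` is a [qsar_dataset()].
#' @param population_size chromosomes per generation (>= 2).
#' @param n_generations number of generations.
#' @param tournament_size competitors per selection tournament.
#' @param crossover_rate probability a child is produced by uniform
#'   crossover rather than copied from its first parent.
#' @param mutation_rate per-gene flip probability; default `1/p`.
#' @param elitism number of top chromosomes copied unchanged (can equal
#'   `population_size`, freezing the population).
#' @param max_subset_size hard cap on selected descriptors.
#' @param fitness_leave_out 1 (leave-one-out, default) or 3
#'   (leave-three-out; the random triplet covering is drawn once per
#'   run).
#' @param seed integer seed.
#' @return An object of class `ga_pls`: `best_genes` (logical vector),
#'   `best_descriptors`, `best_fitness` (Q2), `history` (data frame:
#'   `generation`, `best_fitness`, `mean_fitness` over finite values),
#'   `model` (a PLS `qsar_model` refit on the best subset), `seed`.
#' @export
ga_pls <- function(X, y = NULL, population_size = 50, n_generations = 100,
                   tournament_size = 2, crossover_rate = 0.9,
                   mutation_rate = NULL, elitism = 2, max_subset_size = 10,
                   fitness_leave_out = 1, seed = 1) {
  if (inherits(X, "qsar_dataset")) {
    if (is.null(y)) y <- X$activities
    X <- X$X
  }
  X <- as_descriptor_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (p == 0) stop("descriptor matrix has no columns")
  if (population_size < 2) stop("population_size must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1) stop("crossover_rate in [0,1]")
  if (elitism > population_size) stop("elitism must be <= population_size")
  if (!fitness_leave_out %in% c(1, 3)) {
    warning("fitness_leave_out of ", fitness_leave_out,
            " is unconventional (1 or 3 expected)")
  }
  if (is.null(mutation_rate)) mutation_rate <- 1 / p
  cache <- new.env(parent = emptyenv())
  with_seed(seed, {
    fold <- if (fitness_leave_out == 1) seq_len(n) else
      make_lno_folds(n, fitness_leave_out)
    fitness <- function(genes) {
      s <- sum(genes)
      if (s == 0 || s > max_subset_size) return(-Inf)
      key <- paste(which(genes), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      Xsub <- X[, genes, drop = FALSE]
      a_max <- min(6L, qr(scale(Xsub))$rank)
      val <- if (a_max < 1) -Inf else
        max(pls_cv_q2(Xsub, y, fold, a_max))
      cache[[key]] <- val
      val
    }
    pop <- matrix(rbinom(population_size * p, 1,
                         min(10 / p, 0.5)) == 1L,
                  nrow = population_size)
    fit <- apply(pop, 1, fitness)
    best_genes <- pop[which.max(fit), ]
    best_fit <- max(fit)
    history <- data.frame(generation = integer(0), best_fitness = numeric(0),
                          mean_fitness = numeric(0))
    for (g in seq_len(n_generations)) {
      ord <- order(fit, decreasing = TRUE)
      newpop <- matrix(FALSE, population_size, p)
      n_elite <- min(elitism, population_size)
      if (n_elite > 0) newpop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      if (population_size > n_elite) {
        for (i in (n_elite + 1):population_size) {
          p1 <- tournament(fit, tournament_size)
          child <- if (runif(1) < crossover_rate) {
            p2 <- tournament(fit, tournament_size)
            mask <- runif(p) < 0.5
            ifelse(mask, pop[p1, ], pop[p2, ])
          } else pop[p1, ]
          if (mutation_rate > 0) {
            flip <- runif(p) < mutation_rate
            child <- xor(child, flip)
          }
          newpop[i, ] <- child
        }
      }
      pop <- newpop
      fit <- apply(pop, 1, fitness)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_genes <- pop[which.max(fit), ]
      }
      finite <- fit[is.finite(fit)]
      history <- rbind(history, data.frame(
        generation = g, best_fitness = best_fit,
        mean_fitness = if (length(finite)) mean(finite) else NA_real_))
    }
    model <- fit_pls(X[, best_genes, drop = FALSE], y)
    structure(list(best_genes = stats::setNames(best_genes, colnames(X)),
                   best_descriptors = colnames(X)[best_genes],
                   best_fitness = best_fit, history = history,
                   model = model, seed = seed,
                   fitness_leave_out = fitness_leave_out),
              class = "ga_pls")
  })
}

# Tournament selection: best of `size` uniformly drawn competitors
# (ties: lowest index).
tournament <- function(fit, size) {
  idx <- sample.int(length(fit), size, replace = TRUE)
  idx[which.max(fit[idx])]
}

# Random disjoint groups of `m` covering 1..n (remainder: one smaller
# final group). Uses the current RNG stream.
make_lno_folds <- function(n, m) {
  ord <- sample.int(n)
  fold <- integer(n)
  fold[ord] <- as.integer(ceiling(seq_len(n) / m))
  fold
}

#' @export
print.ga_pls <- function(x, ...) {
  cat(sprintf("GA-PLS selection: %d descriptors, fitness Q2(L%dO) = %.3f\n",
              length(x$best_descriptors), x$fitness_leave_out,
              x$best_fitness))
  cat("  selected:", paste(x$best_descriptors, collapse = ", "), "\n")
  invisible(x)
}
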