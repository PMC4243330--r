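#' Genetic algorithm configuration for the second marker selection
#'
#' A binary GA over the SNPs of a candidate group: each chromosome is a bit
#' vector (1 = SNP kept) and its fitness is the k-fold cross-validated mean
#' squared error of an epsilon-SVR restricted to the kept columns, so lower
#' is better. Crossover probability 0.6 and per-bit mutation probability
#' 0.033 are the reference settings; population and generation counts default
#' to 20 each (the dense-chip setting) and are raised for small simulated
#' panels. The fold partition used inside the fitness is drawn once per run
#' from `seed`, making fitness a deterministic, memoizable function of the
#' chromosome.
#'
#' @param population_size number of chromosomes per generation (>= 2).
#' @param generations number of generations.
#' @param p_crossover probability a selected parent pair undergoes one-point
#'   crossover (otherwise copied).
#' @param p_mutation_per_bit per-bit flip probability.
#' @param elitism_count best individuals copied unchanged each generation.
#' @param selection `"tournament"` (default, size `tournament_size`) or
#'   `"roulette"` on inverse MSE.
#' @param tournament_size tournament size (>= 2).
#' @param fitness_folds folds of the fitness cross-validation (>= 2).
#' @param seed integer seed controlling the whole run.
#' @param fold_seed seed of the fitness fold partition; defaults to `seed`.
#'   Fixing it across runs with different `seed`s keeps the fitness function
#'   identical while varying only the search randomness.
#' @param svr_hyper an [svr_hyper()] held fixed throughout the run (tuned
#'   beforehand on the full candidate group).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L, generations = 20L,
                      p_crossover = 0.6, p_mutation_per_bit = 0.033,
                      elitism_count = 1L,
                      selection = c("tournament", "roulette"),
                      tournament_size = 2L, fitness_folds = 10L, seed = 1L,
                      fold_seed = seed, svr_hyper) {
  selection <- match.arg(selection)
  stopifnot(population_size >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation_per_bit >= 0, p_mutation_per_bit <= 1,
            elitism_count >= 0, elitism_count < population_size,
            tournament_size >= 2, fitness_folds >= 2,
            inherits(svr_hyper, "svr_hyper"))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover,
                 p_mutation_per_bit = p_mutation_per_bit,
                 elitism_count = as.integer(elitism_count),
                 selection = selection,
                 tournament_size = as.integer(tournament_size),
                 fitness_folds = as.integer(fitness_folds),
                 seed = as.integer(seed), fold_seed = as.integer(fold_seed),
                 svr_hyper = svr_hyper),
            class = "ga_config")
}

#' Cross-validated MSE fitness of a chromosome
#'
#' Restricts the design matrix to the 1-bits of the chromosome, runs k-fold
#' cross-validation of the configured SVR with a fold partition derived
#' deterministically from `config$seed`, and returns the mean squared error
#' of the pooled out-of-fold predictions. The all-zero chromosome (no SNP
#' selected) is penalized with `Inf` rather than raised.
#'
#' @param chromosome 0/1 vector, one bit per candidate SNP.
#' @param X numeric matrix of candidate SNP dosages (samples x SNPs).
#' @param y phenotype vector.
#' @param config a [ga_config()].
#' @return Non-negative fitness value (lower is better); `Inf` for the
#'   all-zero chromosome.
#' @export
ga_fitness <- function(chromosome, X, y, config) {
  stopifnot(length(chromosome) == ncol(X))
  if (!any(chromosome == 1)) return(Inf)
  Xs <- X[, chromosome == 1, drop = FALSE]
  cv <- repeated_cv_correlation(Xs, y, config$svr_hyper,
                                k = config$fitness_folds, r = 1,
                                seed = config$fold_seed, statistic = "mse")
  cv$values[1]
}

ga_pick_parent <- function(fitness, config) {
  n <- length(fitness)
  if (config$selection == "tournament") {
    cand <- sample.int(n, config$tournament_size, replace = TRUE)
    cand[which.min(fitness[cand])]
  } else {
    w <- 1 / (fitness + 1e-12)
    w[!is.finite(w)] <- 0
    if (sum(w) == 0) sample.int(n, 1) else sample.int(n, 1, prob = w)
  }
}

#' Second-stage marker selection with a binary genetic algorithm
#'
#' Runs the GA of [ga_config()] over the candidate SNPs: an initial
#' population of i.i.d. Bernoulli(0.5) bit vectors evolves by elitism,
#' parent selection, one-point crossover (probability `p_crossover` per
#' pair) and per-bit mutation. Fitness values are memoized by chromosome, so
#' revisited subsets cost no new SVR fits; with at least one elite the best
#' fitness is non-increasing across generations. Fully deterministic for a
#' fixed seed and configuration.
#'
#' @param X numeric matrix of candidate SNP dosages (samples x SNPs), columns
#'   named by SNP id.
#' @param y phenotype vector.
#' @param candidate_ids SNP identifiers (default `colnames(X)`).
#' @param config a [ga_config()].
#' @return An object of class `ga_result`: `best_chromosome`,
#'   `best_fitness`, `selected_snp_ids`, `trajectory` (per-generation best
#'   and mean finite fitness), `n_evaluations` (distinct chromosomes
#'   evaluated) and the configuration echo.
#' @export
ga_select <- function(X, y, candidate_ids = colnames(X), config) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, inherits(config, "ga_config"))
  if (is.null(candidate_ids)) candidate_ids <- paste0("SNP", seq_len(ncol(X)))
  n_bits <- ncol(X)
  pop_n <- config$population_size

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_of <- function(chrom) {
    key <- paste(chrom, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- ga_fitness(chrom, X, y, config)
    cache[[key]] <- val
    n_eval <<- n_eval + 1L
    val
  }

  withr::with_seed(config$seed, {
    pop <- matrix(stats::rbinom(pop_n * n_bits, 1, 0.5), nrow = pop_n)
    fitness <- apply(pop, 1, fit_of)
    traj_best <- traj_mean <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      newpop <- matrix(0L, nrow = pop_n, ncol = n_bits)
      n_elite <- config$elitism_count
      if (n_elite > 0) {
        elite <- order(fitness)[seq_len(n_elite)]
        newpop[seq_len(n_elite), ] <- pop[elite, , drop = FALSE]
      }
      i <- n_elite
      while (i < pop_n) {
        p1 <- ga_pick_parent(fitness, config)
        p2 <- ga_pick_parent(fitness, config)
        c1 <- pop[p1, ]; c2 <- pop[p2, ]
        if (stats::runif(1) < config$p_crossover && n_bits >= 2) {
          cut <- sample.int(n_bits - 1, 1)
          tmp <- c1
          c1 <- c(c1[seq_len(cut)], c2[(cut + 1):n_bits])
          c2 <- c(c2[seq_len(cut)], tmp[(cut + 1):n_bits])
        }
        for (child in list(c1, c2)) {
          if (i >= pop_n) break
          flip <- stats::runif(n_bits) < config$p_mutation_per_bit
          child[flip] <- 1L - child[flip]
          i <- i + 1L
          newpop[i, ] <- child
        }
      }
      pop <- newpop
      fitness <- apply(pop, 1, fit_of)
      traj_best[gen] <- min(fitness)
      finite <- fitness[is.finite(fitness)]
      traj_mean[gen] <- if (length(finite)) mean(finite) else Inf
    }
  })
  best <- which.min(fitness)
  chrom <- pop[best, ]
  structure(list(best_chromosome = chrom,
                 best_fitness = fitness[best],
                 selected_snp_ids = candidate_ids[chrom == 1],
                 trajectory = data.frame(generation = seq_len(config$generations),
                                         best = traj_best, mean = traj_mean),
                 n_evaluations = n_eval,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: %d of %d SNPs selected, CV-MSE %.4g (%d evaluations)\n",
              sum(x$best_chromosome), length(x$best_chromosome),
              x$best_fitness, x$n_evaluations))
  invisible(x)
}
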