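# Real-coded genetic algorithm: roulette-wheel selection, blx-alpha
# crossover, non-uniform (generation-annealed) mutation, elitism and
# seed-solution injection. Minimises an arbitrary objective over a box.

#' Bounds for the GA decision vector
#'
#' @param lower,upper numeric vectors of equal length with
#'   `lower <= upper` elementwise.
#' @return an object of class `bounds_set`.
#' @export
bounds_set <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)))
  if (any(lower > upper)) {
    stop("lower bound exceeds upper bound", call. = FALSE)
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "bounds_set")
}

#' GA configuration
#'
#' Defaults follow the adversarial-search settings: population 86 for the
#' 86-dimensional decision vector, 100 generations, 5 percent elite, 80
#' percent of the next population from blx-alpha crossover (alpha = 0.5) and
#' the remaining 15 percent from non-uniform mutation.
#'
#' @param population_size number of individuals (>= 2).
#' @param generations number of generations after the initial one.
#' @param elite_fraction,crossover_fraction,mutation_fraction proportions of
#'   the population produced by elitism, crossover and mutation; must sum
#'   to 1.
#' @param blx_alpha blend-crossover expansion factor.
#' @param mutation_shape annealing exponent b of the non-uniform mutation;
#'   larger values shrink mutations faster over the run.
#' @param mutation_gene_prob probability that any one component of a mutant
#'   is perturbed.
#' @param rng_seed integer seed making the run reproducible.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(population_size = 86, generations = 100,
                      elite_fraction = 0.05, crossover_fraction = 0.80,
                      mutation_fraction = 0.15, blx_alpha = 0.5,
                      mutation_shape = 3, mutation_gene_prob = 0.1,
                      rng_seed = 1L) {
  stopifnot(population_size >= 2, generations >= 1,
            elite_fraction >= 0, crossover_fraction >= 0,
            mutation_fraction >= 0, blx_alpha >= 0, mutation_shape > 0,
            mutation_gene_prob > 0, mutation_gene_prob <= 1)
  if (abs(elite_fraction + crossover_fraction + mutation_fraction - 1) > 1e-8) {
    stop("elite, crossover and mutation fractions must sum to 1", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 crossover_fraction = crossover_fraction,
                 mutation_fraction = mutation_fraction,
                 blx_alpha = blx_alpha,
                 mutation_shape = mutation_shape,
                 mutation_gene_prob = mutation_gene_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

# Rounded operator counts; mutation takes the remainder so the counts always
# sum to the population size.
.ga_counts <- function(config) {
  n <- config$population_size
  n_elite <- round(config$elite_fraction * n)
  n_cross <- round(config$crossover_fraction * n)
  n_mut <- n - n_elite - n_cross
  if (n_mut < 0) {
    n_cross <- n_cross + n_mut
    n_mut <- 0
  }
  list(elite = n_elite, crossover = n_cross, mutation = n_mut)
}

#' Initial population with an injected seed solution
#'
#' `population_size - 1` individuals are sampled componentwise uniformly
#' within the bounds; the injected solution is added exactly once.
#'
#' @param bounds a [bounds_set()].
#' @param config a [ga_config()].
#' @param injected numeric vector within the bounds (e.g. two concatenated
#'   copies of the reference parameter set).
#' @return matrix with `population_size` rows.
#' @export
init_population <- function(bounds, config, injected) {
  d <- length(bounds$lower)
  stopifnot(length(injected) == d)
  if (any(injected < bounds$lower - 1e-12) || any(injected > bounds$upper + 1e-12)) {
    stop("injected solution lies outside the bounds", call. = FALSE)
  }
  n <- config$population_size
  pop <- matrix(stats::runif((n - 1) * d), n - 1, d, byrow = TRUE)
  pop <- sweep(pop, 2, bounds$upper - bounds$lower, "*")
  pop <- sweep(pop, 2, bounds$lower, "+")
  rbind(pop, matrix(injected, 1, d))
}

#' Roulette-wheel selection probabilities for a minimisation
#'
#' Fitness is the objective's distance below the population worst,
#' f_i = (h_worst - h_i) + delta, with delta = 1e-9 max(1, |h_worst|) so the
#' worst individual keeps a vanishing but nonzero probability; probabilities
#' are f / sum(f).
#'
#' @param objectives numeric vector of objective values h (lower is better).
#' @return probability vector (nonnegative, sums to 1).
#' @export
selection_probabilities <- function(objectives) {
  stopifnot(length(objectives) >= 1, all(is.finite(objectives)))
  h_worst <- max(objectives)
  f <- (h_worst - objectives) + 1e-9 * max(1, abs(h_worst))
  f / sum(f)
}

#' blx-alpha blend crossover
#'
#' Each child component is sampled uniformly in
#' `[min(a,b) - alpha d, max(a,b) + alpha d]` with `d = |a - b|`, then
#' clipped to the bounds.
#'
#' @param parent_A,parent_B numeric parent vectors.
#' @param alpha expansion factor.
#' @param bounds a [bounds_set()].
#' @return one child vector.
#' @export
crossover_blx <- function(parent_A, parent_B, alpha, bounds) {
  d <- abs(parent_A - parent_B)
  lo <- pmin(parent_A, parent_B) - alpha * d
  hi <- pmax(parent_A, parent_B) + alpha * d
  child <- lo + stats::runif(length(parent_A)) * (hi - lo)
  pmin(pmax(child, bounds$lower), bounds$upper)
}

#' Non-uniform mutation
#'
#' Each selected component moves towards its upper or lower bound (equal
#' probability) by Delta(t, y) = y (1 - r^((1 - t/T)^b)) with r uniform in
#' [0, 1]: mutations span the whole box early in the run and shrink to zero
#' as t approaches the total generation budget T.
#'
#' @param x individual to mutate.
#' @param generation current generation t (0 <= t <= T).
#' @param total total generation budget T.
#' @param bounds a [bounds_set()].
#' @param shape annealing exponent b.
#' @param gene_prob per-component mutation probability.
#' @return mutated vector, always within bounds.
#' @export
mutate_nonuniform <- function(x, generation, total, bounds, shape,
                              gene_prob = 1) {
  stopifnot(generation >= 0, generation <= total)
  d <- length(x)
  sel <- stats::runif(d) < gene_prob
  if (!any(sel)) {
    sel[sample.int(d, 1)] <- TRUE  # mutate at least one component
  }
  up <- stats::runif(d) < 0.5
  r <- stats::runif(d)
  frac <- 1 - r^((1 - generation / total)^shape)
  delta <- ifelse(up, (bounds$upper - x) * frac, -(x - bounds$lower) * frac)
  x[sel] <- x[sel] + delta[sel]
  pmin(pmax(x, bounds$lower), bounds$upper)
}

#' Run the real-coded genetic algorithm
#'
#' Per generation: the elites are copied unchanged; the crossover share is
#' produced from roulette-selected parent pairs with blx-alpha; the mutation
#' share applies non-uniform mutation to roulette-selected individuals. The
#' run is deterministic given `config$rng_seed`; objective failures must be
#' handled inside `objective_fn` (e.g. by penalties) and never abort the
#' run.
#'
#' @param config a [ga_config()].
#' @param bounds a [bounds_set()].
#' @param objective_fn function mapping a decision vector to a finite scalar
#'   h (minimised).
#' @param injected optional seed solution injected into the initial
#'   population.
#' @param trace_file optional path; per-generation CSV trace (generation,
#'   best_h, worst_h, avg_h) is written there.
#' @return list of class `ga_result`: `best_vector`, `best_h`, `best_trace`,
#'   `worst_trace`, `avg_trace` (each of length `generations + 1`, the first
#'   entry describing the initial population).
#' @export
run_rcga <- function(config, bounds, objective_fn, injected = NULL,
                     trace_file = NULL) {
  stopifnot(inherits(config, "ga_config"), inherits(bounds, "bounds_set"))
  d <- length(bounds$lower)
  counts <- .ga_counts(config)
  n <- config$population_size
  total_gen <- config$generations

  set.seed(config$rng_seed)
  pop <- if (is.null(injected)) {
    p <- matrix(stats::runif(n * d), n, d, byrow = TRUE)
    p <- sweep(p, 2, bounds$upper - bounds$lower, "*")
    sweep(p, 2, bounds$lower, "+")
  } else {
    init_population(bounds, config, injected)
  }

  evaluate <- function(pop) {
    apply(pop, 1, objective_fn)
  }
  h <- evaluate(pop)

  best_trace <- numeric(total_gen + 1)
  worst_trace <- numeric(total_gen + 1)
  avg_trace <- numeric(total_gen + 1)
  record <- function(g) {
    best_trace[g + 1] <<- min(h)
    worst_trace[g + 1] <<- max(h)
    avg_trace[g + 1] <<- mean(h)
  }
  record(0)

  for (g in seq_len(total_gen)) {
    ord <- order(h)
    probs <- selection_probabilities(h)
    elites <- pop[ord[seq_len(counts$elite)], , drop = FALSE]

    children <- matrix(0, counts$crossover, d)
    if (counts$crossover > 0) {
      pa <- sample.int(n, counts$crossover, replace = TRUE, prob = probs)
      pb <- sample.int(n, counts$crossover, replace = TRUE, prob = probs)
      for (k in seq_len(counts$crossover)) {
        children[k, ] <- crossover_blx(pop[pa[k], ], pop[pb[k], ],
                                       config$blx_alpha, bounds)
      }
    }
    mutants <- matrix(0, counts$mutation, d)
    if (counts$mutation > 0) {
      pm <- sample.int(n, counts$mutation, replace = TRUE, prob = probs)
      for (k in seq_len(counts$mutation)) {
        mutants[k, ] <- mutate_nonuniform(pop[pm[k], ], g, total_gen, bounds,
                                          config$mutation_shape,
                                          config$mutation_gene_prob)
      }
    }
    new_pop <- rbind(elites, children, mutants)
    new_h <- c(h[ord[seq_len(counts$elite)]],
               if (counts$crossover > 0) evaluate(children) else numeric(0),
               if (counts$mutation > 0) evaluate(mutants) else numeric(0))
    pop <- new_pop
    h <- new_h
    record(g)
  }

  i_best <- which.min(h)
  result <- structure(list(best_vector = pop[i_best, ],
                           best_h = h[i_best],
                           best_trace = best_trace,
                           worst_trace = worst_trace,
                           avg_trace = avg_trace,
                           config = config),
                      class = "ga_result")
  if (!is.null(trace_file)) {
    utils::write.csv(data.frame(generation = 0:total_gen,
                                best_h = best_trace,
                                worst_h = worst_trace,
                                avg_h = avg_trace),
                     trace_file, row.names = FALSE, quote = FALSE)
  }
  result
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d generations, population %d: best h = %.4f\n",
              x$config$generations, x$config$population_size, x$best_h))
  invisible(x)
}
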