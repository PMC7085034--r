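toy_bounds <- bounds_set(rep(-5, 4), rep(5, 4))
toy_objective <- function(x) sum((x - c(1, -2, 0.5, 3))^2)

test_that("initial population respects bounds and contains the injection once", {
  cfg <- ga_config(population_size = 30, generations = 10, rng_seed = 1)
  inj <- c(0, 0, 0, 0)
  set.seed(1)
  pop <- init_population(toy_bounds, cfg, inj)
  expect_equal(dim(pop), c(30, 4))
  expect_true(all(pop >= -5 & pop <= 5))
  hits <- apply(pop, 1, function(r) all(r == inj))
  expect_identical(sum(hits), 1L)
  expect_error(init_population(toy_bounds, cfg, rep(10, 4)), "bounds")
})

test_that("degenerate bounds collapse the population to one point", {
  b <- bounds_set(rep(2, 3), rep(2, 3))
  cfg <- ga_config(population_size = 5, generations = 1, rng_seed = 1)
  set.seed(1)
  pop <- init_population(b, cfg, rep(2, 3))
  expect_true(all(pop == 2))
})

test_that("roulette probabilities are normalised and rank by objective", {
  p <- selection_probabilities(rep(3.5, 7))
  expect_equal(p, rep(1 / 7, 7))

  set.seed(2)
  for (k in 1:10) {
    h <- rnorm(20)
    p <- selection_probabilities(h)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    # lower (better) objective always gets the larger probability
    expect_identical(order(h), order(p, decreasing = TRUE))
  }
})

test_that("blx-alpha crossover blends within the extended parent interval", {
  b <- bounds_set(rep(-100, 3), rep(100, 3))
  pa <- c(1, 2, 3)
  set.seed(3)
  expect_equal(crossover_blx(pa, pa, 0.5, b), pa)

  pa <- rep(0, 3); pb <- rep(1, 3)
  kids <- replicate(3000, crossover_blx(pa, pb, 0.5, b))
  expect_true(all(kids >= -0.5 & kids <= 1.5))
  # samples reach the alpha-extended tails beyond the parent interval
  expect_lt(min(kids), -0.3)
  expect_gt(max(kids), 1.3)

  # clipping keeps children inside tight bounds
  tight <- bounds_set(rep(0, 3), rep(1, 3))
  kids <- replicate(500, crossover_blx(rep(0, 3), rep(1, 3), 0.5, tight))
  expect_true(all(kids >= 0 & kids <= 1))
})

test_that("non-uniform mutation anneals to zero and respects bounds", {
  b <- bounds_set(rep(0, 6), rep(1, 6))
  x <- rep(0.5, 6)
  set.seed(4)
  expect_equal(mutate_nonuniform(x, 10, 10, b, shape = 3, gene_prob = 1), x)

  for (k in 1:50) {
    y <- mutate_nonuniform(x, sample(0:9, 1), 10, b, shape = 3, gene_prob = 1)
    expect_true(all(y >= 0 & y <= 1))
  }

  step_size <- function(t) {
    mean(replicate(400, mean(abs(
      mutate_nonuniform(x, t, 10, b, shape = 3, gene_prob = 1) - x))))
  }
  expect_gt(step_size(1), step_size(9))
})

test_that("the GA minimises a separable quadratic to the optimum", {
  cfg <- ga_config(population_size = 40, generations = 100, rng_seed = 42)
  res <- run_rcga(cfg, toy_bounds, toy_objective)
  expect_lt(res$best_h, 1e-2)
  expect_equal(res$best_vector, c(1, -2, 0.5, 3), tolerance = 0.1)
})

test_that("elitism makes the best trace non-increasing and final", {
  cfg <- ga_config(population_size = 24, generations = 30, rng_seed = 7)
  res <- run_rcga(cfg, toy_bounds, toy_objective)
  expect_true(all(diff(res$best_trace) <= 1e-12))
  expect_equal(min(res$best_trace), res$best_h)
  expect_length(res$best_trace, 31)
  expect_true(all(res$worst_trace >= res$best_trace))
  expect_true(all(res$avg_trace >= res$best_trace &
                  res$avg_trace <= res$worst_trace))
})

test_that("an injected optimum caps the best trace from above", {
  cfg <- ga_config(population_size = 20, generations = 15, rng_seed = 5)
  res <- run_rcga(cfg, toy_bounds, toy_objective,
                  injected = c(1, -2, 0.5, 3))
  expect_true(all(res$best_trace <= 1e-12))
})

test_that("identical seeds reproduce the run exactly", {
  cfg <- ga_config(population_size = 18, generations = 12, rng_seed = 123)
  r1 <- run_rcga(cfg, toy_bounds, toy_objective)
  r2 <- run_rcga(cfg, toy_bounds, toy_objective)
  expect_identical(r1$best_trace, r2$best_trace)
  expect_identical(r1$worst_trace, r2$worst_trace)
  expect_identical(r1$avg_trace, r2$avg_trace)
  expect_identical(r1$best_vector, r2$best_vector)

  cfg2 <- ga_config(population_size = 18, generations = 12, rng_seed = 124)
  r3 <- run_rcga(cfg2, toy_bounds, toy_objective)
  expect_false(identical(r1$best_trace, r3$best_trace))
})

test_that("ga_config validates its fractions", {
  expect_error(ga_config(elite_fraction = 0.2), "sum to 1")
  expect_error(ga_config(population_size = 1), "population_size")
})

test_that("per-generation trace file matches the returned traces", {
  cfg <- ga_config(population_size = 12, generations = 5, rng_seed = 2)
  tf <- tempfile(fileext = ".csv")
  res <- run_rcga(cfg, toy_bounds, toy_objective, trace_file = tf)
  df <- read.csv(tf)
  expect_equal(df$best_h, res$best_trace)
  expect_equal(df$generation, 0:5)
  unlink(tf)
})
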