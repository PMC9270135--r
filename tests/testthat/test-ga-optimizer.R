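test_that("genome encoding is an exact bijection with the weight layout", {
  cfg <- network_config(n_input = 5, n_hidden = 10, n_output = 1)
  set.seed(31)
  w <- init_weights(cfg)
  g <- encode_weights(w)
  expect_length(g, (5 + 1) * 10 + (10 + 1) * 1)  # 71 parameters
  w2 <- decode_genome(g, cfg)
  expect_identical(w2$V, w$V)
  expect_identical(w2$W, w$W)

  # other architectures round-trip too
  for (arch in list(c(2, 3, 1), c(4, 7, 2))) {
    cfg_a <- network_config(n_input = arch[1], n_hidden = arch[2],
                            n_output = arch[3])
    w_a <- init_weights(cfg_a)
    expect_identical(decode_genome(encode_weights(w_a), cfg_a)$V, w_a$V)
  }

  zero <- decode_genome(rep(0, 71), cfg)
  expect_true(all(zero$V == 0) && all(zero$W == 0))
  expect_error(decode_genome(rep(0, 70), cfg), "does not match")
})

test_that("fitness is the guarded reciprocal of the error", {
  expect_equal(fitness_of(2), 0.5, tolerance = 1e-9)
  expect_equal(fitness_of(0.001), 1000, tolerance = 1e-6)
  expect_true(is.finite(fitness_of(0)))
  expect_equal(fitness_of(0), 1e12)
  E <- sort(runif(20))
  expect_true(all(diff(fitness_of(E)) < 0))  # strictly decreasing
  expect_error(fitness_of(-0.1), "non-negative")
})

test_that("selection probabilities are proportional, normalized and
           scale-invariant", {
  expect_equal(selection_probs(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(selection_probs(5), 1)
  set.seed(13)
  for (i in 1:20) {
    f <- runif(10, 0.1, 100)
    p <- selection_probs(f)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_equal(order(p), order(f))
    expect_lt(max(abs(selection_probs(f * 37.5) - p)), 1e-12)
  }
  expect_error(selection_probs(numeric(0)), "no individuals")
  expect_error(selection_probs(c(1, 0)), "positive")
})

test_that("roulette selection hits frequencies matching the wheel", {
  expect_equal(roulette_select(1), 1L)
  probs <- c(0.25, 0.25, 0.5)
  set.seed(99)
  draws <- replicate(100000, roulette_select(probs))
  # 3 standard errors of a binomial proportion at p = 0.5, n = 1e5
  expect_lt(abs(mean(draws == 3) - 0.5), 3 * sqrt(0.25 / 100000))
  expect_lt(abs(mean(draws == 1) - 0.25), 3 * sqrt(0.25 * 0.75 / 100000))
  set.seed(99)
  expect_identical(replicate(100, roulette_select(probs)), draws[1:100])
})

test_that("arithmetic crossover keeps children between their parents", {
  p1 <- c(1, -2, 3)
  p2 <- c(1, -2, 3)
  set.seed(1)
  ch <- crossover(p1, p2)
  expect_equal(ch$child1, p1)
  expect_equal(ch$child2, p1)
  p2 <- c(0, 4, -1)
  ch <- crossover(p1, p2, alpha = 0.5)
  expect_equal(ch$child1, (p1 + p2) / 2)
  expect_equal(ch$child2, (p1 + p2) / 2)
  for (i in 1:20) {
    ch <- crossover(p1, p2)
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    expect_true(all(ch$child1 >= lo & ch$child1 <= hi))
    expect_true(all(ch$child2 >= lo & ch$child2 <= hi))
    # crossover conserves the component-wise parent sum
    expect_equal(ch$child1 + ch$child2, p1 + p2)
  }
  expect_error(crossover(p1, c(1, 2)), "length")
})

test_that("mutation perturbs the binomially expected share of components", {
  g <- rnorm(10000)
  expect_identical(mutate(g, 0), g)
  expect_equal(mutate(g, 1, sd = 0), g)  # degenerate noise
  set.seed(77)
  changed <- sum(mutate(g, 0.01) != g)
  expect_gte(changed, 70)   # 100 +/- 30 expected hits
  expect_lte(changed, 130)
  expect_error(mutate(g, 1.5), "\\[0, 1\\]")
})

test_that("adaptive rates scale with the fitness spread and clamp", {
  r <- adaptive_rates(1, 1)
  expect_equal(unname(r), c(0.01, 0.01))  # zero spread sits at the floor
  r <- adaptive_rates(0.9, 0.5, c = 0.5, d = 0.05)
  expect_equal(unname(r), c(0.2, 0.02))
  set.seed(21)
  for (i in 1:50) {
    fa <- runif(1, 0, 50); fm <- fa + runif(1, 0, 50)
    r <- adaptive_rates(fm, fa)
    expect_true(all(r >= 0.01 & r <= 0.99))
  }
  expect_error(adaptive_rates(1, 2), "at least the mean")
})

test_that("a degenerate population without variation stays fixed", {
  ga <- ga_config(population_size = 6, n_generations = 5, mutation_sd = 0,
                  seed = 4)
  res <- ga_search(ga, 3, function(g) sum((g - 1)^2), init_range = 0)
  expect_equal(res$best_genome, rep(0, 3))
  expect_equal(unique(res$trace$best_error), 3)
})

test_that("elitism makes the best fitness non-decreasing", {
  for (s in 1:3) {
    ga <- ga_config(seed = s, n_generations = 15, population_size = 10)
    res <- ga_search(ga, 8, function(g) sum(g^2) + 0.05, init_range = 0.5)
    expect_true(all(diff(res$trace$best_fitness) >= 0))
  }
})

test_that("evolution improves on the initial population for a toy net", {
  set.seed(55)
  X <- matrix(runif(40), 20, 2)
  b <- sigmoid(1.5 * X[, 1] - X[, 2])
  cfg <- network_config(n_input = 2, n_hidden = 4)
  ga <- ga_config(seed = 8)
  res <- evolve(ga, cfg, X, b)
  expect_lt(res$best_error, res$trace$best_error[1])
  expect_equal(nrow(res$trace), 41L)  # generation 0 plus 40 generations
})

test_that("the GA recovers a known 2-D optimum from almost every seed", {
  opt <- c(0.2, -0.3)
  hits <- 0L
  for (s in 1:20) {
    ga <- ga_config(seed = s)
    res <- ga_search(ga, 2, function(g) sum((g - opt)^2))
    if (sqrt(sum((res$best_genome - opt)^2)) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("GA-BP with a degenerate GA stage reduces to plain BP", {
  toy <- toy_separable_set()
  cfg <- network_config(n_input = 2, n_hidden = 4, max_epochs = 50, seed = 3)
  ga <- ga_config(population_size = 1, n_generations = 0, seed = 17)
  res <- ga_bp_train(ga, cfg, toy$X, toy$b)
  expect_true(res$ga_initialized)
  # replicate the single random draw the degenerate GA makes
  set.seed(17)
  g0 <- runif((2 + 1) * 4 + (4 + 1) * 1, -0.5, 0.5)
  manual <- bp_train(cfg, toy$X, toy$b, weights = decode_genome(g0, cfg))
  expect_identical(res$weights$V, manual$weights$V)
  expect_identical(res$error_history, manual$error_history)
})

test_that("seeded GA-BP runs are bitwise reproducible", {
  toy <- toy_separable_set()
  cfg <- network_config(n_input = 2, n_hidden = 3, max_epochs = 30, seed = 5)
  ga <- ga_config(population_size = 8, n_generations = 5, seed = 5)
  r1 <- ga_bp_train(ga, cfg, toy$X, toy$b)
  r2 <- ga_bp_train(ga, cfg, toy$X, toy$b)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$evolution_trace, r2$evolution_trace)
})

test_that("adaptive rates can drive the evolution loop", {
  set.seed(66)
  X <- matrix(runif(30), 15, 2)
  b <- sigmoid(X[, 1] - 0.5 * X[, 2])
  cfg <- network_config(n_input = 2, n_hidden = 3)
  ga <- ga_config(adaptive = TRUE, n_generations = 10, seed = 6)
  res <- evolve(ga, cfg, X, b)
  expect_true(all(diff(res$trace$best_fitness) >= 0))
  expect_true(is.finite(res$best_error))
})
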