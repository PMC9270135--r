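# Real-coded genetic algorithm over the perceptron's weight space. Each
# individual is a flattened weight vector; fitness is the reciprocal of the
# network's global error on the training set, so the GA searches for a good
# starting point which gradient descent then refines (the GA-BP scheme).

#' Genetic-algorithm control parameters
#'
#' Defaults follow the usual weight-initialization search setup: 20
#' individuals evolved for 40 generations with crossover probability 0.3 and
#' mutation probability 0.01, one elite individual copied unchanged each
#' generation.
#'
#' @param population_size Number of individuals (>= 2).
#' @param n_generations Generations to evolve (>= 0; 0 scores the initial
#'   population only).
#' @param crossover_prob Fixed per-pair crossover probability P_c in (0, 1\].
#' @param mutation_prob Fixed per-component mutation probability P_m in
#'   (0, 1).
#' @param adaptive When `TRUE`, P_c and P_m are recomputed each generation
#'   from the fitness spread via [adaptive_rates()] with constants `c` and
#'   `d`, clamped to \[`rate_floor`, `rate_ceiling`\].
#' @param c,d Adaptive-rate constants, each < 1.
#' @param elitism_count Individuals copied unchanged into the next generation
#'   (default 1).
#' @param rate_floor,rate_ceiling Clamp bounds for adaptive rates.
#' @param mutation_sd Standard deviation of the Gaussian perturbation applied
#'   to a mutated component (default 0.1).
#' @param seed Integer seed used by [evolve()] and [ga_bp_train()].
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L, n_generations = 40L,
                      crossover_prob = 0.3, mutation_prob = 0.01,
                      adaptive = FALSE, c = 0.5, d = 0.05,
                      elitism_count = 1L, rate_floor = 0.01,
                      rate_ceiling = 0.99, mutation_sd = 0.1, seed = 1L) {
  stopifnot(n_generations >= 0, elitism_count >= 0, mutation_sd >= 0,
            rate_floor <= rate_ceiling)
  if (population_size < 2 && n_generations > 0) {
    stop("population_size must be at least 2")
  }
  if (crossover_prob <= 0 || crossover_prob > 1) {
    stop("crossover_prob must lie in (0, 1]")
  }
  if (mutation_prob <= 0 || mutation_prob >= 1) {
    stop("mutation_prob must lie in (0, 1)")
  }
  if (c >= 1 || d >= 1) stop("adaptive constants c and d must be < 1")
  structure(
    list(population_size = as.integer(population_size),
         n_generations = as.integer(n_generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         adaptive = isTRUE(adaptive), c = c, d = d,
         elitism_count = as.integer(elitism_count),
         rate_floor = rate_floor, rate_ceiling = rate_ceiling,
         mutation_sd = mutation_sd, seed = as.integer(seed)),
    class = "ga_config")
}

#' Encode network weights as a real-valued genome
#'
#' Flattens V column-major, then W column-major, biases included. The layout
#' is fixed, so [decode_genome()] is an exact inverse.
#'
#' @param weights A `network_weights` object.
#' @return Numeric genome of length (m+1)H + (H+1)l.
#' @export
encode_weights <- function(weights) {
  c(as.vector(weights$V), as.vector(weights$W))
}

#' Decode a genome back into network weights
#'
#' @param genome Numeric vector produced by [encode_weights()] (or searched
#'   by the GA).
#' @param config The [network_config()] fixing the architecture.
#' @return A `network_weights` object.
#' @export
decode_genome <- function(genome, config) {
  m <- config$n_input; H <- config$n_hidden; l <- config$n_output
  nv <- (m + 1L) * H
  nw <- (H + 1L) * l
  if (length(genome) != nv + nw) {
    stop("genome length ", length(genome), " does not match architecture (",
         nv + nw, " weights for ", m, "-", H, "-", l, ")")
  }
  new_network_weights(V = matrix(genome[seq_len(nv)], m + 1L, H),
                      W = matrix(genome[nv + seq_len(nw)], H + 1L, l))
}

#' Fitness of a network error
#'
#' f = 1 / (E + eps) with eps = 1e-12 guarding the perfect-fit case E = 0;
#' strictly decreasing in E.
#'
#' @param E Non-negative global error (vectorized).
#' @return Positive fitness value(s).
#' @export
fitness_of <- function(E) {
  if (any(E < 0)) stop("error must be non-negative")
  1 / (E + 1e-12)
}

#' Roulette-wheel selection probabilities
#'
#' P_i = f_i / sum(f), proportional to fitness.
#'
#' @param fitnesses Positive fitness vector.
#' @return Probability vector summing to 1.
#' @export
selection_probs <- function(fitnesses) {
  if (length(fitnesses) == 0) stop("no individuals to select from")
  if (any(fitnesses <= 0)) stop("fitnesses must be positive")
  fitnesses / sum(fitnesses)
}

#' Spin the roulette wheel once
#'
#' Draws one parent index with the given probabilities, by inverting the
#' cumulative wheel at a uniform draw from the current RNG.
#'
#' @param probs Probability vector from [selection_probs()].
#' @return Integer index in 1..length(probs).
#' @export
roulette_select <- function(probs) {
  u <- stats::runif(1)
  sum(u > cumsum(probs)) + 1L
}

#' Arithmetic crossover of two real-coded parents
#'
#' With a mixing coefficient alpha drawn uniformly from (0, 1), children are
#' the convex combinations alpha p1 + (1-alpha) p2 and its mirror, so every
#' child component lies between its parents' components.
#'
#' @param p1,p2 Parent genomes of equal length.
#' @param alpha Optional fixed mixing coefficient (drawn at random when
#'   `NULL`).
#' @return List of two child genomes.
#' @export
crossover <- function(p1, p2, alpha = NULL) {
  if (length(p1) != length(p2)) stop("parent genomes differ in length")
  if (is.null(alpha)) alpha <- stats::runif(1)
  list(child1 = alpha * p1 + (1 - alpha) * p2,
       child2 = (1 - alpha) * p1 + alpha * p2)
}

#' Gaussian mutation of a genome
#'
#' Each component is independently perturbed with probability `mutation_prob`
#' by adding N(0, sd^2) noise.
#'
#' @param genome Real-coded genome.
#' @param mutation_prob Per-component mutation probability in \[0, 1\].
#' @param sd Perturbation standard deviation (default 0.1).
#' @return Mutated genome.
#' @export
mutate <- function(genome, mutation_prob, sd = 0.1) {
  if (mutation_prob < 0 || mutation_prob > 1) {
    stop("mutation_prob must lie in [0, 1]")
  }
  if (mutation_prob == 0) return(genome)
  hit <- stats::runif(length(genome)) < mutation_prob
  genome[hit] <- genome[hit] + stats::rnorm(sum(hit), 0, sd)
  genome
}

#' Adaptive crossover and mutation rates
#'
#' P_c = c (f_max - f_a) and P_m = d (f_max - f_a), where f_max and f_a are
#' the population's maximum and mean fitness, clamped into
#' \[rate_floor, rate_ceiling\]. A converged population (zero spread) sits at
#' the floor.
#'
#' @param f_max Maximum fitness (>= f_a).
#' @param f_a Mean fitness.
#' @param c,d Constants < 1.
#' @param rate_floor,rate_ceiling Clamp bounds.
#' @return Named numeric vector `c(P_c = ..., P_m = ...)`.
#' @export
adaptive_rates <- function(f_max, f_a, c = 0.5, d = 0.05,
                           rate_floor = 0.01, rate_ceiling = 0.99) {
  if (f_max < f_a) stop("f_max must be at least the mean fitness f_a")
  spread <- f_max - f_a
  clamp <- function(x) min(max(x, rate_floor), rate_ceiling)
  c(P_c = clamp(c * spread), P_m = clamp(d * spread))
}

#' Genetic search over real-coded genomes
#'
#' The GA loop over an arbitrary error function: score every genome (fitness
#' 1/(E + eps)), copy the `elitism_count` best unchanged, then fill the next
#' generation by roulette selection, arithmetic crossover (probability P_c
#' per pair) and Gaussian mutation (probability P_m per component). With
#' elitism the best fitness never decreases. The best individual *ever seen*
#' is returned, along with a per-generation trace.
#'
#' @param ga A [ga_config()].
#' @param genome_length Dimension of the search space.
#' @param error_fn Function genome -> non-negative error to be minimized.
#' @param init_range Half-width of the uniform initialization
#'   \[-init_range, init_range\].
#' @return List with `best_genome`, `best_error`, `best_fitness`, and `trace`
#'   — a data.frame with one row per scored generation (generation 0 is the
#'   initial population): `generation`, `best_fitness`, `mean_fitness`,
#'   `max_fitness`, `best_error`.
#' @export
ga_search <- function(ga, genome_length, error_fn, init_range = 0.5) {
  if (ga$population_size < 2 && ga$n_generations > 0) {
    stop("population_size must be at least 2")
  }
  set.seed(ga$seed)
  pop <- lapply(seq_len(ga$population_size),
                function(i) stats::runif(genome_length,
                                         -init_range, init_range))
  score <- function(pop) vapply(pop, error_fn, numeric(1))
  errs <- score(pop)
  fits <- fitness_of(errs)
  best_idx <- which.max(fits)
  best <- list(genome = pop[[best_idx]], error = errs[best_idx],
               fitness = fits[best_idx])
  trace <- data.frame(generation = 0L, best_fitness = max(fits),
                      mean_fitness = mean(fits), max_fitness = max(fits),
                      best_error = min(errs))
  for (gen in seq_len(ga$n_generations)) {
    if (ga$adaptive) {
      rates <- adaptive_rates(max(fits), mean(fits), ga$c, ga$d,
                              ga$rate_floor, ga$rate_ceiling)
      pc <- rates[["P_c"]]; pm <- rates[["P_m"]]
    } else {
      pc <- ga$crossover_prob; pm <- ga$mutation_prob
    }
    probs <- selection_probs(fits)
    elite_idx <- order(fits, decreasing = TRUE)[seq_len(ga$elitism_count)]
    nxt <- pop[elite_idx]
    while (length(nxt) < ga$population_size) {
      i <- roulette_select(probs)
      j <- roulette_select(probs)
      pair <- list(pop[[i]], pop[[j]])
      if (stats::runif(1) < pc) {
        cr <- crossover(pair[[1]], pair[[2]])
        pair <- list(cr$child1, cr$child2)
      }
      pair <- lapply(pair, mutate, mutation_prob = pm, sd = ga$mutation_sd)
      nxt <- c(nxt, pair)
    }
    pop <- nxt[seq_len(ga$population_size)]
    errs <- score(pop)
    fits <- fitness_of(errs)
    gi <- which.max(fits)
    if (fits[gi] > best$fitness) {
      best <- list(genome = pop[[gi]], error = errs[gi], fitness = fits[gi])
    }
    trace <- rbind(trace, data.frame(
      generation = gen, best_fitness = best$fitness,
      mean_fitness = mean(fits), max_fitness = max(fits),
      best_error = best$error))
  }
  list(best_genome = best$genome, best_error = best$error,
       best_fitness = best$fitness, trace = trace)
}

#' Evolve a population of network-weight genomes
#'
#' [ga_search()] specialized to the perceptron: genomes are flattened weight
#' vectors (see [encode_weights()]) scored by [global_error()] on the
#' training set, initialized uniformly in
#' \[-`config$init_scale`, `config$init_scale`\].
#'
#' @param ga A [ga_config()].
#' @param config The [network_config()] fixing genome length and
#'   initialization scale.
#' @param X,B Normalized training inputs and targets (as for [bp_train()]).
#' @return As [ga_search()].
#' @export
evolve <- function(ga, config, X, B) {
  X <- as.matrix(X)
  B <- as_target_matrix(B, nrow(X), config$n_output)
  glen <- (config$n_input + 1L) * config$n_hidden +
          (config$n_hidden + 1L) * config$n_output
  ga_search(ga, glen,
            function(g) global_error(decode_genome(g, config), X, B),
            init_range = config$init_scale)
}

#' GA-initialized backpropagation training (GA-BP)
#'
#' Two-phase hybrid training: [evolve()] searches the weight space for the
#' lowest-error genome, which is decoded into initial weights for
#' [bp_train()] to refine by gradient descent. With `n_generations = 0` and a
#' single-individual population the GA stage degenerates to one random draw,
#' i.e. plain BP with that initialization.
#'
#' @inheritParams evolve
#' @return A `train_result` (see [bp_train()]) with `ga_initialized = TRUE`,
#'   plus an `evolution_trace` element carrying the GA trace.
#' @export
ga_bp_train <- function(ga, config, X, B) {
  ev <- evolve(ga, config, X, B)
  w0 <- decode_genome(ev$best_genome, config)
  attr(w0, "ga_initialized") <- TRUE
  res <- bp_train(config, X, B, weights = w0)
  res$evolution_trace <- ev$trace
  res
}
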