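#' Sunflower optimiser configuration
#'
#' Continuous population metaheuristic over a bounded box: every
#' candidate ("sunflower") orients toward the incumbent best ("sun") with
#' a distance-dependent step, neighbours near the sun recombine
#' ("pollination"), and the worst candidates are periodically replaced by
#' fresh uniform draws ("elimination"/mortality). Maximization
#' convention; minimize by negating the objective.
#'
#' Default rates follow the published experimental settings: population
#' 30, pollination rate 2.5%, mortality 20%, 300 iterations. The inertia
#' coefficient `phi` scales step sizes and defaults to 0.05 (no published
#' value exists). The step magnitude law is
#' `s_i = phi * P_i * ||C_i + C_[i-1]||` (norm of the sum of consecutive
#' positions) with the pollination-probability weight `P_i = 1`, since
#' the model assumes each sunflower performs exactly one pollination per
#' iteration; the resulting displacement is truncated per dimension at
#' the `d_max` cap of [max_step()], so steps saturate the cap while the
#' population is spread out and individuals end up probing a
#' `d_max`-scale neighbourhood of the sun instead of collapsing onto it.
#' The magnitude law can be replaced via `step_law`.
#'
#' @param lower,upper numeric vectors, per-dimension box bounds
#'   (`lower < upper`).
#' @param n_pop population size (>= 2).
#' @param pollination_rate fraction `p` in `[0, 1)`; `ceiling(p * n_pop)`
#'   offspring per iteration (so 2.5% of 30 still yields one).
#' @param elimination_rate removal rate `O` in `[0, 1)`;
#'   `floor(O * n_pop)` replacements per iteration.
#' @param iterations number of iterations (>= 1).
#' @param phi inertia coefficient scaling step magnitudes.
#' @param seed optional integer seed; fixed seed gives a bit-identical
#'   trajectory.
#' @param step_law optional function
#'   `(x_i, x_prev, phi, d_max) -> scalar step` overriding the default
#'   magnitude law (the per-dimension cap is still applied afterwards).
#' @param d_max optional explicit step cap (scalar or per-dimension)
#'   overriding [max_step()]; the rule miner uses the cap computed on
#'   the normalized data interval rather than on each encoding
#'   dimension's (often much narrower) subspace width.
#' @return an `sfoa_config` list.
#' @export
sfoa_config <- function(lower, upper, n_pop = 30L,
                        pollination_rate = 0.025,
                        elimination_rate = 0.20,
                        iterations = 300L, phi = 0.05,
                        seed = NULL, step_law = NULL, d_max = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), length(lower) >= 1L,
            all(lower < upper),
            n_pop >= 2L,
            pollination_rate >= 0, pollination_rate < 1,
            elimination_rate >= 0, elimination_rate < 1,
            iterations >= 1L, phi >= 0)
  structure(list(lower = lower, upper = upper, n_pop = as.integer(n_pop),
                 pollination_rate = pollination_rate,
                 elimination_rate = elimination_rate,
                 iterations = as.integer(iterations), phi = phi,
                 seed = seed, step_law = step_law, d_max = d_max),
            class = "sfoa_config")
}

#' Uniform initial population
#'
#' @param config an [sfoa_config()].
#' @return `n_pop x D` matrix of i.i.d. uniform positions in the box.
#' @export
initialize_population <- function(config) {
  d <- length(config$lower)
  pop <- matrix(stats::runif(config$n_pop * d), nrow = config$n_pop)
  sweep(sweep(pop, 2L, config$upper - config$lower, `*`),
        2L, config$lower, `+`)
}

evaluate_rows <- function(pop, fitness_fn, idx = seq_len(nrow(pop))) {
  vapply(idx, function(i) fitness_fn(pop[i, ]), numeric(1L))
}

#' Index of the sun (incumbent best)
#'
#' Argmax of fitness; ties broken by lowest index.
#'
#' @param fitness numeric vector of evaluated fitnesses.
#' @return integer index.
#' @export
find_sun <- function(fitness) {
  stopifnot(!anyNA(fitness))
  which.max(fitness)
}

#' Unit orientation vector toward the sun
#'
#' `(C* - C_i) / ||C* - C_i||` (Euclidean). When the individual sits on
#' the sun, a zero vector is returned with attribute `at_sun = TRUE`
#' ("the sun holds its position").
#'
#' @param sun,individual numeric position vectors.
#' @return unit vector (norm 1 within 1e-12), or zero vector flagged
#'   `at_sun`.
#' @export
orientation <- function(sun, individual) {
  diff <- sun - individual
  nrm <- sqrt(sum(diff^2))
  if (nrm == 0) return(structure(diff, at_sun = TRUE))
  diff / nrm
}

#' Per-dimension maximum step
#'
#' `d_max = (C_max - C_min) / (2 * S_pop)`: the cap keeping orientation
#' steps from skipping over global structure.
#'
#' @param config an [sfoa_config()] (or any list with `lower`, `upper`,
#'   `n_pop`).
#' @return numeric vector (scalar-valued per dimension).
#' @export
max_step <- function(config) {
  (config$upper - config$lower) / (2 * config$n_pop)
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Move every non-sun individual toward the sun
#'
#' Each individual `i` (sun excluded: elitism) takes a step of magnitude
#' `s_i = phi * ||C_i + C_[i-1]||` along the unit orientation
#' toward the sun, with index `i-1` taken circularly;
#' the displacement is truncated per dimension at `d_max` (see
#' [max_step()]), positions are clamped to the box and moved individuals
#' are re-evaluated. Individuals closer to their neighbour (hence
#' typically closer to the sun) take smaller steps.
#'
#' @param pop `n_pop x D` position matrix.
#' @param fitness evaluated fitness vector.
#' @param sun_idx index of the sun.
#' @param config an [sfoa_config()].
#' @param fitness_fn objective, position vector to real (maximized).
#' @return list with updated `pop` and `fitness`.
#' @export
step_and_update <- function(pop, fitness, sun_idx, config, fitness_fn) {
  n <- nrow(pop)
  cap <- if (is.null(config$d_max)) max_step(config) else config$d_max
  for (i in seq_len(n)) {
    if (i == sun_idx) next
    prev <- if (i == 1L) n else i - 1L
    s <- if (is.null(config$step_law))
      config$phi * sqrt(sum((pop[i, ] + pop[prev, ])^2))
    else config$step_law(pop[i, ], pop[prev, ], config$phi, cap)
    if (s <= 0) next
    r <- orientation(pop[sun_idx, ], pop[i, ])
    if (isTRUE(attr(r, "at_sun"))) next
    disp <- s * r
    disp <- sign(disp) * pmin(abs(disp), cap)  # per-dimension d_max cap
    pop[i, ] <- clamp(pop[i, ] + disp, config$lower, config$upper)
    fitness[i] <- fitness_fn(pop[i, ])
  }
  list(pop = pop, fitness = fitness)
}

#' Pollination: local recombination near the sun
#'
#' The `ceiling(p * n_pop)` individuals closest to the sun (the sun
#' itself ranks first) each produce one offspring placed uniformly at
#' random on the segment to their next-ranked neighbour; offspring
#' replace the equally many worst-fitness individuals (never the sun).
#'
#' @inheritParams step_and_update
#' @return list with updated `pop` and `fitness`.
#' @export
pollinate <- function(pop, fitness, sun_idx, config, fitness_fn) {
  n <- nrow(pop)
  m <- ceiling(config$pollination_rate * n)
  if (m == 0L) return(list(pop = pop, fitness = fitness))
  m <- min(m, n - 1L)
  dist <- sqrt(rowSums((pop - matrix(pop[sun_idx, ], n, ncol(pop),
                                     byrow = TRUE))^2))
  ranked <- order(dist)  # stable: ties by lowest index
  offspring <- matrix(NA_real_, m, ncol(pop))
  for (k in seq_len(m)) {
    parent <- ranked[k]
    neighbour <- if (k < n) ranked[k + 1L] else ranked[k - 1L]
    u <- stats::runif(1L)
    offspring[k, ] <- pop[parent, ] + u * (pop[neighbour, ] - pop[parent, ])
  }
  victims <- setdiff(order(fitness), sun_idx)[seq_len(m)]
  pop[victims, ] <- offspring
  fitness[victims] <- evaluate_rows(pop, fitness_fn, victims)
  list(pop = pop, fitness = fitness)
}

#' Elimination: replace the worst individuals with fresh draws
#'
#' The `floor(O * n_pop)` worst-fitness individuals (never the sun) are
#' replaced by fresh uniform positions, keeping exploration alive.
#'
#' @inheritParams step_and_update
#' @param iteration current iteration (reserved; the rate is constant).
#' @return list with updated `pop` and `fitness`.
#' @export
eliminate_and_replace <- function(pop, fitness, sun_idx, config,
                                  fitness_fn, iteration = 1L) {
  n <- nrow(pop)
  k <- floor(config$elimination_rate * n)
  if (k == 0L) return(list(pop = pop, fitness = fitness))
  k <- min(k, n - 1L)
  victims <- setdiff(order(fitness), sun_idx)[seq_len(k)]
  d <- length(config$lower)
  fresh <- matrix(stats::runif(k * d), nrow = k)
  fresh <- sweep(sweep(fresh, 2L, config$upper - config$lower, `*`),
                 2L, config$lower, `+`)
  pop[victims, ] <- fresh
  fitness[victims] <- evaluate_rows(pop, fitness_fn, victims)
  list(pop = pop, fitness = fitness)
}

#' Run the sunflower optimiser
#'
#' Full loop: uniform initialization, then per iteration sun selection,
#' orientation steps, pollination and elimination. The sun is never moved
#' or eliminated, so the best-so-far fitness is non-decreasing.
#'
#' @param fitness_fn objective, position vector to real (maximized).
#' @param config an [sfoa_config()]; `config$seed`, when set, seeds the
#'   RNG for a bit-identical trajectory.
#' @return list with `best_position`, `best_fitness`, `history`
#'   (best-so-far per iteration), final `population` and `fitness`.
#' @export
sfoa_optimize <- function(fitness_fn, config) {
  stopifnot(inherits(config, "sfoa_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- initialize_population(config)
  fitness <- evaluate_rows(pop, fitness_fn)
  history <- numeric(config$iterations)
  for (it in seq_len(config$iterations)) {
    sun <- find_sun(fitness)
    st <- step_and_update(pop, fitness, sun, config, fitness_fn)
    sun <- find_sun(st$fitness)
    st <- pollinate(st$pop, st$fitness, sun, config, fitness_fn)
    sun <- find_sun(st$fitness)
    st <- eliminate_and_replace(st$pop, st$fitness, sun, config,
                                fitness_fn, it)
    pop <- st$pop; fitness <- st$fitness
    history[it] <- max(fitness)
  }
  best <- find_sun(fitness)
  list(best_position = pop[best, ], best_fitness = fitness[best],
       history = history, population = pop, fitness = fitness)
}
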