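# The three death channels: starvation (energy below zero after foraging),
# density-dependent predation, and intrinsic aging (age reaches t_die).

#' Starvation and intrinsic-death predicates
#'
#' An individual starves when its stored energy drops strictly below zero
#' after costs and foraging are settled; it dies of intrinsic aging when its
#' age reaches or surpasses its inherited death time.
#'
#' @param energy Stored energy (vectorised).
#' @param age,t_die Age and intrinsic death time (vectorised).
#' @return Logical vector.
#' @export
is_starved <- function(energy) energy < 0

#' @rdname is_starved
#' @export
is_aged <- function(age, t_die) age >= t_die

#' Per-iteration predation probability
#'
#' Predation is density-dependent and age-independent: each alive individual
#' dies with probability `min(1, x * (pop_size / n_modifier)^pred_density_exp)`
#' per iteration, where `pop_size / n_modifier` is the population density.
#' The modifier `x` scales the probability linearly at any given density;
#' the density exponent (default 2, a type-III-like predator response)
#' makes predation intensify in crowded populations and relax in sparse
#' ones.
#'
#' @param pop_size Current population size (count).
#' @param cfg A [sim_config()].
#' @return A probability in `[0, 1]`.
#' @export
predation_probability <- function(pop_size, cfg) {
  if (any(pop_size < 0)) stop("'pop_size' must be >= 0")
  pmin(1, cfg$x * (pop_size / cfg$n_modifier)^cfg$pred_density_exp)
}

#' Apply predation to a population of individuals
#'
#' Each alive individual independently dies ("eaten") with the same
#' [predation_probability()] evaluated at the supplied population size,
#' using one uniform variate per individual.
#'
#' @param n Number of alive individuals.
#' @param pop_size Population size at which the probability is evaluated
#'   (defaults to `n`).
#' @param cfg A [sim_config()].
#' @param u Optional vector of `n` uniform variates (drawn when omitted).
#' @return Logical vector: `TRUE` for individuals eaten this iteration.
#' @export
predation_draw <- function(n, cfg, pop_size = n, u = runif(n)) {
  if (n == 0L) return(logical(0))
  u < predation_probability(pop_size, cfg)
}
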