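# Shared energy pool dynamics: generation with saturation, and greedy
# stochastic foraging with a size-scaled storage cap. These R functions are
# the reference primitives; the compiled engine inlines the identical
# arithmetic (pinned by the trajectory-identity test).

#' Generate pool energy for one iteration
#'
#' The shared pool gains `n_modifier * c_adult * epsilon` energy per
#' iteration independently of the current population size
#' (density-independent foraging), then saturates at [pool_capacity()].
#'
#' @param pool Current pool energy.
#' @param cfg A [sim_config()].
#' @return The updated pool energy.
#' @export
generate_energy <- function(pool, cfg) {
  min(pool + generation_rate(cfg), pool_capacity(cfg))
}

#' One individual's foraging draw
#'
#' The per-iteration intake is limited by (i) the stochastic foraging
#' capacity `s^forage_size_exp * (forage_rate + u)`, an allometric
#' (sublinearly size-scaled) maximum with `u` uniform on (0, 1) added to
#' reduce starvation-driven extinction under the discrete schedule, (ii) the
#' energy left in the pool, and (iii) the headroom to the individual's
#' storage cap [storage_max()]. The intake is removed from the pool
#' (conservation).
#'
#' @param energy Current stored energy of the individual.
#' @param s Fractional size, see [fractional_size()].
#' @param pool Current pool energy.
#' @param cfg A [sim_config()].
#' @param u Uniform(0,1) variate; drawn from the session RNG when omitted.
#' @return A list with `gained`, the new `energy` and the new `pool`.
#' @export
forage <- function(energy, s, pool, cfg, u = runif(1)) {
  capacity <- s^cfg$forage_size_exp * (cfg$forage_rate + u)
  headroom <- storage_max(cfg, s) - energy
  gained <- max(0, min(capacity, min(pool, headroom)))
  list(gained = gained, energy = energy + gained, pool = pool - gained)
}
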