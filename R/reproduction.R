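# Mating eligibility, energetically costly mating attempts, fecundity
# schedules, and biparental trait inheritance with multiplicative mutation.

#' Mating eligibility
#'
#' An individual is eligible to mate when it is mature (`age >= t_mat`), its
#' stored energy strictly exceeds `mate_threshold`, and — for females — it is
#' not currently gestating.
#'
#' @param age,t_mat Age and maturation age (vectorised).
#' @param energy Stored energy.
#' @param gestating Logical; only meaningful for females.
#' @param cfg A [sim_config()].
#' @return Logical vector.
#' @export
mating_eligible <- function(age, t_mat, energy, gestating, cfg) {
  age >= t_mat & energy > cfg$annealable$mate_threshold & !gestating
}

#' Pregnancy probability of a mature female
#'
#' Under the default declining-fecundity schedule the probability of a
#' successful mating falls linearly with maternal age, from 1 at the
#' female's own maturation age to 0 at her intrinsic death time:
#' `p = (t_die - age) / (t_die - t_mat)`. Under the increasing-fertility
#' variant the probability is a constant 0.5 (litter size then grows with
#' age instead, see [litter_size()]).
#'
#' @param age,t_mat,t_die Maternal age, maturation age, death time.
#' @param cfg A [sim_config()].
#' @return Probability in `[0, 1]`.
#' @export
pregnancy_probability <- function(age, t_mat, t_die, cfg) {
  if (cfg$fecundity_mode == "increasing") return(rep(0.5, length(age)))
  if (any(age < t_mat)) stop("pregnancy probability is defined for mature females")
  pmin(1, pmax(0, (t_die - age) / (t_die - t_mat)))
}

#' Litter size at birth
#'
#' Declining mode: 1 or 2 offspring with equal probability (the uniform
#' draw `u` decides). Increasing mode: litter size grows with maternal age,
#' `floor(1 + 8 * (age - t_mat) / (t_die - t_mat))`, capped to 1..8.
#'
#' @param age,t_mat,t_die Maternal age, maturation age, death time.
#' @param cfg A [sim_config()].
#' @param u Uniform(0,1) variate used in declining mode.
#' @return Integer litter size.
#' @export
litter_size <- function(age, t_mat, t_die, cfg, u = runif(1)) {
  if (cfg$fecundity_mode == "increasing") {
    n <- floor(1 + 8 * (age - t_mat) / (t_die - t_mat))
    as.integer(pmin(8, pmax(1, n)))
  } else {
    if (u < 0.5) 1L else 2L
  }
}

#' Biparental trait inheritance with multiplicative mutation
#'
#' Each offspring trait is a random convex combination of the two parental
#' values, perturbed by a multiplicative mutation uniform on
#' `[1 - ev, 1 + ev]`:
#' `trait = (u * mother + (1 - u) * father) * (1 + ev * (2v - 1))`,
#' with independent `u, v ~ Uniform(0, 1)` per trait. With zero evolvability
#' and identical parents the parental value is returned exactly. If the
#' drawn death time does not exceed the drawn maturation age, the death-time
#' draw is repeated (up to `max_redraw` times, then clamped to
#' `t_mat + 1`) so the two ages stay ordered.
#'
#' @param mother,father Named lists or vectors with elements `t_mat` and
#'   `t_die`.
#' @param cfg A [sim_config()].
#' @param max_redraw Bounded retry count for the ordering constraint.
#' @return A list with offspring `t_mat` and `t_die`.
#' @export
inherit_traits <- function(mother, father, cfg, max_redraw = 10L) {
  blend <- function(m, f, ev) {
    u <- runif(1); v <- runif(1)
    (u * m + (1 - u) * f) * (1 + ev * (2 * v - 1))
  }
  t_mat <- blend(mother[["t_mat"]], father[["t_mat"]], cfg$evolvability_mat)
  t_die <- blend(mother[["t_die"]], father[["t_die"]], cfg$evolvability_die)
  tries <- 0L
  while (t_die <= t_mat && tries < max_redraw) {
    t_die <- blend(mother[["t_die"]], father[["t_die"]], cfg$evolvability_die)
    tries <- tries + 1L
  }
  if (t_die <= t_mat) t_die <- t_mat + 1
  list(t_mat = t_mat, t_die = t_die)
}
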