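# Per-iteration energy costs: growth/maturation, somatic repair under six
# cost-function shapes, and metabolism. Pure functions of (age, t_mat, t_die)
# and the configuration; sizes are computed from the closed-form growth
# trajectory, not stored per individual.

#' Repair cost function constants
#'
#' The per-iteration somatic maintenance cost of a mature individual is a
#' time-independent function D(t_die) of its intended intrinsic death time,
#' taking one of six shapes: \{sigmoidal, linear, asymptotic\} x \{low,
#' high\}, with each "high" variant `high_factor` times its "low"
#' counterpart (so it dominates pointwise). All shapes are non-negative and
#' non-decreasing in `t_die`: a longer intended lifespan is never cheaper to
#' maintain.
#'
#' Shapes (`tau = t_die`, low level; energy units of `c_adult`):
#' \itemize{
#'   \item linear: `scale * tau / linear_tref`
#'   \item asymptotic: `scale * tau / (tau + asym_half)`
#'   \item sigmoidal: `scale / (1 + exp(-(tau - sig_mid) / sig_width))`
#' }
#'
#' @param scale Low-variant plateau/slope scale (energy units).
#' @param linear_tref Iterations at which the low linear cost reaches `scale`.
#' @param asym_half Half-saturation time of the asymptotic shape.
#' @param sig_mid,sig_width Midpoint and width of the sigmoidal shape.
#' @param high_factor Multiplier of each "high" variant over its "low" one.
#' @return A list of class `cost_function_spec`.
#' @export
cost_function_spec <- function(scale = 1.4, linear_tref = 200,
                               asym_half = 150, sig_mid = 150,
                               sig_width = 30, high_factor = 2) {
  stopifnot(scale > 0, linear_tref > 0, asym_half > 0, sig_width > 0,
            high_factor >= 1)
  structure(list(scale = scale, linear_tref = linear_tref,
                 asym_half = asym_half, sig_mid = sig_mid,
                 sig_width = sig_width, high_factor = high_factor),
            class = "cost_function_spec")
}

#' @rdname cost_function_spec
#' @param d_type Integer 0-5.
#' @export
d_type_label <- function(d_type) {
  labs <- c("Sigmoidal Low", "Linear Low", "Asymptotic Low",
            "Sigmoidal High", "Linear High", "Asymptotic High")
  labs[as.integer(d_type) + 1L]
}

#' Mature per-iteration repair cost for an intended death time
#'
#' @param t_die Intrinsic death time(s), iterations.
#' @param d_type Shape selector 0-5 (see [cost_function_spec()]).
#' @param spec A [cost_function_spec()].
#' @return Per-iteration maintenance cost(s) of a fully grown individual.
#' @export
repair_cost_base <- function(t_die, d_type, spec = cost_function_spec()) {
  d_type <- as.integer(d_type)
  stopifnot(length(d_type) == 1L)
  if (d_type < 0L || d_type > 5L) stop("unsupported d_type (must be 0..5)")
  level <- if (d_type >= 3L) spec$high_factor else 1
  shape <- d_type %% 3L  # 0 sigmoidal, 1 linear, 2 asymptotic
  base <- if (shape == 1L) {
    spec$scale * t_die / spec$linear_tref
  } else if (shape == 2L) {
    spec$scale * t_die / (t_die + spec$asym_half)
  } else {
    spec$scale / (1 + exp(-(t_die - spec$sig_mid) / spec$sig_width))
  }
  level * base
}

#' Proportional growth rate to maturity
#'
#' Individuals grow multiplicatively, `size(a + 1) = size(a) * (1 + k)`,
#' from the newborn size to the mature size (`size_ratio` times larger) in
#' exactly `t_mat` iterations, so `k = size_ratio^(1/t_mat) - 1`.
#'
#' @param cfg A [sim_config()].
#' @param t_mat Maturation age, iterations (> 0).
#' @return The per-iteration growth rate `k`.
#' @export
growth_constant <- function(cfg, t_mat) {
  if (any(t_mat <= 0)) stop("'t_mat' must be positive")
  if (cfg$annealable$e_init >= e_mature(cfg))
    stop("newborn energy must be below the mature energy level")
  cfg$size_ratio^(1 / t_mat) - 1
}

#' Fractional size of an individual
#'
#' Closed form of the multiplicative growth trajectory:
#' `s(a) = size_ratio^(a / t_mat - 1)` for `a < t_mat`, and 1 from
#' maturation onwards. Newborns have `s(0) = 1 / size_ratio`.
#'
#' @param age Age(s) in iterations.
#' @param t_mat Maturation age(s).
#' @param cfg A [sim_config()].
#' @return Fractional size(s) in `(0, 1]`.
#' @export
fractional_size <- function(age, t_mat, cfg) {
  pmin(1, cfg$size_ratio^(age / t_mat - 1))
}

#' Per-iteration energy costs of an individual
#'
#' `maturation_cost()` is the foraged energy spent on growth this iteration:
#' the mass gained, `e_mature * (s(a + 1) - s(a))`, divided by the growth
#' efficiency (zero once mature). `repair_cost()` is the somatic maintenance
#' cost `s(a) * D(t_die)` (see [repair_cost_base()]). `metabolic_cost()` is
#' `c_adult * s(a)`. `total_cost()` returns the three components and their
#' sum as an energy budget.
#'
#' @param age,t_mat,t_die Age, maturation age and intrinsic death time
#'   (iterations); vectorised.
#' @param cfg A [sim_config()].
#' @return Energy (vectorised); `total_cost()` returns a data.frame with
#'   columns `repair`, `maturation`, `metabolism`, `total`.
#' @export
maturation_cost <- function(age, t_mat, cfg) {
  eff <- cfg$annealable$growth_eff
  if (eff <= 0) stop("'growth_eff' must be positive")
  em <- e_mature(cfg)
  s_now <- fractional_size(age, t_mat, cfg)
  s_next <- fractional_size(age + 1, t_mat, cfg)
  em * (s_next - s_now) / eff
}

#' @rdname maturation_cost
#' @export
repair_cost <- function(age, t_mat, t_die, cfg) {
  fractional_size(age, t_mat, cfg) *
    repair_cost_base(t_die, cfg$annealable$d_type, cfg$repair_spec)
}

#' @rdname maturation_cost
#' @export
metabolic_cost <- function(age, t_mat, cfg) {
  cfg$c_adult * fractional_size(age, t_mat, cfg)
}

#' @rdname maturation_cost
#' @export
total_cost <- function(age, t_mat, t_die, cfg) {
  rep_ <- repair_cost(age, t_mat, t_die, cfg)
  mat_ <- maturation_cost(age, t_mat, cfg)
  met_ <- metabolic_cost(age, t_mat, cfg)
  data.frame(repair = rep_, maturation = mat_, metabolism = met_,
             total = rep_ + mat_ + met_)
}

#' Tabulate the six repair cost shapes on a grid
#'
#' Convenience export for plotting the cost-function family (one column per
#' `d_type`).
#'
#' @param t_die Grid of intrinsic death times.
#' @param spec A [cost_function_spec()].
#' @param file Optional CSV path.
#' @return A data.frame, invisibly written to `file` when given.
#' @export
repair_cost_grid <- function(t_die = seq(30, 300, by = 5),
                             spec = cost_function_spec(), file = NULL) {
  grid <- data.frame(t_die = t_die)
  for (d in 0:5) grid[[d_type_label(d)]] <- repair_cost_base(t_die, d, spec)
  if (!is.null(file)) write.csv(grid, file, row.names = FALSE)
  invisible(grid)
}
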