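#' @useDynLib agesim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif sd setNames
#' @importFrom utils modifyList write.csv
NULL

# Allowed ranges for the six annealable parameters. e_mate and mate_threshold
# range over (0.01, 0.5) x mate_energy_scale (a mature-scale energy; see
# sim_config()).
.annealable_ranges <- function(mate_energy_scale = 10) {
  list(
    epsilon        = c(0.5, 3.0),
    growth_eff     = c(0.01, 0.25),
    e_mate         = c(0.01, 0.5) * mate_energy_scale,
    mate_threshold = c(0.01, 0.5) * mate_energy_scale,
    e_init         = c(0.001, 0.1),
    d_type         = c(0, 5)
  )
}

#' Annealable (simulation-invariant) parameter set
#'
#' The six global parameters tuned by the simulated-annealing search: the
#' starvation (food-turnover) modifier, the growth efficiency, the mating
#' energy and eligibility threshold, the newborn starting energy, and the
#' repair-cost-function selector.
#'
#' @param epsilon Starvation modifier: scales the shared pool's per-iteration
#'   energy generation (dimensionless, in `[0.5, 3]`). Near 0.5 most deaths
#'   are starvation deaths at typical density; near 3 food is abundant.
#' @param growth_eff Fraction of foraged energy converted to body mass while
#'   maturing (in `[0.01, 0.25]`). Smaller values make maturation costlier.
#' @param e_mate Energy debited from *both* participants per mating attempt,
#'   regardless of outcome (energy units).
#' @param mate_threshold Minimum stored energy (strict) required to be
#'   mating-eligible (energy units).
#' @param e_init Starting stored energy of newborns (energy units, in
#'   `[0.001, 0.1]`).
#' @param d_type Repair cost function selector, integer 0-5:
#'   0 Sigmoidal Low, 1 Linear Low, 2 Asymptotic Low, 3 Sigmoidal High,
#'   4 Linear High, 5 Asymptotic High.
#' @param mate_energy_scale Energy scale multiplying the `(0.01, 0.5)` mating
#'   ranges during validation.
#' @return A list of class `annealable_params`.
#' @seealso [classical_preset()], [nonclassical_preset()], [sim_config()]
#' @export
annealable_params <- function(epsilon = 1.75, growth_eff = 0.05,
                              e_mate = 2.0, mate_threshold = 4.0,
                              e_init = 0.02, d_type = 2L,
                              mate_energy_scale = 10) {
  p <- list(epsilon = as.numeric(epsilon), growth_eff = as.numeric(growth_eff),
            e_mate = as.numeric(e_mate),
            mate_threshold = as.numeric(mate_threshold),
            e_init = as.numeric(e_init), d_type = as.integer(d_type))
  class(p) <- "annealable_params"
  validate_annealable(p, mate_energy_scale)
  p
}

validate_annealable <- function(p, mate_energy_scale = 10) {
  rng <- .annealable_ranges(mate_energy_scale)
  for (key in names(rng)) {
    v <- p[[key]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("annealable parameter '%s' must be a single finite number", key))
    r <- rng[[key]]
    if (v < r[1] || v > r[2])
      stop(sprintf("'%s' = %g is outside its allowed range [%g, %g]",
                   key, v, r[1], r[2]))
  }
  if (p$d_type != round(p$d_type))
    stop("'d_type' must be an integer in 0..5")
  invisible(p)
}

#' Optimised parameter presets for the two evolutionary regimes
#'
#' `classical_preset()` returns the annealed optimum under which increased
#' predation selects for *shorter* evolved lifespans: relatively low food
#' turnover (epsilon = 1.51) and cheap mating (e_mate = 1.65,
#' mate_threshold = 3.58). `nonclassical_preset()` returns the optimum under
#' which increased predation selects for *longer* lifespans: abundant food
#' (epsilon = 2.92) and expensive mating (e_mate = 3.36,
#' mate_threshold = 4.70).
#'
#' Both regimes share a low growth efficiency, a low newborn energy and the
#' cheap asymptotic repair cost function (d_type = 2). The reported quadruple
#' 0.052 / 0.022 / 0.02 / 0.007 is read "respectively" as (classical
#' growth_eff, non-classical growth_eff, classical e_init, non-classical
#' e_init).
#'
#' @return An [annealable_params()] object.
#' @export
classical_preset <- function() {
  annealable_params(epsilon = 1.51, growth_eff = 0.052, e_mate = 1.65,
                    mate_threshold = 3.58, e_init = 0.02, d_type = 2L)
}

#' @rdname classical_preset
#' @export
nonclassical_preset <- function() {
  annealable_params(epsilon = 2.92, growth_eff = 0.022, e_mate = 3.36,
                    mate_threshold = 4.70, e_init = 0.007, d_type = 2L)
}

#' Simulation configuration
#'
#' Fixed model parameters plus an [annealable_params()] set. Energies are in
#' units of the adult metabolic cost `c_adult` (1.0 per iteration for a
#' mature individual); times are in iteration rounds.
#'
#' @param n_modifier Population size modifier N. Sets the pool generation
#'   rate and the density scale for predation; the realised population size
#'   is stochastic.
#' @param duration Number of iterations per run, D.
#' @param run_times Default replicate count for [run_replicates()].
#' @param gestation Gestation time in iterations (1: offspring are born the
#'   iteration after a successful mating, if the mother survived).
#' @param evolvability_mat,evolvability_die Half-widths of the uniform
#'   multiplicative mutation applied to inherited maturation age and
#'   intrinsic death time.
#' @param c_adult Adult metabolic cost per iteration; the model's energy
#'   scale, 1.0.
#' @param x Predation modifier: the per-individual, per-iteration predation
#'   probability is `min(1, x * (pop_size / n_modifier)^pred_density_exp)`.
#' @param pred_density_exp Exponent of the density dependence of predation.
#'   Values above 1 give a type-III-like response: predation intensifies
#'   superlinearly in crowded populations and relaxes in sparse ones
#'   (a low-density refuge), which stabilises small populations.
#' @param t_mat_init,t_die_init Length-2 ranges for the founders' maturation
#'   age and intrinsic death time (uniform draws).
#' @param fecundity_mode `"declining"`: pregnancy probability falls linearly
#'   from 1 at age `t_mat` to 0 at `t_die` and litters are uniform on
#'   \{1, 2\}; `"increasing"`: pregnancy probability is constant 0.5 and
#'   litter size grows from 1 towards 8 with maternal age.
#' @param storage_factor Individual energy storage cap, as multiples of the
#'   maximum single-iteration foraging intake (size-scaled).
#' @param size_ratio Mature-to-newborn size ratio (mature individuals are
#'   ~50 times larger than newborns).
#' @param e_mature_ref Mature body mass in energy-equivalent units, the
#'   reference for growth costs; a fixed constant (about 50 times a typical
#'   newborn), not tied to the annealable `e_init` (which is the newborn's
#'   starting *stored* energy).
#' @param forage_rate Deterministic part of the stochastic per-iteration
#'   foraging capacity `s^forage_size_exp * (forage_rate + U)`,
#'   `U ~ Uniform(0,1)`, `s` the fractional size.
#' @param forage_size_exp Allometric exponent scaling foraging capacity
#'   (and the storage cap) with fractional size; below 1, small juveniles
#'   forage more per unit mass than adults.
#' @param pool_capacity_factor Shared-pool saturation capacity, as multiples
#'   of the per-iteration generation `n_modifier * c_adult * epsilon`.
#' @param mate_energy_scale Energy scale for the mating-parameter annealing
#'   ranges (see [annealable_params()]).
#' @param founders Founding cohort size (default `n_modifier`), half female.
#' @param record_every Statistics recording interval; `NULL` keeps every
#'   iteration up to 50,000 iterations and every 10th beyond.
#' @param predation_on_start_count Evaluate predation at the
#'   start-of-iteration population count instead of the post-starvation
#'   count.
#' @param repair_spec Repair cost function constants, see [cost_function_spec()].
#' @param annealable An [annealable_params()] object.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(annealable = classical_preset(), x = 0.0025)
#' e_mature(cfg)
#' @export
sim_config <- function(n_modifier = 50, duration = 300000L, run_times = 400L,
                       gestation = 1L, evolvability_mat = 0.2,
                       evolvability_die = 0.2, c_adult = 1.0, x = 0.01,
                       t_mat_init = c(45, 55), t_die_init = c(65, 75),
                       fecundity_mode = c("declining", "increasing"),
                       storage_factor = 5, size_ratio = 50,
                       e_mature_ref = 0.24,
                       forage_rate = 1.6, forage_size_exp = 0.75,
                       pool_capacity_factor = 10,
                       pred_density_exp = 2,
                       mate_energy_scale = 10, founders = NULL,
                       record_every = NULL,
                       predation_on_start_count = FALSE,
                       repair_spec = cost_function_spec(),
                       annealable = annealable_params()) {
  fecundity_mode <- match.arg(fecundity_mode)
  cfg <- list(
    n_modifier = as.numeric(n_modifier), duration = as.integer(duration),
    run_times = as.integer(run_times), gestation = as.integer(gestation),
    evolvability_mat = as.numeric(evolvability_mat),
    evolvability_die = as.numeric(evolvability_die),
    c_adult = as.numeric(c_adult), x = as.numeric(x),
    pred_density_exp = as.numeric(pred_density_exp),
    t_mat_init = as.numeric(t_mat_init), t_die_init = as.numeric(t_die_init),
    fecundity_mode = fecundity_mode,
    storage_factor = as.numeric(storage_factor),
    size_ratio = as.numeric(size_ratio),
    e_mature_ref = as.numeric(e_mature_ref),
    forage_rate = as.numeric(forage_rate),
    forage_size_exp = as.numeric(forage_size_exp),
    pool_capacity_factor = as.numeric(pool_capacity_factor),
    mate_energy_scale = as.numeric(mate_energy_scale),
    founders = if (is.null(founders)) as.integer(round(n_modifier))
               else as.integer(founders),
    record_every = if (is.null(record_every)) NULL else as.integer(record_every),
    predation_on_start_count = isTRUE(predation_on_start_count),
    repair_spec = repair_spec,
    annealable = annealable
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_pos_int <- function(key) {
    v <- cfg[[key]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      stop(sprintf("'%s' = %s must be a positive integer", key, format(v)))
  }
  for (key in c("run_times", "gestation", "founders")) chk_pos_int(key)
  if (cfg$duration < 0) stop("'duration' must be >= 0")
  if (cfg$x < 0) stop(sprintf("'x' = %g: the predation modifier must be >= 0", cfg$x))
  if (cfg$pred_density_exp <= 0) stop("'pred_density_exp' must be > 0")
  if (cfg$n_modifier <= 0) stop("'n_modifier' must be > 0")
  if (cfg$c_adult <= 0) stop("'c_adult' must be > 0")
  if (cfg$size_ratio <= 1) stop("'size_ratio' must exceed 1")
  if (cfg$e_mature_ref <= 0) stop("'e_mature_ref' must be > 0")
  if (cfg$storage_factor <= 0) stop("'storage_factor' must be > 0")
  if (cfg$forage_rate <= 0) stop("'forage_rate' must be > 0")
  if (cfg$forage_size_exp <= 0 || cfg$forage_size_exp > 1)
    stop("'forage_size_exp' must lie in (0, 1]")
  if (cfg$pool_capacity_factor <= 0) stop("'pool_capacity_factor' must be > 0")
  if (cfg$evolvability_mat < 0 || cfg$evolvability_mat >= 1 ||
      cfg$evolvability_die < 0 || cfg$evolvability_die >= 1)
    stop("evolvability constants must lie in [0, 1)")
  if (length(cfg$t_mat_init) != 2L || length(cfg$t_die_init) != 2L ||
      any(diff(cfg$t_mat_init) < 0) || any(diff(cfg$t_die_init) < 0))
    stop("'t_mat_init' and 't_die_init' must be non-decreasing length-2 ranges")
  if (cfg$t_mat_init[2] >= cfg$t_die_init[1])
    stop("the 't_mat_init' range must lie entirely below the 't_die_init' range")
  if (!is.null(cfg$record_every) && cfg$record_every < 1)
    stop("'record_every' must be >= 1")
  validate_annealable(cfg$annealable, cfg$mate_energy_scale)
  invisible(cfg)
}

# Derived quantities ---------------------------------------------------------

#' Derived energy scales of a configuration
#'
#' `e_mature()` is the mature body mass in energy-equivalent units (the
#' fixed reference `e_mature_ref`; mature individuals are ~`size_ratio`
#' times larger than newborns). `pool_capacity()` is the shared pool's
#' saturation cap. `generation_rate()` is the per-iteration pool generation
#' `n_modifier * c_adult * epsilon`. `storage_max()` is the individual
#' energy storage cap, about `storage_factor` iterations of maximum
#' foraging for an individual of fractional size `s`.
#'
#' @param cfg A [sim_config()].
#' @param s Fractional size in `(0, 1]`.
#' @return A numeric scalar (vectorised over `s` for `storage_max`).
#' @export
e_mature <- function(cfg) cfg$e_mature_ref

#' @rdname e_mature
#' @export
generation_rate <- function(cfg) cfg$n_modifier * cfg$c_adult * cfg$annealable$epsilon

#' @rdname e_mature
#' @export
pool_capacity <- function(cfg) cfg$pool_capacity_factor * generation_rate(cfg)

#' @rdname e_mature
#' @export
storage_max <- function(cfg, s = 1)
  cfg$storage_factor * s^cfg$forage_size_exp * (cfg$forage_rate + 1)

# Config file I/O ------------------------------------------------------------

.config_keys <- c("n_modifier", "duration", "run_times", "gestation",
                  "evolvability_mat", "evolvability_die", "c_adult", "x",
                  "pred_density_exp",
                  "t_mat_init", "t_die_init", "fecundity_mode",
                  "storage_factor", "size_ratio", "e_mature_ref", "forage_rate", "forage_size_exp",
                  "pool_capacity_factor", "mate_energy_scale", "founders",
                  "record_every", "predation_on_start_count")
.annealable_keys <- c("epsilon", "growth_eff", "e_mate", "mate_threshold",
                      "e_init", "d_type")

#' Read or write a simulation configuration file
#'
#' Configurations are flat key-value YAML documents whose keys mirror the
#' model symbols (`epsilon`, `growth_eff`, `e_mate`, `mate_threshold`,
#' `e_init`, `d_type`, `n_modifier`, `duration`, `x`, ...). Omitted keys take
#' the [sim_config()] defaults; out-of-range values raise an error naming
#' the key and its allowed range. An empty document yields the full default
#' configuration.
#'
#' @param path File path.
#' @param cfg A [sim_config()].
#' @return `load_config()` returns a validated [sim_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf(
                    "config file '%s' could not be parsed: %s", path,
                    conditionMessage(e))))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop(sprintf("config file '%s' is not a key-value document", path))
  config_from_list(doc)
}

#' Build a configuration from a flat named list
#'
#' @param doc Named list of configuration keys (may be empty).
#' @return A validated [sim_config()].
#' @export
config_from_list <- function(doc) {
  unknown <- setdiff(names(doc), c(.config_keys, .annealable_keys))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  ann_args <- doc[intersect(names(doc), .annealable_keys)]
  cfg_args <- doc[intersect(names(doc), .config_keys)]
  scale <- if (!is.null(cfg_args$mate_energy_scale))
    as.numeric(cfg_args$mate_energy_scale) else 10
  ann <- do.call(annealable_params, c(ann_args, list(mate_energy_scale = scale)))
  do.call(sim_config, c(cfg_args, list(annealable = ann)))
}

#' @rdname load_config
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  doc <- cfg[setdiff(.config_keys, "record_every")]
  if (!is.null(cfg$record_every)) doc$record_every <- cfg$record_every
  doc <- c(doc, unclass(cfg$annealable))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Energy-allocation aging model configuration\n")
  cat(sprintf("  N = %g, D = %d iterations, x = %g, fecundity: %s\n",
              x$n_modifier, x$duration, x$x, x$fecundity_mode))
  a <- x$annealable
  cat(sprintf("  epsilon = %g, growth_eff = %g, e_mate = %g, mate_threshold = %g\n",
              a$epsilon, a$growth_eff, a$e_mate, a$mate_threshold))
  cat(sprintf("  e_init = %g (e_mature = %g), d_type = %d (%s)\n",
              a$e_init, e_mature(x), a$d_type, d_type_label(a$d_type)))
  invisible(x)
}

#' @export
print.annealable_params <- function(x, ...) {
  cat("Annealable parameters:\n")
  cat(sprintf("  epsilon = %g, growth_eff = %g, e_mate = %g,\n", x$epsilon,
              x$growth_eff, x$e_mate))
  cat(sprintf("  mate_threshold = %g, e_init = %g, d_type = %d (%s)\n",
              x$mate_threshold, x$e_init, x$d_type, d_type_label(x$d_type)))
  invisible(x)
}
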