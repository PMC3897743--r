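# Shared fixtures: small configurations for unit tests and a cache for the
# scaled scenario runs used by the acceptance suite (computed once per
# session, shared across test files).

tiny_cfg <- function(n_modifier = 12, founders = 12, duration = 300,
                     x = 0.01, ...) {
  sim_config(n_modifier = n_modifier, founders = founders,
             duration = duration, x = x, ...)
}

# A hand-built population state for stepper-level tests.
make_state <- function(energy, age, female, t_mat, t_die, cfg,
                       gest = rep(FALSE, length(energy)),
                       pool = pool_capacity(cfg)) {
  n <- length(energy)
  list(ind = list(energy = energy, age = age, female = female,
                  t_mat = t_mat, t_die = t_die, gest = gest,
                  mated_iter = rep(0L, n), fa_tmat = rep(0, n),
                  fa_tdie = rep(0, n)),
       pool = pool, iter = 0L)
}

.acc_cache <- new.env(parent = emptyenv())

# Scaled study conditions: N = 50, D = 30,000, n = 20 replicates per level.
acc_scenario <- function(which = c("classical", "nonclassical")) {
  which <- match.arg(which)
  key <- paste0("scen_", which)
  if (!is.null(.acc_cache[[key]])) return(.acc_cache[[key]])
  preset <- if (which == "classical") classical_preset()
            else nonclassical_preset()
  xs <- if (which == "classical") c(0.0025, 0.04) else c(0.0025, 0.02)
  cfg <- sim_config(annealable = preset, duration = 30000L)
  scen <- run_scenario(cfg, xs, n = 20L, master_seed = 20251L)
  .acc_cache[[key]] <- scen
  scen
}

acc_survival_screen <- function() {
  if (!is.null(.acc_cache$screen)) return(.acc_cache$screen)
  cfg <- sim_config(annealable = classical_preset(), duration = 30000L,
                    x = 0.04)
  .acc_cache$screen <- run_replicates(cfg, n = 50L, master_seed = 20252L)
  .acc_cache$screen
}

# Planted annealing objective: the slope of mean T_die against the predation
# level changes sign at a planted neutral point in epsilon, so only the
# region above the neutral point produces the increasing (non-classical)
# trend the search is rewarded for; below it the score surface is
# flat-to-opposed. The optimum's basin is epsilon above the neutral point.
planted_stub <- function(neutral = 1.8, sd = 0.05) {
  function(params, x, seed) {
    set.seed(seed)
    idx <- match(x, c(0.0025, 0.005, 0.01, 0.02, 0.04))
    list(mean_t_die = 70 + (params$epsilon - neutral) * idx +
           rnorm(1, 0, sd),
         extinct = FALSE)
  }
}
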