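# Pure-R reference implementation of the per-iteration schedule. It mirrors
# the compiled engine draw-for-draw and expression-for-expression, so a run
# from the same seed produces a bit-identical trajectory; the test suite
# pins this identity. It is intentionally written as explicit loops over
# individuals (clarity over speed) and is only meant for short runs.

.stat_cols <- c("iteration", "pop", "pool", "births", "starved", "eaten",
                "aged", "mean_t_mat", "mean_t_die", "mean_energy_mature",
                "juv_maint", "juv_matur", "juv_metab", "mat_maint",
                "mat_repro", "mat_metab", "pred_frac", "generated",
                "foraged", "cost_total", "mating_total")

#' Founding population
#'
#' A cohort of age-0 newborns with energy `e_init`, alternating
#' female/male (so the sexes are exactly balanced for even counts),
#' maturation ages uniform on `t_mat_init` and intrinsic death times
#' uniform on `t_die_init` (all independent).
#'
#' @param cfg A [sim_config()].
#' @return A population state: list of parallel vectors `energy`, `age`,
#'   `female`, `t_mat`, `t_die`, `gest`, `mated_iter`, `fa_tmat`, `fa_tdie`.
#' @export
init_population <- function(cfg) {
  n <- cfg$founders
  t_mat <- runif(n, cfg$t_mat_init[1], cfg$t_mat_init[2])
  t_die <- runif(n, cfg$t_die_init[1], cfg$t_die_init[2])
  list(energy = rep(cfg$annealable$e_init, n), age = rep(0, n),
       female = rep(c(TRUE, FALSE), length.out = n),
       t_mat = t_mat, t_die = t_die,
       gest = rep(FALSE, n), mated_iter = rep(0L, n),
       fa_tmat = rep(0, n), fa_tdie = rep(0, n))
}

# Fisher-Yates permutation using floor(u * i); identical to the engine's.
.fy_permute <- function(n) {
  perm <- seq_len(n)
  if (n >= 2) {
    for (i in n:2) {
      j <- floor(runif(1) * i) + 1
      if (j > i) j <- i
      tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
    }
  }
  perm
}

.keep <- function(ind, keep) {
  lapply(ind, function(v) v[keep])
}

#' Advance the model by one iteration (reference stepper)
#'
#' Executes one full iteration: pool generation; per-individual cost
#' deduction then foraging in a fresh random order; starvation, predation
#' and intrinsic-death removals; mating; births from females that finished
#' gestating; age increment; statistics.
#'
#' @param state A list with elements `ind` (see [init_population()]),
#'   `pool` and `iter`.
#' @param cfg A [sim_config()].
#' @return The updated state, with a named `stats` vector, the iteration's
#'   death records (`deaths`) and the `extinct` flag.
#' @export
sim_step <- function(state, cfg) {
  ind <- state$ind
  pool <- state$pool
  t <- state$iter + 1L
  a_par <- cfg$annealable
  thr <- a_par$mate_threshold
  em <- e_mature(cfg)
  fec_inc <- cfg$fecundity_mode == "increasing"

  # 1. pool generation
  pool_before <- pool
  pool <- min(pool + generation_rate(cfg), pool_capacity(cfg))
  generated <- pool - pool_before

  n_start <- length(ind$energy)
  perm <- .fy_permute(n_start)

  juv_rep <- 0; juv_mat <- 0; juv_met <- 0
  mat_rep <- 0; mat_met <- 0; mat_repro <- 0
  foraged_total <- 0; cost_total <- 0

  # 2. costs then foraging, in permuted order
  for (i in perm) {
    a <- ind$age[i]; tm <- ind$t_mat[i]; td <- ind$t_die[i]
    s <- fractional_size(a, tm, cfg)
    rep_c <- s * repair_cost_base(td, a_par$d_type, cfg$repair_spec)
    mat_c <- if (a >= tm) 0 else {
      s_next <- fractional_size(a + 1, tm, cfg)
      em * (s_next - s) / a_par$growth_eff
    }
    met_c <- cfg$c_adult * s
    total <- rep_c + mat_c + met_c
    if (a < tm) {
      juv_rep <- juv_rep + rep_c; juv_mat <- juv_mat + mat_c
      juv_met <- juv_met + met_c
    } else {
      mat_rep <- mat_rep + rep_c; mat_met <- mat_met + met_c
    }
    ind$energy[i] <- ind$energy[i] - total
    cost_total <- cost_total + total

    out <- forage(ind$energy[i], s, pool, cfg)
    ind$energy[i] <- out$energy
    pool <- out$pool
    foraged_total <- foraged_total + out$gained
  }

  rec_deaths <- function(ind, mask, cause) {
    if (!any(mask)) return(NULL)
    data.frame(iteration = t, cause = cause,
               age_at_death = ind$age[mask], t_die = ind$t_die[mask],
               t_mat = ind$t_mat[mask])
  }

  # 3. starvation
  starved_mask <- is_starved(ind$energy)
  starved <- sum(starved_mask)
  deaths <- rec_deaths(ind, starved_mask, "starved")
  ind <- .keep(ind, !starved_mask)

  # 4. predation
  n2 <- length(ind$energy)
  dens_count <- if (cfg$predation_on_start_count) n_start else n2
  eaten_mask <- predation_draw(n2, cfg, pop_size = dens_count)
  eaten <- sum(eaten_mask)
  pred_frac <- if (n2 > 0) eaten / n2 else NA_real_
  deaths <- rbind(deaths, rec_deaths(ind, eaten_mask, "eaten"))
  ind <- .keep(ind, !eaten_mask)

  # 5. intrinsic aging death
  aged_mask <- is_aged(ind$age, ind$t_die)
  aged <- sum(aged_mask)
  deaths <- rbind(deaths, rec_deaths(ind, aged_mask, "aged"))
  ind <- .keep(ind, !aged_mask)

  # 6. mating
  mature <- ind$age >= ind$t_mat
  F_idx <- which(ind$female & mature & ind$energy > thr & !ind$gest)
  M_idx <- which(!ind$female & mature)
  F_idx <- F_idx[.fy_permute(length(F_idx))]
  mating_total <- 0
  for (f in F_idx) {
    tried <- rep(FALSE, length(M_idx))
    while (ind$energy[f] > thr && !ind$gest[f]) {
      avail <- which(!tried & ind$energy[M_idx] > thr)
      if (length(avail) == 0L) break
      j <- floor(runif(1) * length(avail)) + 1
      if (j > length(avail)) j <- length(avail)
      km <- avail[j]
      m <- M_idx[km]
      tried[km] <- TRUE
      ind$energy[f] <- ind$energy[f] - a_par$e_mate
      ind$energy[m] <- ind$energy[m] - a_par$e_mate
      mat_repro <- mat_repro + 2 * a_par$e_mate
      mating_total <- mating_total + 2 * a_par$e_mate
      pp <- if (fec_inc) 0.5 else
        min(1, max(0, (ind$t_die[f] - ind$age[f]) /
                        (ind$t_die[f] - ind$t_mat[f])))
      if (runif(1) < pp) {
        ind$gest[f] <- TRUE
        ind$mated_iter[f] <- t
        ind$fa_tmat[f] <- ind$t_mat[m]
        ind$fa_tdie[f] <- ind$t_die[m]
      }
    }
  }

  # 7. births
  born <- list(energy = numeric(0), age = numeric(0), female = logical(0),
               t_mat = numeric(0), t_die = numeric(0))
  births <- 0L
  due <- which(ind$female & ind$gest & (t - ind$mated_iter >= cfg$gestation))
  for (i in due) {
    litter <- litter_size(ind$age[i], ind$t_mat[i], ind$t_die[i], cfg)
    for (z in seq_len(litter)) {
      tr <- inherit_traits(
        list(t_mat = ind$t_mat[i], t_die = ind$t_die[i]),
        list(t_mat = ind$fa_tmat[i], t_die = ind$fa_tdie[i]), cfg)
      fem <- runif(1) < 0.5
      born$energy <- c(born$energy, a_par$e_init)
      born$age <- c(born$age, 0)
      born$female <- c(born$female, fem)
      born$t_mat <- c(born$t_mat, tr$t_mat)
      born$t_die <- c(born$t_die, tr$t_die)
    }
    ind$gest[i] <- FALSE
    births <- births + litter
  }

  # 8. age increment for pre-existing individuals; newborns appended
  ind$age <- ind$age + 1
  nb <- length(born$energy)
  if (nb > 0) {
    ind$energy <- c(ind$energy, born$energy)
    ind$age <- c(ind$age, born$age)
    ind$female <- c(ind$female, born$female)
    ind$t_mat <- c(ind$t_mat, born$t_mat)
    ind$t_die <- c(ind$t_die, born$t_die)
    ind$gest <- c(ind$gest, rep(FALSE, nb))
    ind$mated_iter <- c(ind$mated_iter, rep(0L, nb))
    ind$fa_tmat <- c(ind$fa_tmat, rep(0, nb))
    ind$fa_tdie <- c(ind$fa_tdie, rep(0, nb))
  }

  # 9. statistics
  np <- length(ind$energy)
  mature_now <- ind$age >= ind$t_mat
  juv_tot <- juv_rep + juv_mat + juv_met
  mat_tot <- mat_rep + mat_repro + mat_met
  stats <- c(
    iteration = t, pop = np, pool = pool, births = births,
    starved = starved, eaten = eaten, aged = aged,
    mean_t_mat = if (np > 0) sum(ind$t_mat) / np else NA_real_,
    mean_t_die = if (np > 0) sum(ind$t_die) / np else NA_real_,
    mean_energy_mature = if (any(mature_now))
      sum(ind$energy[mature_now]) / sum(mature_now) else NA_real_,
    juv_maint = if (juv_tot > 0) juv_rep / juv_tot else NA_real_,
    juv_matur = if (juv_tot > 0) juv_mat / juv_tot else NA_real_,
    juv_metab = if (juv_tot > 0) juv_met / juv_tot else NA_real_,
    mat_maint = if (mat_tot > 0) mat_rep / mat_tot else NA_real_,
    mat_repro = if (mat_tot > 0) mat_repro / mat_tot else NA_real_,
    mat_metab = if (mat_tot > 0) mat_met / mat_tot else NA_real_,
    pred_frac = pred_frac, generated = generated, foraged = foraged_total,
    cost_total = cost_total, mating_total = mating_total)

  list(ind = ind, pool = pool, iter = t, stats = stats, deaths = deaths,
       extinct = np == 0L)
}

#' Run the reference stepper for several iterations
#'
#' Slow pure-R counterpart of [run_simulation()], used to cross-validate the
#' compiled engine: from the same seed both produce identical trajectories.
#'
#' @param cfg A [sim_config()].
#' @param iterations Number of iterations (defaults to `cfg$duration`).
#' @param seed Optional RNG seed.
#' @return A list with the per-iteration `stats` matrix, the accumulated
#'   death records, the final `state`, and the `extinct` flag.
#' @export
run_reference <- function(cfg, iterations = cfg$duration, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- list(ind = init_population(cfg), pool = pool_capacity(cfg),
                iter = 0L)
  rows <- vector("list", iterations)
  drows <- vector("list", iterations)
  extinct <- length(state$ind$energy) == 0L
  n_used <- 0L
  for (k in seq_len(iterations)) {
    if (extinct) break
    state <- sim_step(state, cfg)
    n_used <- n_used + 1L
    rows[[k]] <- state$stats
    drows[[k]] <- state$deaths
    extinct <- state$extinct
  }
  stats <- if (n_used > 0) do.call(rbind, rows[seq_len(n_used)]) else
    matrix(numeric(0), 0, length(.stat_cols),
           dimnames = list(NULL, .stat_cols))
  deaths <- do.call(rbind, drows[seq_len(n_used)])
  list(stats = stats, deaths = deaths, state = state, extinct = extinct)
}
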