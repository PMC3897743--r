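# Replicate runner, RNG management, statistics containers.

.default_record_every <- function(cfg) {
  if (!is.null(cfg$record_every)) return(cfg$record_every)
  if (cfg$duration <= 50000L) 1L else 10L
}

.engine_par <- function(cfg) {
  a <- cfg$annealable
  rs <- cfg$repair_spec
  list(n_modifier = cfg$n_modifier, c_adult = cfg$c_adult, x = cfg$x,
       pred_density_exp = cfg$pred_density_exp,
       evolvability_mat = cfg$evolvability_mat,
       evolvability_die = cfg$evolvability_die,
       size_ratio = cfg$size_ratio, storage_factor = cfg$storage_factor,
       forage_rate = cfg$forage_rate,
       forage_size_exp = cfg$forage_size_exp,
       pool_cap = pool_capacity(cfg),
       gen_rate = generation_rate(cfg), growth_eff = a$growth_eff,
       e_mate = a$e_mate, mate_threshold = a$mate_threshold,
       e_init = a$e_init, e_mature = e_mature(cfg),
       gestation = cfg$gestation, d_type = a$d_type,
       fec_increasing = as.integer(cfg$fecundity_mode == "increasing"),
       pred_on_start = as.integer(cfg$predation_on_start_count),
       max_redraw = 10L,
       d_scale = rs$scale, d_lin_tref = rs$linear_tref,
       d_asym_half = rs$asym_half, d_sig_mid = rs$sig_mid,
       d_sig_width = rs$sig_width, d_high_factor = rs$high_factor)
}

#' Run one simulation
#'
#' Runs the full per-iteration schedule (pool generation; costs then
#' foraging in random order; starvation, predation and intrinsic-death
#' removals; mating; births; aging) for `cfg$duration` iterations or until
#' extinction, starting from a fresh founding cohort and a full pool.
#' The hot loop is compiled; [run_reference()] is the pure-R twin.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed; a fixed seed makes the whole
#'   trajectory reproducible bit-for-bit.
#' @return An object of class `aging_sim`: list with `stats` (data.frame,
#'   one row per recorded iteration: population size, pool energy, births,
#'   deaths by cause, population mean maturation age and death time, mean
#'   mature energy, juvenile and mature energy-allocation fractions,
#'   realised predation fraction, and the iteration energy ledger),
#'   `deaths` (one record per removed individual: iteration, cause —
#'   starved / eaten / aged — age at death and inherited trait values), the
#'   final population (`t_mat`, `t_die`, `energy`, `age`, `female`),
#'   `extinct`, `extinct_iter`, `record_every` and `seed`.
#' @examples
#' cfg <- sim_config(annealable = classical_preset(), duration = 500,
#'                   x = 0.0025)
#' sim <- run_simulation(cfg, seed = 1)
#' summary(sim)
#' @export
run_simulation <- function(cfg, seed = NULL) {
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  rec <- .default_record_every(cfg)
  ind <- init_population(cfg)
  res <- .engine_run(.engine_par(cfg), ind$energy, ind$age,
                     as.integer(ind$female), ind$t_mat, ind$t_die,
                     pool_capacity(cfg), cfg$duration, rec)
  stats <- as.data.frame(res$stats)
  names(stats) <- .stat_cols
  deaths <- data.frame(
    iteration = res$death_iter,
    cause = c("starved", "eaten", "aged")[res$death_cause],
    age_at_death = res$death_age, t_die = res$death_tdie,
    t_mat = res$death_tmat)
  out <- list(stats = stats, deaths = deaths,
              final = list(t_mat = res$t_mat, t_die = res$t_die,
                           energy = res$energy, age = res$age,
                           female = as.logical(res$female)),
              pool = res$pool, extinct = res$extinct,
              extinct_iter = res$extinct_iter,
              record_every = rec, seed = if (is.null(seed)) NA_integer_
                                         else as.integer(seed),
              config = cfg)
  class(out) <- "aging_sim"
  out
}

#' Tail average of a recorded statistic
#'
#' Mean of the last `last_m` recorded values of a statistic column,
#' the smoothing used both for reporting steady-state values and for the
#' annealing objective.
#'
#' @param sim An `aging_sim` object.
#' @param column Column of `sim$stats`.
#' @param last_m Number of trailing recorded rows to average.
#' @return A scalar (NA when nothing was recorded).
#' @export
tail_mean <- function(sim, column = "mean_t_die", last_m = 1000L) {
  v <- sim$stats[[column]]
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  mean(v[max(1L, n - last_m + 1L):n])
}

#' Run independent replicate simulations
#'
#' Runs `n` independent simulations whose seeds are derived
#' deterministically from `master_seed`, and aggregates them: per-time-point
#' trajectory means over the replicates still alive, the survival fraction
#' over time, pooled final trait distributions, and per-replicate
#' steady-state summaries (tail averages over the last `last_m` recorded
#' rows).
#'
#' @param cfg A [sim_config()].
#' @param n Number of replicates (defaults to `cfg$run_times`).
#' @param master_seed Integer master seed.
#' @param last_m Tail window for steady-state summaries.
#' @param keep_runs Keep the individual `aging_sim` objects (memory-hungry
#'   for long runs).
#' @return An object of class `aging_replicates`: list with `summary` (one
#'   row per replicate), `survival` (data.frame: iteration, fraction of
#'   replicates alive), `trajectory` (data.frame of across-replicate means
#'   of the recorded statistics at each recorded iteration, surviving
#'   replicates only), pooled `final_t_die` / `final_t_mat`, `n_extinct`,
#'   and optionally `runs`.
#' @export
run_replicates <- function(cfg, n = cfg$run_times, master_seed = 1L,
                           last_m = 1000L, keep_runs = FALSE) {
  stopifnot(n >= 1)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max, n)
  runs <- vector("list", n)
  for (i in seq_len(n)) runs[[i]] <- run_simulation(cfg, seed = seeds[i])

  summ <- data.frame(
    replicate = seq_len(n), seed = seeds,
    extinct = vapply(runs, function(r) r$extinct, logical(1)),
    extinct_iter = vapply(runs, function(r)
      if (r$extinct) r$extinct_iter else NA_integer_, integer(1)),
    final_mean_t_die = vapply(runs, function(r)
      if (length(r$final$t_die)) mean(r$final$t_die) else NA_real_,
      numeric(1)),
    final_mean_t_mat = vapply(runs, function(r)
      if (length(r$final$t_mat)) mean(r$final$t_mat) else NA_real_,
      numeric(1)),
    final_cv_t_die = vapply(runs, function(r)
      if (length(r$final$t_die) > 1)
        sd(r$final$t_die) / mean(r$final$t_die) else NA_real_,
      numeric(1)),
    tail_t_die = vapply(runs, tail_mean, numeric(1), column = "mean_t_die",
                        last_m = last_m),
    tail_t_mat = vapply(runs, tail_mean, numeric(1), column = "mean_t_mat",
                        last_m = last_m))
  for (col in c("pop", "pool", "births", "mean_energy_mature", "juv_maint",
                "juv_matur", "juv_metab", "mat_maint", "mat_repro",
                "mat_metab", "pred_frac")) {
    summ[[paste0("tail_", col)]] <-
      vapply(runs, tail_mean, numeric(1), column = col, last_m = last_m)
  }

  # common recording grid (all replicates share duration and interval)
  grid <- runs[[which.max(vapply(runs, function(r) nrow(r$stats),
                                 integer(1)))]]$stats$iteration
  alive_at <- function(r, it) !r$extinct | r$extinct_iter > it
  surv <- vapply(grid, function(it)
    mean(vapply(runs, alive_at, logical(1), it = it)), numeric(1))

  traj <- NULL
  if (length(grid)) {
    cols <- setdiff(.stat_cols, "iteration")
    traj <- data.frame(iteration = grid)
    mats <- lapply(runs, function(r) {
      m <- as.matrix(r$stats[match(grid, r$stats$iteration), cols])
      m
    })
    arr <- array(unlist(mats), dim = c(length(grid), length(cols), n))
    for (k in seq_along(cols))
      traj[[cols[k]]] <- rowMeans(arr[, k, , drop = FALSE], na.rm = TRUE)
  }

  surviving <- !summ$extinct
  out <- list(
    summary = summ,
    survival = data.frame(iteration = grid, fraction_alive = surv),
    trajectory = traj,
    final_t_die = unlist(lapply(runs[surviving], function(r) r$final$t_die)),
    final_t_mat = unlist(lapply(runs[surviving], function(r) r$final$t_mat)),
    n_extinct = sum(summ$extinct), n = n, master_seed = master_seed,
    config = cfg)
  if (keep_runs) out$runs <- runs
  class(out) <- "aging_replicates"
  out
}

# S3 methods -----------------------------------------------------------------

#' @export
print.aging_sim <- function(x, ...) {
  cat("Agent-based aging simulation\n")
  cat(sprintf("  %d iterations requested, x = %g, seed = %s\n",
              x$config$duration, x$config$x, format(x$seed)))
  if (x$extinct) {
    cat(sprintf("  population went extinct at iteration %d\n", x$extinct_iter))
  } else {
    cat(sprintf("  final population: %d individuals\n", length(x$final$t_die)))
    cat(sprintf("  final mean T_mat = %.2f, mean T_die = %.2f\n",
                mean(x$final$t_mat), mean(x$final$t_die)))
  }
  invisible(x)
}

#' @export
summary.aging_sim <- function(object, last_m = 1000L, ...) {
  out <- list(
    extinct = object$extinct,
    final_pop = length(object$final$t_die),
    mean_t_die = tail_mean(object, "mean_t_die", last_m),
    mean_t_mat = tail_mean(object, "mean_t_mat", last_m),
    mean_pop = tail_mean(object, "pop", last_m),
    mean_pool = tail_mean(object, "pool", last_m),
    mean_energy_mature = tail_mean(object, "mean_energy_mature", last_m),
    pred_frac = tail_mean(object, "pred_frac", last_m))
  class(out) <- "summary.aging_sim"
  out
}

#' @export
print.summary.aging_sim <- function(x, ...) {
  cat("Steady-state (tail-averaged) simulation summary\n")
  cat(sprintf("  population: %.1f alive, pool energy %.1f%s\n", x$mean_pop,
              x$mean_pool, if (x$extinct) " (extinct)" else ""))
  cat(sprintf("  mean T_mat = %.2f, mean T_die = %.2f\n",
              x$mean_t_mat, x$mean_t_die))
  cat(sprintf("  mean mature energy = %.2f, predation fraction = %.4f\n",
              x$mean_energy_mature, x$pred_frac))
  invisible(x)
}

#' @export
plot.aging_sim <- function(x, which = c("pop", "mean_t_die", "mean_t_mat",
                                        "pool"), ...) {
  which <- match.arg(which, choices = names(x$stats), several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (w in which)
    graphics::plot(x$stats$iteration, x$stats[[w]], type = "l",
                   xlab = "iteration", ylab = w, ...)
  invisible(x)
}

#' @export
print.aging_replicates <- function(x, ...) {
  cat(sprintf("Aging-model replicates: n = %d, x = %g, %d extinct\n",
              x$n, x$config$x, x$n_extinct))
  ok <- !x$summary$extinct
  if (any(ok)) {
    cat(sprintf("  surviving mean final T_die = %.2f, T_mat = %.2f\n",
                mean(x$summary$final_mean_t_die[ok]),
                mean(x$summary$final_mean_t_mat[ok])))
  }
  invisible(x)
}

#' @export
plot.aging_replicates <- function(x, column = "mean_t_die", ...) {
  graphics::plot(x$trajectory$iteration, x$trajectory[[column]], type = "l",
                 xlab = "iteration", ylab = paste("mean", column), ...)
  invisible(x)
}

#' Export simulation outputs as plain-text files
#'
#' Writes the recorded statistics time series, the per-individual death
#' records (for survival-curve analyses) and the final trait samples of a
#' run, all as CSV.
#'
#' @param sim An `aging_sim` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory path, invisibly.
#' @export
export_run <- function(sim, dir, prefix = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sim$stats, file.path(dir, paste0(prefix, "_stats.csv")),
            row.names = FALSE)
  fin <- data.frame(t_mat = sim$final$t_mat, t_die = sim$final$t_die,
                    age = sim$final$age, energy = sim$final$energy,
                    female = sim$final$female)
  write.csv(fin, file.path(dir, paste0(prefix, "_final.csv")),
            row.names = FALSE)
  write.csv(sim$deaths, file.path(dir, paste0(prefix, "_deaths.csv")),
            row.names = FALSE)
  invisible(dir)
}
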