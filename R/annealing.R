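# Simulated-annealing search over the six annealable parameters, with
# monotonic-trend scoring of the evolved mean intrinsic death time across
# five predation levels, Metropolis acceptance, geometric cooling and the
# extinction-discard rule.

.default_x_levels <- c(0.0025, 0.005, 0.01, 0.02, 0.04)

#' Evaluate a candidate parameter set across predation levels
#'
#' For each predation level, runs `runs_per_level` independent simulations;
#' each contributes the mean of its last `last_m` recorded population-mean
#' intrinsic death times, and the level value is the mean over non-extinct
#' runs. The evaluation is invalid (and the annealer discards the candidate
#' without cooling) when every run at some level went extinct.
#'
#' @param params An [annealable_params()] candidate.
#' @param cfg A [sim_config()] providing the fixed parameters (its
#'   `duration` controls the per-run length, so scaled-down evaluations are
#'   configured there).
#' @param x_levels Predation modifiers, in increasing order.
#' @param runs_per_level Independent simulations per level.
#' @param last_m Tail window of recorded mean-T_die values averaged per run.
#' @param simulate_fn Simulator hook: `function(params, x, seed)` returning
#'   a list with `mean_t_die` (scalar tail average) and `extinct`. The
#'   default runs the full engine; tests substitute planted stubs.
#' @return A list of class `objective_evaluation`: `mean_t_die_by_x`,
#'   `n_extinct`, `valid`, `x_levels`.
#' @export
evaluate_params <- function(params, cfg, x_levels = .default_x_levels,
                            runs_per_level = 8L, last_m = 1000L,
                            simulate_fn = NULL) {
  if (is.null(simulate_fn)) {
    simulate_fn <- function(params, x, seed) {
      cfg_x <- cfg
      cfg_x$x <- x
      cfg_x$annealable <- params
      validate_config(cfg_x)
      sim <- run_simulation(cfg_x, seed = seed)
      list(mean_t_die = tail_mean(sim, "mean_t_die", last_m),
           extinct = sim$extinct)
    }
  }
  vals <- numeric(length(x_levels))
  n_extinct <- 0L
  valid <- TRUE
  seeds <- sample.int(.Machine$integer.max, length(x_levels) * runs_per_level)
  k <- 0L
  for (ix in seq_along(x_levels)) {
    lv <- rep(NA_real_, runs_per_level)
    for (r in seq_len(runs_per_level)) {
      k <- k + 1L
      out <- simulate_fn(params, x_levels[ix], seeds[k])
      if (isTRUE(out$extinct)) n_extinct <- n_extinct + 1L
      else lv[r] <- out$mean_t_die
    }
    ok <- !is.na(lv)
    if (!any(ok)) { valid <- FALSE; vals[ix] <- NA_real_ }
    else vals[ix] <- mean(lv[ok])
  }
  structure(list(mean_t_die_by_x = vals, n_extinct = n_extinct,
                 valid = valid, x_levels = x_levels),
            class = "objective_evaluation")
}

#' Monotonic-trend score of an evaluated candidate
#'
#' Indicator-based score of the five-level mean-T_die sequence: one point
#' for a net change in the objective's direction between the lowest and
#' highest predation level, one point per consecutive step in that
#' direction, and a bonus point when the whole sequence is monotone.
#' Only directions of change matter (the score is invariant to adding a
#' constant to all levels); higher is better, maximum `length(x) + 1`.
#'
#' @param evaluation An `objective_evaluation` (or a bare numeric sequence).
#' @param objective `"classical"` (reward decreases with predation) or
#'   `"nonclassical"` (reward increases).
#' @return Integer score.
#' @export
score_trend <- function(evaluation,
                        objective = c("classical", "nonclassical")) {
  objective <- match.arg(objective)
  vals <- if (inherits(evaluation, "objective_evaluation")) {
    if (!evaluation$valid) stop("cannot score an invalid (all-extinct) evaluation")
    evaluation$mean_t_die_by_x
  } else as.numeric(evaluation)
  dir <- if (objective == "nonclassical") 1 else -1
  d <- dir * diff(vals)
  net <- dir * (vals[length(vals)] - vals[1])
  sum(d > 0) + (net > 0) + all(d > 0)
}

#' Metropolis acceptance rule
#'
#' A candidate replacing the current parameter set is accepted with
#' probability `min(1, exp((candidate - current) / temperature))`:
#' improvements always, deteriorations with a probability that vanishes as
#' the temperature cools.
#'
#' @param candidate_score,current_score Scores.
#' @param temperature Current annealing temperature (> 0).
#' @param u Uniform variate (drawn when omitted).
#' @return Logical.
#' @export
sa_accept <- function(candidate_score, current_score, temperature,
                      u = runif(1)) {
  stopifnot(temperature > 0)
  delta <- candidate_score - current_score
  if (delta > 0) TRUE else u < exp(delta / temperature)
}

#' Acceptance probability of the Metropolis rule
#' @rdname sa_accept
#' @export
sa_accept_probability <- function(candidate_score, current_score,
                                  temperature) {
  min(1, exp((candidate_score - current_score) / temperature))
}

#' Propose a neighbouring parameter set
#'
#' Perturbs each continuous parameter independently by a uniform step within
#' +/- `step_frac` of its allowed range, reflecting at the bounds; the
#' repair-cost shape `d_type` is resampled uniformly over 0..5 with
#' probability `d_type_prob`.
#'
#' @param params Current [annealable_params()].
#' @param step_frac Relative step size.
#' @param d_type_prob Probability of resampling the cost-function shape.
#' @param mate_energy_scale Energy scale of the mating ranges.
#' @return A new [annealable_params()].
#' @export
propose_params <- function(params, step_frac = 0.1, d_type_prob = 0.2,
                           mate_energy_scale = 10) {
  rng <- .annealable_ranges(mate_energy_scale)
  reflect <- function(v, lo, hi) {
    while (v < lo || v > hi) {
      if (v < lo) v <- lo + (lo - v)
      if (v > hi) v <- hi - (v - hi)
    }
    v
  }
  out <- params
  for (key in c("epsilon", "growth_eff", "e_mate", "mate_threshold",
                "e_init")) {
    r <- rng[[key]]
    step <- runif(1, -step_frac, step_frac) * (r[2] - r[1])
    out[[key]] <- reflect(params[[key]] + step, r[1], r[2])
  }
  if (runif(1) < d_type_prob) out$d_type <- sample.int(6L, 1L) - 1L
  out
}

#' Cooling schedule length
#'
#' Number of annealing rounds executed by a geometric schedule starting at
#' `t0`, multiplied by `cooling` each round, and stopping once the
#' temperature falls below `t_min`. With the defaults (100, 0.95, 0.5) the
#' schedule runs 104 rounds.
#'
#' @param t0 Initial temperature.
#' @param cooling Per-round multiplier in (0, 1).
#' @param t_min Stopping temperature.
#' @return Integer round count.
#' @export
cooling_rounds <- function(t0 = 100, cooling = 0.95, t_min = 0.5) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, t_min > 0, t_min <= t0)
  n <- 0L
  temp <- t0
  while (temp >= t_min) { n <- n + 1L; temp <- t0 * cooling^n }
  n
}

#' Simulated-annealing search for a predation-response regime
#'
#' Searches the six annealable parameters for a set under which the evolved
#' mean intrinsic death time decreases (`"classical"`) or increases
#' (`"nonclassical"`) across the five predation levels. Each round proposes
#' a neighbour, evaluates it ([evaluate_params()]), scores the trend
#' ([score_trend()]) and applies Metropolis acceptance at the current
#' temperature; the temperature is multiplied by `cooling` after each
#' round and the search stops below `t_min` (104 rounds with the
#' defaults). Candidates whose evaluation is invalid (all runs extinct at
#' some level) are discarded without advancing the schedule.
#'
#' @param objective `"classical"` or `"nonclassical"`.
#' @param cfg A [sim_config()] for the underlying simulations.
#' @param master_seed Integer seed for the whole search.
#' @param t0,cooling,t_min Cooling schedule (see [cooling_rounds()]).
#' @param x_levels,runs_per_level,last_m,simulate_fn Passed to
#'   [evaluate_params()].
#' @param init Optional starting [annealable_params()] (defaults to
#'   range midpoints).
#' @param max_rounds Optional cap on the number of rounds (scaled-down
#'   searches); the full schedule otherwise.
#' @param max_invalid Safety cap on consecutive discarded candidates.
#' @param step_frac,d_type_prob Proposal tuning, see [propose_params()].
#' @return An object of class `aging_anneal`: `best` / `current` parameter
#'   sets with scores, the per-round `trace` data.frame (round,
#'   temperature, parameters, score, accepted, monotone flag) and the
#'   schedule settings.
#' @export
anneal <- function(objective = c("classical", "nonclassical"), cfg,
                   master_seed = 1L, t0 = 100, cooling = 0.95, t_min = 0.5,
                   x_levels = .default_x_levels, runs_per_level = 8L,
                   last_m = 1000L, simulate_fn = NULL, init = NULL,
                   max_rounds = Inf, max_invalid = 200L,
                   step_frac = 0.1, d_type_prob = 0.2) {
  objective <- match.arg(objective)
  set.seed(master_seed)
  scale <- cfg$mate_energy_scale
  if (is.null(init)) {
    rng <- .annealable_ranges(scale)
    init <- annealable_params(
      epsilon = mean(rng$epsilon), growth_eff = mean(rng$growth_eff),
      e_mate = mean(rng$e_mate), mate_threshold = mean(rng$mate_threshold),
      e_init = mean(rng$e_init), d_type = 2L, mate_energy_scale = scale)
  }
  ev0 <- evaluate_params(init, cfg, x_levels, runs_per_level, last_m,
                         simulate_fn)
  if (!ev0$valid)
    stop("initial parameter set is unstable (all runs extinct); choose another start")
  cur <- list(params = init, score = score_trend(ev0, objective))
  best <- cur
  n_rounds <- min(cooling_rounds(t0, cooling, t_min), max_rounds)

  trace <- vector("list", n_rounds)
  round_i <- 0L
  invalid_streak <- 0L
  while (round_i < n_rounds) {
    temp <- t0 * cooling^round_i
    cand <- propose_params(cur$params, step_frac, d_type_prob, scale)
    ev <- evaluate_params(cand, cfg, x_levels, runs_per_level, last_m,
                          simulate_fn)
    if (!ev$valid) {
      # discard without temperature change
      invalid_streak <- invalid_streak + 1L
      if (invalid_streak >= max_invalid) {
        warning("stopping early: too many consecutive unstable candidates")
        break
      }
      next
    }
    invalid_streak <- 0L
    sc <- score_trend(ev, objective)
    acc <- sa_accept(sc, cur$score, temp)
    if (acc) cur <- list(params = cand, score = sc)
    if (sc > best$score && acc) best <- list(params = cand, score = sc)
    dirsign <- if (objective == "nonclassical") 1 else -1
    round_i <- round_i + 1L
    trace[[round_i]] <- data.frame(
      round = round_i, temperature = temp,
      epsilon = cand$epsilon, growth_eff = cand$growth_eff,
      e_mate = cand$e_mate, mate_threshold = cand$mate_threshold,
      e_init = cand$e_init, d_type = cand$d_type,
      score = sc, accepted = acc,
      monotone = all(dirsign * diff(ev$mean_t_die_by_x) > 0),
      n_extinct = ev$n_extinct)
  }
  trace <- do.call(rbind, trace[seq_len(round_i)])
  out <- list(objective = objective, best = best, current = cur,
              trace = trace, rounds = round_i,
              t0 = t0, cooling = cooling, t_min = t_min,
              master_seed = master_seed)
  class(out) <- "aging_anneal"
  out
}

#' @export
print.aging_anneal <- function(x, ...) {
  cat(sprintf("Simulated-annealing search (%s objective), %d rounds\n",
              x$objective, x$rounds))
  cat(sprintf("  best score %g with parameters:\n", x$best$score))
  print(x$best$params)
  invisible(x)
}

#' @export
plot.aging_anneal <- function(x, ...) {
  graphics::plot(x$trace$round, x$trace$score, type = "p",
                 pch = ifelse(x$trace$monotone, 19, 1),
                 xlab = "annealing round", ylab = "score", ...)
  graphics::lines(x$trace$round, cummax(x$trace$score), lty = 2)
  invisible(x)
}
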