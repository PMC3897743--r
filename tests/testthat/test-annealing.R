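test_that("the default cooling schedule runs exactly 104 rounds", {
  expect_equal(cooling_rounds(100, 0.95, 0.5), 104L)
  # the schedule stops strictly below the floor temperature
  expect_gte(100 * 0.95^103, 0.5)
  expect_lt(100 * 0.95^104, 0.5)
  # other schedules follow the same geometric rule
  expect_equal(cooling_rounds(10, 0.5, 1), 4L)
})

test_that("the trend score rewards direction and monotonicity", {
  # enumerated: net decrease (1) + four falling steps (4) + monotone (1)
  expect_equal(score_trend(c(70, 68, 66, 64, 62), "classical"), 6)
  # one rise breaks a step and the monotone bonus
  expect_equal(score_trend(c(70, 71, 66, 64, 62), "classical"), 4)
  expect_gt(score_trend(c(70, 68, 66, 64, 62), "classical"),
            score_trend(c(70, 71, 66, 64, 62), "classical"))
  # a strictly increasing sequence maxes the non-classical score
  expect_equal(score_trend(c(60, 61, 63, 66, 70), "nonclassical"), 6)
  # constant sequences earn nothing
  expect_equal(score_trend(rep(70, 5), "classical"), 0)
  expect_equal(score_trend(rep(70, 5), "nonclassical"), 0)
  # only directions of change matter
  expect_equal(score_trend(c(70, 68, 66, 64, 62) + 1000, "classical"), 6)
})

test_that("Metropolis acceptance behaves with temperature and score gap", {
  expect_true(sa_accept(10, 2, temperature = 0.5, u = 0.999999))
  expect_equal(sa_accept_probability(10, 2, 100), 1)
  # worse candidates: acceptance probability shrinks as the system cools
  p_hot <- sa_accept_probability(2, 5, 100)
  p_cold <- sa_accept_probability(2, 5, 0.5)
  expect_equal(p_hot, exp(-3 / 100))
  expect_equal(p_cold, exp(-3 / 0.5))
  expect_lt(p_cold, p_hot)
  # ties pass through the probabilistic branch at probability exp(0) = 1
  expect_true(sa_accept(5, 5, 1, u = 0.9999999))
  expect_error(sa_accept(1, 1, temperature = 0), "temperature")
})

test_that("proposals stay inside the allowed ranges and move locally", {
  set.seed(51)
  p <- classical_preset()
  for (i in 1:200) {
    q <- propose_params(p)
    expect_silent(validate_annealable(q))
    expect_lte(abs(q$epsilon - p$epsilon), 0.1 * (3.0 - 0.5) + 1e-12)
    p <- q
  }
})

test_that("candidate evaluation honours the tail-averaging contract", {
  cfg <- sim_config()
  # constant stub: every level averages to the constant
  stub70 <- function(params, x, seed) list(mean_t_die = 70, extinct = FALSE)
  set.seed(52)
  ev <- evaluate_params(classical_preset(), cfg, runs_per_level = 3,
                        simulate_fn = stub70)
  expect_equal(ev$mean_t_die_by_x, rep(70, 5))
  expect_true(ev$valid)
  expect_equal(ev$n_extinct, 0)

  # planted per-level values, two runs per level, hand-computed means
  stub_seq <- function(params, x, seed) {
    base <- c(`0.0025` = 60, `0.005` = 62, `0.01` = 64, `0.02` = 66,
              `0.04` = 68)[as.character(x)]
    list(mean_t_die = base + (seed %% 2), extinct = FALSE)
  }
  set.seed(53)
  ev2 <- evaluate_params(classical_preset(), cfg, runs_per_level = 2,
                         simulate_fn = stub_seq)
  expect_true(all(ev2$mean_t_die_by_x >= c(60, 62, 64, 66, 68)))
  expect_true(all(ev2$mean_t_die_by_x <= c(61, 63, 65, 67, 69)))

  # every run extinct at a level invalidates the evaluation
  stub_dead <- function(params, x, seed)
    list(mean_t_die = NA_real_, extinct = TRUE)
  set.seed(54)
  ev3 <- evaluate_params(classical_preset(), cfg, runs_per_level = 2,
                         simulate_fn = stub_dead)
  expect_false(ev3$valid)
  expect_error(score_trend(ev3, "classical"), "invalid")
})

test_that("unstable candidates are discarded without cooling", {
  cfg <- sim_config()
  counter <- new.env(); counter$k <- 0L
  # every second evaluated candidate goes extinct at every level
  flaky <- function(params, x, seed) {
    if (x == 0.0025) counter$k <- counter$k + 1L
    dead <- (counter$k %% 2L == 0L) && counter$k > 1L
    list(mean_t_die = if (dead) NA_real_ else 70 + params$epsilon,
         extinct = dead)
  }
  res <- anneal("classical", cfg, master_seed = 55, runs_per_level = 1L,
                simulate_fn = flaky, max_rounds = 12L)
  expect_equal(res$rounds, 12L)
  # the recorded schedule is an unbroken geometric sequence: discarded
  # candidates consumed no temperature steps
  expect_equal(res$trace$temperature, 100 * 0.95^(res$trace$round - 1))
})

test_that("the search recovers a planted optimum in nearly all seeded runs", {
  cfg <- sim_config()
  hits <- 0L
  for (ms in 1:20) {
    res <- anneal("nonclassical", cfg, master_seed = 6000 + ms,
                  runs_per_level = 4L, simulate_fn = planted_stub(),
                  step_frac = 0.15)
    if (res$best$params$epsilon > 1.8) hits <- hits + 1L
  }
  expect_gte(hits, 18L)  # >= 90 percent basin recovery
})

test_that("the best score tracks the running maximum of accepted rounds", {
  cfg <- sim_config()
  res <- anneal("nonclassical", cfg, master_seed = 57, runs_per_level = 4L,
                simulate_fn = planted_stub(), max_rounds = 25L)
  acc <- res$trace[res$trace$accepted, ]
  expect_gte(res$best$score, max(acc$score))
  expect_lte(res$best$score, 6)
})
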