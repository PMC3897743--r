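test_that("the founding cohort matches the initial conditions", {
  cfg <- sim_config(founders = 50)
  set.seed(41)
  pop <- init_population(cfg)
  expect_length(pop$energy, 50)
  expect_true(all(pop$energy == cfg$annealable$e_init))
  expect_true(all(pop$age == 0))
  expect_equal(sum(pop$female), 25)  # exactly balanced sexes
  expect_true(all(pop$t_mat >= 45 & pop$t_mat <= 55))
  expect_true(all(pop$t_die >= 65 & pop$t_die <= 75))
  expect_true(all(pop$t_die > pop$t_mat))
})

test_that("compiled engine and pure-R stepper produce identical trajectories", {
  for (preset in list(classical_preset(), nonclassical_preset())) {
    cfg <- tiny_cfg(annealable = preset, duration = 300)
    ref <- run_reference(cfg, seed = 42)
    sim <- run_simulation(cfg, seed = 42)
    expect_equal(nrow(ref$stats), nrow(sim$stats))
    expect_equal(unname(as.matrix(ref$stats)),
                 unname(as.matrix(sim$stats)), tolerance = 1e-12)
    expect_identical(as.numeric(ref$state$ind$energy),
                     as.numeric(sim$final$energy))
    expect_identical(as.numeric(ref$state$ind$t_die),
                     as.numeric(sim$final$t_die))
    expect_identical(as.numeric(ref$state$ind$t_mat),
                     as.numeric(sim$final$t_mat))
    expect_identical(as.numeric(ref$state$ind$age),
                     as.numeric(sim$final$age))
    # the per-individual death logs agree record for record
    expect_equal(nrow(ref$deaths), nrow(sim$deaths))
    if (nrow(sim$deaths)) {
      expect_identical(ref$deaths$cause, sim$deaths$cause)
      expect_identical(as.numeric(ref$deaths$age_at_death),
                       sim$deaths$age_at_death)
      expect_identical(as.numeric(ref$deaths$iteration), sim$deaths$iteration)
    }
  }
})

test_that("a fixed seed reproduces a run bit-for-bit; seeds differ otherwise", {
  cfg <- tiny_cfg(duration = 500)
  a <- run_simulation(cfg, seed = 7)
  b <- run_simulation(cfg, seed = 7)
  expect_identical(a$stats, b$stats)
  expect_identical(a$final, b$final)
  c <- run_simulation(cfg, seed = 8)
  expect_false(identical(a$stats, c$stats))
})

test_that("degenerate inputs are handled: zero duration and extinction", {
  cfg <- tiny_cfg(duration = 0)
  set.seed(1)
  sim <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(sim$stats), 0)
  expect_false(sim$extinct)
  expect_length(sim$final$t_die, cfg$founders)
  expect_true(all(sim$final$t_die >= 65 & sim$final$t_die <= 75))

  # a population whose foraging cannot cover adult metabolism starves out,
  # and the recorded series ends at the extinction iteration
  cfg2 <- tiny_cfg(duration = 3000, forage_rate = 0.2)
  sim2 <- run_simulation(cfg2, seed = 2)
  expect_true(sim2$extinct)
  expect_equal(max(sim2$stats$iteration), sim2$extinct_iter)
  expect_equal(sim2$stats$pop[nrow(sim2$stats)], 0)
  expect_length(sim2$final$t_die, 0)
})

test_that("a single mature male can never produce births", {
  cfg <- tiny_cfg(x = 0)
  st <- make_state(energy = 20, age = 60, female = FALSE, t_mat = 50,
                   t_die = 5000, cfg = cfg)
  set.seed(43)
  for (i in 1:20) {
    st <- sim_step(st, cfg)
    expect_equal(st$stats[["births"]], 0)
    st <- list(ind = st$ind, pool = st$pool, iter = st$iter)
  }
})

test_that("per-iteration statistics satisfy their structural invariants", {
  cfg <- tiny_cfg(duration = 1500)
  sim <- run_simulation(cfg, seed = 44)
  s <- sim$stats
  juv <- s$juv_maint + s$juv_matur + s$juv_metab
  mat <- s$mat_maint + s$mat_repro + s$mat_metab
  expect_true(all(abs(juv[!is.na(juv)] - 1) < 1e-9))
  expect_true(all(abs(mat[!is.na(mat)] - 1) < 1e-9))
  expect_true(all(s$pop >= 0 & s$births >= 0 & s$starved >= 0 &
                    s$eaten >= 0 & s$aged >= 0))
  expect_true(all(s$pred_frac >= 0 & s$pred_frac <= 1, na.rm = TRUE))
  # stored energy never exceeds the size-scaled storage cap
  smax <- storage_max(cfg, fractional_size(sim$final$age, sim$final$t_mat, cfg))
  expect_true(all(sim$final$energy <= smax + 1e-9))
})

test_that("replicate aggregation is deterministic and coherent", {
  cfg <- tiny_cfg(duration = 400)
  agg <- run_replicates(cfg, n = 4, master_seed = 99)
  agg2 <- run_replicates(cfg, n = 4, master_seed = 99)
  expect_identical(agg$summary, agg2$summary)
  expect_identical(agg$trajectory, agg2$trajectory)
  # survival fraction never increases (extinction is absorbing)
  expect_true(all(diff(agg$survival$fraction_alive) <= 1e-12))
  # a single replicate equals the corresponding bare run
  one <- run_replicates(cfg, n = 1, master_seed = 99)
  set.seed(99)
  seed1 <- sample.int(.Machine$integer.max, 1)
  bare <- run_simulation(cfg, seed = seed1)
  expect_equal(one$summary$final_mean_t_die, mean(bare$final$t_die))
  expect_equal(one$trajectory$pop, bare$stats$pop)
})

test_that("more replicates shrink the sampling variance of the aggregate", {
  cfg <- tiny_cfg(duration = 300)
  means_small <- vapply(1:12, function(ms)
    mean(run_replicates(cfg, n = 2, master_seed = 1000 + ms)$summary$final_mean_t_die,
         na.rm = TRUE), numeric(1))
  means_large <- vapply(1:12, function(ms)
    mean(run_replicates(cfg, n = 8, master_seed = 2000 + ms)$summary$final_mean_t_die,
         na.rm = TRUE), numeric(1))
  expect_lt(var(means_large), var(means_small))
})

test_that("runs can be exported as plain-text files", {
  cfg <- tiny_cfg(duration = 100)
  sim <- run_simulation(cfg, seed = 3)
  dir <- withr::local_tempdir()
  export_run(sim, dir)
  stats <- read.csv(file.path(dir, "run_stats.csv"))
  expect_equal(nrow(stats), nrow(sim$stats))
  fin <- read.csv(file.path(dir, "run_final.csv"))
  expect_equal(fin$t_die, sim$final$t_die)
  deaths <- read.csv(file.path(dir, "run_deaths.csv"))
  expect_equal(nrow(deaths), nrow(sim$deaths))
})
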