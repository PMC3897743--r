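# Independent transcription of the six repair-cost shapes, written on a
# different algebraic route than the implementation (plogis, 1/(1 + h/tau)).
repair_oracle <- function(t_die, d_type, spec = cost_function_spec()) {
  level <- if (d_type >= 3) spec$high_factor else 1
  base <- switch((d_type %% 3) + 1L,
                 spec$scale * stats::plogis((t_die - spec$sig_mid) / spec$sig_width),
                 t_die * (spec$scale / spec$linear_tref),
                 spec$scale / (1 + spec$asym_half / t_die))
  level * base
}

test_that("growth rate solves the maturation boundary-value problem", {
  cfg <- sim_config()
  k <- growth_constant(cfg, t_mat = 50)
  expect_equal((1 + k)^50, cfg$size_ratio, tolerance = 1e-9)
  # iterate the multiplicative growth recurrence from newborn to mature mass
  mass <- e_mature(cfg) / cfg$size_ratio
  for (a in 1:50) mass <- mass * (1 + k)
  expect_equal(mass, e_mature(cfg), tolerance = 1e-9)
  # slower maturation means a strictly smaller per-iteration rate
  expect_lt(growth_constant(cfg, 100), k)
  expect_error(growth_constant(cfg, 0), "positive")
})

test_that("fractional size spans (0, 1] and hits 1 exactly at maturation", {
  cfg <- sim_config()
  for (t_mat in c(20.5, 45, 50, 72.3)) {
    s <- fractional_size(0:ceiling(t_mat + 5), t_mat, cfg)
    expect_equal(s[1], 1 / cfg$size_ratio)
    grow <- s[seq_len(ceiling(t_mat))]
    expect_true(all(diff(grow) > 0))
    expect_equal(fractional_size(t_mat, t_mat, cfg), 1, tolerance = 1e-6)
    expect_true(all(fractional_size(ceiling(t_mat):200, t_mat, cfg) == 1))
  }
})

test_that("maturation cost telescopes to the total mass gain", {
  cfg <- sim_config()
  for (t_mat in c(45, 50, 55)) {
    costs <- maturation_cost(0:(ceiling(t_mat) - 1), t_mat, cfg)
    gained <- sum(costs) * cfg$annealable$growth_eff
    expect_equal(gained, e_mature(cfg) - e_mature(cfg) / cfg$size_ratio,
                 tolerance = 1e-6)
  }
  # mature individuals have finished growing
  expect_equal(maturation_cost(50, 50, cfg), 0)
  # halving the efficiency doubles the foraged-energy cost
  cfg2 <- cfg
  cfg2$annealable$growth_eff <- cfg$annealable$growth_eff / 2
  expect_equal(maturation_cost(10, 50, cfg2),
               2 * maturation_cost(10, 50, cfg))
})

test_that("repair cost matches an independent transcription of all six shapes", {
  cfg <- sim_config()
  grid <- seq(30, 300, by = 5)
  for (d in 0:5) {
    expect_equal(repair_cost_base(grid, d, cfg$repair_spec),
                 repair_oracle(grid, d, cfg$repair_spec), tolerance = 1e-12,
                 info = d_type_label(d))
  }
  expect_error(repair_cost_base(70, 6), "d_type")
})

test_that("repair cost respects dominance, monotonicity and size scaling", {
  cfg <- sim_config()
  grid <- seq(30, 300, by = 5)
  for (shape in 0:2) {
    lo <- repair_cost_base(grid, shape, cfg$repair_spec)
    hi <- repair_cost_base(grid, shape + 3L, cfg$repair_spec)
    expect_true(all(hi >= lo))           # "high" dominates "low" pointwise
    expect_true(all(diff(lo) >= 0))      # never cheaper to intend longer life
    expect_true(all(lo >= 0 & is.finite(lo)))
  }
  # juvenile cost is the mature cost scaled by fractional size
  juv <- repair_cost(age = 10, t_mat = 50, t_die = 70, cfg)
  mat <- repair_cost(age = 60, t_mat = 50, t_die = 70, cfg)
  expect_equal(juv, fractional_size(10, 50, cfg) * mat)
  # and constant in age once mature
  expect_equal(repair_cost(90, 50, 120, cfg), repair_cost(51, 50, 120, cfg))
})

test_that("metabolic cost is the adult cost scaled by size", {
  cfg <- sim_config()
  expect_equal(metabolic_cost(60, 50, cfg), 1.0)  # c_adult anchor
  expect_equal(metabolic_cost(0, 50, cfg), cfg$c_adult / cfg$size_ratio)
  ages <- 0:80
  expect_true(all(diff(metabolic_cost(ages, 50, cfg)) >= 0))
  # rescaling c_adult rescales metabolism linearly, leaves size untouched
  cfg2 <- cfg
  cfg2$c_adult <- 3
  expect_equal(metabolic_cost(25, 50, cfg2), 3 * metabolic_cost(25, 50, cfg))
  expect_equal(fractional_size(25, 50, cfg2), fractional_size(25, 50, cfg))
})

test_that("the energy budget is additive with non-negative components", {
  cfg <- sim_config()
  b <- total_cost(c(0, 10, 49, 50, 70), t_mat = 50, t_die = 80, cfg)
  expect_true(all(b$repair >= 0 & b$maturation >= 0 & b$metabolism >= 0))
  expect_equal(b$total, b$repair + b$maturation + b$metabolism)
  expect_equal(b$maturation[4:5], c(0, 0))  # mature rows
})

test_that("the cost-function grid export tabulates all six shapes", {
  path <- withr::local_tempfile(fileext = ".csv")
  grid <- repair_cost_grid(file = path)
  expect_equal(ncol(grid), 7L)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back[["Asymptotic Low"]], grid[["Asymptotic Low"]])
})
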