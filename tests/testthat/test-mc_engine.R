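# Monte Carlo engine: degenerate limits, determinism, closed-form
# reductions, sensitivity, convergence.

degenerate_model <- function(p_reinf = 0, n = 500L, seed = 1L) {
  scenario_model(
    inputs = list(hospitalization_cost = point_mass(1000),
                  surgical_cost = point_mass(2000),
                  antibiotic_days = point_mass(12),
                  reinfection_rate = dist_spec("bernoulli", p = p_reinf),
                  lost_workdays = point_mass(5)),
    antibiotic_cost_per_day = 10, reinfection_episode_cost = 999,
    daily_wage = 20, n_iterations = n, seed = seed)
}

test_that("point-mass inputs give the exact linear composition", {
  sim <- run_simulation(degenerate_model(p_reinf = 0))
  # 1000 + 2000 + 12*10 + 0*999 + 5*20
  expect_equal(sim$iteration_totals, rep(3220, 500))
  expect_equal(sim$mean_total, 3220)
  expect_equal(unname(sim$ci95), c(3220, 3220))
  sim1 <- run_simulation(degenerate_model(p_reinf = 1))
  expect_equal(sim1$iteration_totals, rep(3220 + 999, 500))
})

test_that("same seed gives bit-identical results; different seeds differ", {
  m <- scenario_model(n_iterations = 2000L, seed = 31L)
  a <- run_simulation(m); b <- run_simulation(m)
  expect_identical(a$iteration_totals, b$iteration_totals)
  expect_identical(a$sensitivity, b$sensitivity)
  m2 <- scenario_model(n_iterations = 2000L, seed = 32L)
  expect_false(identical(run_simulation(m2)$iteration_totals,
                         a$iteration_totals))
})

test_that("with all coefficients zero and other inputs degenerate, the total
           reduces to the triangular hospitalization draw", {
  m <- scenario_model(
    inputs = list(
      hospitalization_cost = dist_spec("triangular", min = 8000,
                                       mode = 12000, max = 18000),
      surgical_cost = point_mass(0),
      antibiotic_days = point_mass(0),
      reinfection_rate = dist_spec("bernoulli", p = 0),
      lost_workdays = point_mass(0)),
    antibiotic_cost_per_day = 0, reinfection_episode_cost = 0, daily_wage = 0,
    n_iterations = 10000L, seed = 5L)
  sim <- run_simulation(m)
  tri_mean <- (8000 + 12000 + 18000) / 3
  tri_var <- (8000^2 + 12000^2 + 18000^2 - 8000 * 12000 - 8000 * 18000 -
                12000 * 18000) / 18
  expect_lt(abs(sim$mean_total - tri_mean), 3 * sqrt(tri_var / 10000))
  expect_lte(sim$ci95[["low"]], sim$mean_total)
  expect_lte(sim$mean_total, sim$ci95[["high"]])
})

test_that("an input with zero unit cost has sensitivity within the noise band", {
  m <- scenario_model(daily_wage = 0, n_iterations = 10000L, seed = 17L)
  sim <- run_simulation(m)
  expect_lt(abs(sim$sensitivity[["lost_workdays"]]), 4 / sqrt(10000))
  # paying inputs dominate the ranking
  expect_gt(abs(sim$sensitivity[["hospitalization_cost"]]), 0.3)
})

test_that("currency conversion applies to the composed totals", {
  sim_try <- run_simulation(degenerate_model())
  tab <- conversion_tables(
    fx = data.frame(year = 2022L, rate = 5),
    cpi = data.frame(period = c("2022", "2022Q4"), index = c(100, 120)))
  sim_usd <- run_simulation(degenerate_model(), tables = tab)
  expect_equal(sim_usd$iteration_totals, sim_try$iteration_totals / 5 * 1.2)
  expect_equal(sim_usd$currency, "USD-2022Q4")
})

test_that("the percentile CI covers the mean and the normal CI is available", {
  m <- scenario_model(n_iterations = 5000L, seed = 2L)
  sim <- run_simulation(m)
  expect_lte(sim$ci95[["low"]], sim$mean_total)
  expect_lte(sim$mean_total, sim$ci95[["high"]])
  simn <- run_simulation(m, ci_method = "normal")
  expect_lt(simn$ci95[["high"]] - simn$ci95[["low"]],
            sim$ci95[["high"]] - sim$ci95[["low"]])
})

test_that("convergence half-widths shrink like 1/sqrt(n) in the CI sense", {
  # CI half-width of the running mean is not reported directly; the report
  # tracks the percentile spread, which stabilizes, and the running-mean
  # shift, which must shrink
  m <- scenario_model(n_iterations = 10000L, seed = 12L)
  sim <- run_simulation(m)
  rep <- convergence_report(sim, batch_size = 1000L)
  expect_equal(nrow(rep), 10L)
  expect_true(attr(rep, "converged"))
  shifts <- rep$mean_shift[-1]
  expect_lt(mean(tail(shifts, 3)), mean(head(shifts, 3)) + 1e-9)
  # degenerate inputs: zero spread at every batch
  repd <- convergence_report(run_simulation(degenerate_model(n = 400L)),
                             batch_size = 100L)
  expect_true(all(repd$ci_half_width == 0))
  # determinism of the report itself
  expect_identical(rep, convergence_report(run_simulation(m),
                                           batch_size = 1000L))
})

test_that("running-mean standard error scales as 1/sqrt(n) across runs", {
  ns <- c(100L, 1000L, 10000L)
  spread <- vapply(ns, function(n) {
    means <- vapply(1:30, function(s) {
      run_simulation(scenario_model(n_iterations = n, seed = s))$mean_total
    }, numeric(1))
    stats::sd(means)
  }, numeric(1))
  # each tenfold n should shrink the SE by about sqrt(10); allow slack 2
  expect_lt(spread[2], spread[1] / sqrt(10) * 2)
  expect_lt(spread[3], spread[2] / sqrt(10) * 2)
})

test_that("configuration errors are raised for bad scenarios", {
  expect_error(scenario_model(inputs = list()), "missing",
               class = "dhicost_config_error")
  expect_error(scenario_model(n_iterations = 1), class = "dhicost_config_error")
  expect_error(scenario_model(daily_wage = -3), class = "dhicost_config_error")
  sim <- run_simulation(scenario_model(n_iterations = 100L))
  expect_error(convergence_report(sim, batch_size = 60L),
               class = "dhicost_config_error")
})

test_that("scenario YAML configuration overrides defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_iterations: 5000",
    "seed: 9",
    "inputs:",
    "  hospitalization_cost: {family: triangular, min: 1000, mode: 2000, max: 3000}",
    "coefficients: {daily_wage: 100}"), path)
  m <- read_scenario_config(path)
  expect_equal(m$n_iterations, 5000L)
  expect_equal(m$inputs$hospitalization_cost$params$mode, 2000)
  expect_equal(m$coefficients$daily_wage, 100)
  expect_equal(m$inputs$surgical_cost$params$mean, 6500)  # default retained
})
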