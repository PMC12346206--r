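# Cohort generator: exact fixture marginals, stochastic fidelity,
# reproducibility, configuration validation.

test_that("the reference fixture reproduces every published marginal exactly", {
  cohort <- build_reference_fixture()
  p <- cohort$patients
  expect_equal(nrow(p), 75L)
  expect_equal(sum(p$sex == "female"), 11L)
  expect_equal(sum(p$sex == "male"), 64L)
  expect_equal(sum(p$diabetes_type == "type2"), 62L)
  counts <- table(factor(p$intervention, intervention_levels()))
  expect_equal(unname(as.integer(counts)), c(24L, 4L, 5L, 18L, 7L, 10L, 6L, 1L))
  expect_equal(sum(p$outpatient_visits >= 30), 15L)
  expect_equal(stats::median(p$outpatient_visits), 20)
  # handedness cross-counts
  expect_equal(sum(p$dominant_hand == "right"), 59L)
  expect_equal(sum(p$dominant_hand == p$infected_side), 58L)
  expect_equal(sum(p$infected_side == "right"), 54L)
  # incapacity tail reaches the published maximum of 102 days
  expect_equal(max(p$incapacity_days), 102L)
})

test_that("fixture per-group visit layouts match the published group medians", {
  p <- build_reference_fixture()$patients
  med <- tapply(p$outpatient_visits, factor(p$intervention,
                                            intervention_levels()), median)
  expect_equal(as.numeric(med[c("Drainage", "Drainage + VAC", "Ray Amputation",
                            "Fasciotomy + VAC", "Fasciotomy + Ray Amputation",
                            "Amputation + Flap Reconstruction",
                            "Fasciotomy + VAC + Flap Reconstruction")]),
               c(17, 18, 20.5, 22, 19.5, 31.5, 21))
  rng <- tapply(p$outpatient_visits, p$intervention, range)
  expect_equal(rng[["Drainage"]], c(7, 59))
  expect_equal(rng[["Ray Amputation"]], c(12, 58))
})

test_that("the fixture is deterministic and leaves the RNG stream alone", {
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(build_reference_fixture())
  after <- stats::runif(1)
  expect_identical(before, after)
  expect_identical(build_reference_fixture(), build_reference_fixture())
})

test_that("an empty configuration yields an empty cohort", {
  cohort <- generate_cohort(cohort_config(n_patients = 0L))
  expect_equal(n_patients(cohort), 0L)
  expect_equal(nrow(cohort$cost_items), 0L)
})

test_that("stochastic generation is bit-reproducible for a fixed seed", {
  cfg <- cohort_config(n_patients = 200L, seed = 77L)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  alt <- generate_cohort(cohort_config(n_patients = 200L, seed = 78L))
  expect_false(identical(generate_cohort(cfg), alt))
})

test_that("clinical-sign prevalences are recovered within 3 binomial SEs", {
  n <- 10000L
  cohort <- generate_cohort(cohort_config(n_patients = n, seed = 424242L))
  for (s in names(sign_prevalences())) {
    p <- sign_prevalences()[[s]]
    frac <- mean(cohort$patients[[paste0("sign_", s)]])
    expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n), label = s)
  }
})

test_that("generated continuous fields respect their truncation bounds", {
  cohort <- generate_cohort(cohort_config(n_patients = 2000L, seed = 5L))
  p <- cohort$patients
  expect_true(all(p$hba1c_percent >= 6 & p$hba1c_percent <= 13))
  expect_true(all(p$crp_mg_l >= 25 & p$crp_mg_l <= 102))
  expect_true(all(p$clinic_days >= 0 & p$clinic_days <= 48))
  expect_true(all(p$icu_days >= 0 & p$icu_days <= 30))
  expect_true(all(p$outpatient_visits >= 7))
  expect_true(all(cohort$cost_items$amount >= 0))
})

test_that("the visit distribution is over-dispersed with a heavy right tail", {
  cohort <- generate_cohort(cohort_config(n_patients = 10000L, seed = 9L))
  v <- cohort$patients$outpatient_visits
  expect_gt(stats::var(v), mean(v))           # over-dispersion
  expect_gt(mean(v >= 30), 0.10)              # substantial >= 30 tail
  expect_lt(abs(mean(v) - 22.29), 1)
})

test_that("invalid configurations raise configuration errors", {
  expect_error(cohort_config(n_patients = 10, mode = "fixture",
                             sex_counts = c(female = 3, male = 4)),
               class = "dhicost_config_error")
  expect_error(cohort_config(sign_prevalences = c(erythema = 1.3)),
               class = "dhicost_config_error")
  expect_error(cohort_config(n_patients = -1),
               class = "dhicost_config_error")
  expect_error(generate_cohort(list()), class = "dhicost_config_error")
})
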