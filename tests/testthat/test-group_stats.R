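# Rank-based group comparison: tie-corrected H, exact enumeration,
# chi-square/permutation agreement, invariances.

test_that("H matches stats::kruskal.test on tied and untied data", {
  set.seed(21)
  for (rep in 1:5) {
    samples <- list(round(stats::rnorm(8, 0, 2)), round(stats::rnorm(6, 1, 2)),
                    round(stats::rnorm(7, 0.5, 2)))
    ours <- kruskal_wallis(samples)
    ref <- stats::kruskal.test(unlist(samples),
                               rep(1:3, vapply(samples, length, 1L)))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exchangeable identical groups give H near 0 and p near 1", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(res$H, 0.1)
  expect_gt(res$p_value, 0.8)
  allsame <- kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5)),
                            method = "permutation")
  expect_equal(allsame$H, 0)
  expect_equal(allsame$p_value, 1)
})

test_that("separated groups match full enumeration over all 20 assignments", {
  samples <- list(c(1, 2, 3), c(10, 11, 12))
  res <- kruskal_wallis(samples, method = "permutation")
  expect_true(res$exact)
  # independent oracle: enumerate all C(6,3) = 20 assignments and score
  # each with stats::kruskal.test
  pooled <- unlist(samples)
  obs <- unname(stats::kruskal.test(pooled, rep(1:2, each = 3))$statistic)
  picks <- utils::combn(6, 3, simplify = FALSE)
  hs <- vapply(picks, function(idx) {
    g <- rep(2L, 6); g[idx] <- 1L
    unname(stats::kruskal.test(pooled, g)$statistic)
  }, numeric(1))
  expect_equal(length(hs), 20L)
  expect_equal(res$H, obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(hs >= obs - 1e-12))
  expect_equal(res$p_value, 0.1)  # the split and its mirror are maximal
})

test_that("chi-square and permutation p-values agree at moderate n", {
  set.seed(33)
  samples <- lapply(1:3, function(i) stats::rnorm(12, mean = 0.3 * i))
  chi <- kruskal_wallis(samples, method = "chi2_approx")
  perm <- kruskal_wallis(samples, method = "permutation", n_perm = 4000L,
                         seed = 101L)
  expect_false(perm$exact)
  expect_lt(abs(chi$p_value - perm$p_value), 0.05)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(40)
  samples <- list(stats::runif(9), stats::runif(11) + 0.2, stats::runif(6))
  h0 <- kruskal_wallis(samples)$H
  expect_equal(kruskal_wallis(lapply(samples, exp))$H, h0)
  expect_equal(kruskal_wallis(lapply(samples, function(x) 3 * x - 10))$H, h0)
  expect_equal(kruskal_wallis(lapply(samples, function(x) x^3))$H, h0)
})

test_that("degenerate inputs raise data errors", {
  expect_error(kruskal_wallis(list(c(1, 2, 3))), "2 groups",
               class = "dhicost_data_error")
  expect_error(kruskal_wallis(list(1, numeric(0))), "empty",
               class = "dhicost_data_error")
  expect_error(kruskal_wallis(list(1, 2)), "3 observations",
               class = "dhicost_data_error")
})

test_that("fixture comparison reproduces the published group sizes", {
  cohort <- build_reference_fixture()
  cmp <- compare_by_intervention(cohort, "outpatient_visits")
  expect_equal(cmp$groups$n, c(24L, 4L, 5L, 18L, 7L, 10L, 6L, 1L))
  expect_true(cmp$groups$singleton[8])
  expect_true(is.na(cmp$groups$sd[8]))
  expect_gte(cmp$H, 0)
  expect_true(cmp$p_value >= 0 && cmp$p_value <= 1)
})

test_that("a cohort with all values equal gives H = 0", {
  cohort <- build_reference_fixture()
  cohort$patients$outpatient_visits <- 10L
  cmp <- compare_by_intervention(cohort, "outpatient_visits")
  expect_equal(cmp$H, 0)
})

test_that("a strongly shifted group is detected at the fixture group sizes", {
  cohort <- generate_cohort(cohort_config(n_patients = 75L, mode = "fixture"))
  set.seed(50)
  v <- stats::rnorm(75)
  v[cohort$patients$intervention == "Ray Amputation"] <-
    v[cohort$patients$intervention == "Ray Amputation"] + 50
  cohort$patients$outpatient_visits <- v - min(v) + 1
  cmp <- compare_by_intervention(cohort, "outpatient_visits",
                                 method = "permutation", n_perm = 2000L,
                                 seed = 7L)
  expect_lt(cmp$p_value, 0.01)
})

test_that("cost fields require conversion tables and flow through them", {
  cohort <- toy_cohort()
  expect_error(compare_by_intervention(cohort, "drug"),
               class = "dhicost_data_error")
  cmp <- compare_by_intervention(cohort, "drug", tables = toy_tables())
  expect_equal(sum(cmp$groups$n), 3L)
  expect_error(compare_by_intervention(cohort, "shoe_size",
                                       tables = toy_tables()),
               class = "dhicost_data_error")
})
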