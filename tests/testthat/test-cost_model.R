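# Bottom-up aggregation and the human-capital indirect cost.

test_that("indirect cost is days times the daily wage", {
  expect_equal(indirect_cost(0, 50)$amount, 0)
  expect_equal(indirect_cost(14, 50)$amount, 700)
  expect_equal(indirect_cost(102, 9.82)$amount, 102 * 9.82)
  expect_error(indirect_cost(-1, 50), class = "dhicost_data_error")
})

test_that("a patient with no cost items gets an all-zero breakdown", {
  cohort <- toy_cohort()
  cohort$cost_items <- cohort$cost_items[0, ]
  b <- aggregate_cohort(cohort, toy_tables())
  expect_equal(nrow(b), 3L)
  expect_true(all(b$total == 0))
  expect_true(all(b$subtotal_without_surgical == 0))
})

test_that("item conversion flows through the currency pipeline", {
  cohort <- toy_cohort()
  b <- aggregate_patient(cohort, "P0001", toy_tables())
  expect_equal(b$drug, 24)        # 100 TRY / 5 * 1.2
  expect_equal(b$surgical, 12)
  expect_equal(b$total, 36)
  expect_equal(b$subtotal_without_surgical, 24)
})

test_that("aggregation is invariant to item order and to splitting items", {
  cohort <- toy_cohort()
  tab <- toy_tables()
  base <- aggregate_cohort(cohort, tab)
  shuffled <- cohort
  set.seed(4)
  shuffled$cost_items <- shuffled$cost_items[sample(nrow(shuffled$cost_items)), ]
  expect_equal(aggregate_cohort(shuffled, tab), base)
  split <- cohort
  i <- 1L
  half <- split$cost_items[i, ]; half$amount <- half$amount / 2
  split$cost_items$amount[i] <- split$cost_items$amount[i] / 2
  split$cost_items <- rbind(split$cost_items, half)
  expect_equal(aggregate_cohort(split, tab), base)
})

test_that("summary statistics agree with a brute-force recomputation", {
  cohort <- generate_cohort(cohort_config(n_patients = 10L, seed = 8L))
  tab <- example_conversion_tables()
  b <- aggregate_cohort(cohort, tab)
  s <- summarize_cohort(b)
  for (col in c("drug", "total", "subtotal_without_surgical")) {
    x <- b[[col]]
    row <- s[s$component == col, ]
    expect_equal(row$mean, sum(x) / length(x))
    expect_equal(row$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
    expect_equal(row$median, sort(x)[c(5, 6)] |> mean())
    expect_equal(row$min, min(x)); expect_equal(row$max, max(x))
  }
})

test_that("two patients give mean = median = (a+b)/2; n = 1 is flagged", {
  cohort <- toy_cohort()
  tab <- toy_tables()
  b <- aggregate_cohort(cohort, tab)[1:2, ]
  s <- summarize_cohort(b)
  tot <- s[s$component == "total", ]
  expect_equal(tot$mean, mean(b$total))
  expect_equal(tot$median, mean(b$total))
  s1 <- summarize_cohort(b[1, , drop = FALSE])
  expect_true(all(s1$degenerate_n))
  expect_equal(s1[s1$component == "total", "sd"], 0)
  expect_error(summarize_cohort(b[0, ]), class = "dhicost_data_error")
})

test_that("fixture category means match an independent spreadsheet-style pass", {
  cohort <- build_reference_fixture()
  tab <- example_conversion_tables()
  b <- aggregate_cohort(cohort, tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  # independent pass: USD-2022 items inflate by the 2022Q4/2022 CPI ratio
  raw <- raw[!is.na(raw$cost_amount), ]
  usd <- raw$cost_amount * 297.5 / 292.7
  for (cat in c("drug", "outpatient", "surgical", "incapacity")) {
    manual <- sum(usd[raw$cost_category == cat]) / 75
    expect_equal(mean(b[[cat]]), manual, tolerance = 1e-10, label = cat)
  }
  expect_equal(mean(b$total) - mean(b$surgical),
               mean(b$subtotal_without_surgical))
})

test_that("fixture visit summary reproduces the published median of 20", {
  p <- build_reference_fixture()$patients
  s <- summarize_cohort(p, columns = "outpatient_visits")
  expect_equal(s$median, 20)
  expect_equal(s$min, 7)
  expect_equal(s$max, 59)
})
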