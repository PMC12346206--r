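# Shared test fixtures, built in code.

# Minimal conversion tables with round numbers: 5 TRY/USD in 2018 and a
# CPI ratio of 1.2 from 2018 to the 2022Q4 target, so 100 TRY (2018)
# converts to exactly 24 USD.
toy_tables <- function() {
  conversion_tables(
    fx = data.frame(year = c(2018L, 2022L), rate = c(5, 1)),
    cpi = data.frame(period = c("2018", "2022", "2022Q4"),
                     index = c(100, 115, 120)))
}

# A tiny hand-written cohort: 3 patients, 2 interventions, costs in TRY
# (2018) so toy_tables() conversion applies.
toy_cohort <- function() {
  cfg <- cohort_config(n_patients = 3L, mode = "stochastic", seed = 42L)
  cohort <- generate_cohort(cfg)
  cohort$patients$intervention <- c("Drainage", "Drainage", "Ray Amputation")
  cohort$cost_items <- data.frame(
    patient_id = c("P0001", "P0001", "P0002", "P0003"),
    category = c("drug", "surgical", "drug", "outpatient"),
    amount = c(100, 50, 200, 400),
    currency = "TRY", year = 2018L, stringsAsFactors = FALSE)
  cohort
}

# Point-mass spec helper (triangular with min = mode = max).
point_mass <- function(v) dist_spec("triangular", min = v, mode = v, max = v)

# Standard error of a sample variance from sample moments.
var_se <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  sqrt((m4 - stats::var(x)^2) / n)
}
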