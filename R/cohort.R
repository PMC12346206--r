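# Cohort container and generators.
#
# A cohort is a pair of data frames: one row per patient, and a long table
# of itemized cost lines (one row per patient x cost item) tagged with the
# currency and calendar year in which each amount was incurred.

.sign_cols <- function() paste0("sign_", names(sign_prevalences()))

.patient_cols <- function() {
  c("patient_id", "sex", "age_years", "diabetes_type", "dominant_hand",
    "infected_side", "intervention", .sign_cols(),
    "hba1c_percent", "glucose_mg_dl", "sedimentation_mm_h", "crp_mg_l",
    "wbc_per_mcl", "clinic_days", "icu_days", "outpatient_visits",
    "incapacity_days")
}

stop_config <- function(fmt, ...) {
  stop(structure(class = c("dhicost_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

stop_data <- function(fmt, ...) {
  stop(structure(class = c("dhicost_data_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

new_cohort <- function(patients, cost_items) {
  structure(list(patients = patients, cost_items = cost_items),
            class = "dhi_cohort")
}

.empty_cost_items <- function() {
  data.frame(patient_id = character(0), category = character(0),
              amount = numeric(0), currency = character(0),
              year = integer(0), stringsAsFactors = FALSE)
}

#' Number of patients in a cohort
#' @param cohort A `dhi_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' @export
print.dhi_cohort <- function(x, ...) {
  cat(sprintf("<dhi_cohort: %d patients, %d cost items>\n",
              nrow(x$patients), nrow(x$cost_items)))
  if (nrow(x$patients)) {
    tab <- table(factor(x$patients$intervention, intervention_levels()))
    for (g in names(tab)) cat(sprintf("  %-40s %d\n", g, tab[[g]]))
  }
  invisible(x)
}

#' Cohort generator configuration
#'
#' Assembles and validates the configuration consumed by
#' [generate_cohort()]. All defaults reproduce the study conditions: a
#' 75-patient cohort with an 11/64 female/male split, 62 type-2 diabetics,
#' the eight surgical-intervention groups, the published clinical-sign
#' prevalences, lab distributions matched to the published summary moments
#' and truncated at the observed ranges, an over-dispersed (shifted
#' negative-binomial) outpatient-visit count with a hard floor at 7 visits,
#' and right-skewed lognormal cost components clipped to the observed
#' ranges.
#'
#' @param n_patients Cohort size (default 75).
#' @param mode `"stochastic"` (sample every field) or `"fixture"`
#'   (deterministic reference cohort; see [build_reference_fixture()]).
#' @param seed Integer seed for the stochastic mode.
#' @param sex_probs Named probabilities for `female`/`male` (stochastic
#'   mode).
#' @param sex_counts Named integer counts (fixture mode); must sum to
#'   `n_patients`.
#' @param group_probs,group_counts Sampling probabilities or exact counts
#'   over the eight canonical intervention labels.
#' @param sign_prevalences Named Bernoulli prevalences for the five
#'   admission clinical signs.
#' @param lab_specs Named list of [dist_spec()]s for the continuous fields.
#' @param visit_spec [dist_spec()] for outpatient visit counts.
#' @param cost_specs Named list of [dist_spec()]s per cost category.
#' @param daily_wage Daily wage used to price incapacity days
#'   (human-capital approach), in `currency` units of `cost_year`.
#' @param currency ISO currency code stamped on generated cost items.
#' @param cost_year Calendar year stamped on generated cost items.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 75L,
                          mode = c("stochastic", "fixture"),
                          seed = 1L,
                          sex_probs = NULL, sex_counts = NULL,
                          group_probs = NULL, group_counts = NULL,
                          sign_prevalences = dhicost::sign_prevalences(),
                          lab_specs = default_lab_specs(),
                          visit_spec = default_visit_spec(),
                          cost_specs = default_cost_specs(),
                          daily_wage = 9.82,
                          currency = "USD",
                          cost_year = 2022L) {
  mode <- match.arg(mode)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0 ||
      n_patients != floor(n_patients))
    stop_config("n_patients must be a single nonnegative integer")
  n_patients <- as.integer(n_patients)

  if (mode == "fixture") {
    if (is.null(sex_counts)) sex_counts <- c(female = 11L, male = 64L)
    if (is.null(group_counts)) {
      group_counts <- stats::setNames(.intervention_counts,
                                      intervention_levels())
    }
    if (sum(sex_counts) != n_patients)
      stop_config("fixture mode: sex_counts sum to %d, not n_patients = %d",
                  sum(sex_counts), n_patients)
    if (sum(group_counts) != n_patients)
      stop_config("fixture mode: group_counts sum to %d, not n_patients = %d",
                  sum(group_counts), n_patients)
  } else {
    if (is.null(sex_probs)) sex_probs <- c(female = 11 / 75, male = 64 / 75)
    if (is.null(group_probs)) {
      group_probs <- stats::setNames(.intervention_counts / 75,
                                     intervention_levels())
    }
    for (nm in c("sex_probs", "group_probs")) {
      p <- get(nm)
      if (any(p < 0) || any(p > 1))
        stop_config("%s contains a probability outside [0, 1]", nm)
    }
  }
  if (any(sign_prevalences < 0) || any(sign_prevalences > 1))
    stop_config("sign prevalence outside [0, 1]")
  if (daily_wage < 0) stop_config("daily_wage must be nonnegative")

  structure(list(n_patients = n_patients, mode = mode, seed = as.integer(seed),
                 sex_probs = sex_probs, sex_counts = sex_counts,
                 group_probs = group_probs, group_counts = group_counts,
                 sign_prevalences = sign_prevalences, lab_specs = lab_specs,
                 visit_spec = visit_spec, cost_specs = cost_specs,
                 daily_wage = daily_wage, currency = currency,
                 cost_year = as.integer(cost_year)),
            class = "cohort_config")
}

#' Default continuous-field specifications
#'
#' Truncated normal distributions matched to the published cohort
#' mean/SD and clipped to the observed min-max for each lab and
#' length-of-stay field. Day counts are rounded to integers at generation.
#'
#' @return Named list of [dist_spec()]s.
#' @export
default_lab_specs <- function() {
  lapply(.study_lab_moments, function(m) {
    dist_spec("normal", mean = m[["mean"]], sd = m[["sd"]],
              bounds = c(m[["min"]], m[["max"]]))
  })
}

#' Default outpatient-visit specification
#'
#' Visit counts are over-dispersed (published mean 22.29, SD 11.01) with a
#' hard floor at the observed minimum of 7 visits, so they are modelled as
#' 7 plus a negative binomial moment-matched to the shifted mean and
#' variance.
#'
#' @return A [dist_spec()].
#' @export
default_visit_spec <- function() {
  m <- .visit_moments
  mu <- m[["mean"]] - m[["min"]]
  v <- m[["sd"]]^2
  dist_spec("negbinom", mu = mu, size = mu^2 / (v - mu), shift = m[["min"]])
}

#' Default cost-component specifications
#'
#' Right-skewed lognormal distributions moment-matched to the published
#' per-category mean/SD and clipped to the observed min-max (the published
#' medians sit below the means throughout, and costs are nonnegative, so a
#' lognormal is the natural emulation).
#'
#' @return Named list of [dist_spec()]s keyed by cost category.
#' @export
default_cost_specs <- function() {
  lapply(.study_cost_moments, function(m) {
    dist_spec("lognormal", mean = m[["mean"]], sd = m[["sd"]],
              bounds = c(max(m[["min"]], 0.01), m[["max"]]))
  })
}

# run expr with a locally-seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic patient cohort
#'
#' In stochastic mode every field is drawn from the configured
#' distributions (categoricals from the configured probabilities,
#' continuous fields from their truncated specs) using a single seeded
#' generator, so output is bit-reproducible given the seed. In fixture mode
#' the cohort is fully deterministic: categorical fields are laid out to
#' match the configured counts exactly and continuous fields replicate the
#' published medians (see [build_reference_fixture()]).
#'
#' @param config A [cohort_config()].
#' @return A `dhi_cohort`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_config("config must be built with cohort_config()")
  n <- config$n_patients
  if (n == 0L) {
    return(new_cohort(
      stats::setNames(data.frame(matrix(nrow = 0, ncol = length(.patient_cols()))),
                      .patient_cols()),
      .empty_cost_items()))
  }
  if (config$mode == "fixture") return(.build_fixture(config))
  .with_seed(config$seed, .generate_stochastic(config))
}

.generate_stochastic <- function(config) {
  n <- config$n_patients
  id <- sprintf("P%04d", seq_len(n))
  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  # type split beyond the published 62/75 type-2 fraction is not printed;
  # the residual 13/75 is split 10 type-1 / 3 other
  diabetes <- sample(c("type1", "type2", "other"), n, replace = TRUE,
                     prob = c(10, 62, 3) / 75)
  dominant <- sample(c("right", "left"), n, replace = TRUE,
                     prob = c(59, 16) / 75)
  infected <- sample(c("right", "left"), n, replace = TRUE,
                     prob = c(54, 21) / 75)
  intervention <- sample(names(config$group_probs), n, replace = TRUE,
                         prob = config$group_probs)
  signs <- lapply(config$sign_prevalences, function(p) sample_event(p, n))
  labs <- lapply(config$lab_specs, sample_dist, n = n)
  for (f in c("clinic_days", "icu_days", "incapacity_days"))
    labs[[f]] <- round(labs[[f]])
  visits <- round(sample_dist(config$visit_spec, n))

  patients <- data.frame(patient_id = id, sex = sex, age_years = labs$age_years,
                         diabetes_type = diabetes, dominant_hand = dominant,
                         infected_side = infected, intervention = intervention,
                         stringsAsFactors = FALSE)
  for (s in names(signs)) patients[[paste0("sign_", s)]] <- signs[[s]]
  for (f in c("hba1c_percent", "glucose_mg_dl", "sedimentation_mm_h",
              "crp_mg_l", "wbc_per_mcl", "clinic_days", "icu_days"))
    patients[[f]] <- labs[[f]]
  patients$outpatient_visits <- pmax(1, visits)
  patients$incapacity_days <- labs$incapacity_days
  patients <- patients[, .patient_cols()]

  items <- list()
  for (cat in names(config$cost_specs)) {
    amount <- round(sample_dist(config$cost_specs[[cat]], n), 2)
    if (cat == "icu_stay") amount[patients$icu_days == 0] <- 0
    keep <- amount > 0
    if (any(keep)) {
      items[[cat]] <- data.frame(patient_id = id[keep], category = cat,
                                 amount = amount[keep],
                                 currency = config$currency,
                                 year = config$cost_year,
                                 stringsAsFactors = FALSE)
    }
  }
  inc <- round(patients$incapacity_days * config$daily_wage, 2)
  keep <- inc > 0
  if (any(keep)) {
    items$incapacity <- data.frame(patient_id = id[keep],
                                   category = "incapacity", amount = inc[keep],
                                   currency = config$currency,
                                   year = config$cost_year,
                                   stringsAsFactors = FALSE)
  }
  cost_items <- if (length(items)) do.call(rbind, c(items, make.row.names = FALSE))
                else .empty_cost_items()
  cost_items <- cost_items[order(match(cost_items$patient_id, id),
                                 match(cost_items$category, cost_categories())), ]
  rownames(cost_items) <- NULL
  new_cohort(patients, cost_items)
}

# Deterministic per-group outpatient-visit layouts for the reference
# fixture: each group reproduces its published min / median / max, the
# pooled median is 20, and exactly 15 of the 75 values are >= 30.
.fixture_visits <- list(
  "Drainage" = c(7, 8, 9, 10, 11, 12, 14, 15, 16, 16, 17, 17, 17, 18, 19, 20,
                 22, 24, 26, 28, 29, 36, 44, 59),
  "Drainage + VAC" = c(16, 18, 18, 23),
  "Open Amputation + VAC" = c(10, 13, 16, 30, 41),
  "Ray Amputation" = c(12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 26,
                       28, 31, 35, 58),
  "Fasciotomy + VAC" = c(10, 15, 20, 22, 25, 28, 35),
  "Fasciotomy + Ray Amputation" = c(10, 12, 15, 18, 19, 20, 24, 27, 33, 41),
  "Amputation + Flap Reconstruction" = c(16, 25, 30, 33, 40, 54),
  "Fasciotomy + VAC + Flap Reconstruction" = 21)

# Published per-group median outpatient-visit cost (adjusted USD), keyed by
# canonical label.
.fixture_outpatient_cost <- c(
  "Drainage" = 2273.00,
  "Drainage + VAC" = 7611.50,
  "Open Amputation + VAC" = 4872.00,
  "Ray Amputation" = 457.50,
  "Fasciotomy + VAC" = 4409.00,
  "Fasciotomy + Ray Amputation" = 4434.50,
  "Amputation + Flap Reconstruction" = 1291.00,
  "Fasciotomy + VAC + Flap Reconstruction" = 1953.00)

.build_fixture <- function(config) {
  n <- config$n_patients
  labels <- names(config$group_counts)
  intervention <- rep(labels, config$group_counts)
  id <- sprintf("P%04d", seq_len(n))

  sex <- rep("male", n)
  sex[((seq_len(sum(config$sex_counts[["female"]])) - 1L) * 7L) %% n + 1L] <- "female"

  diabetes <- rep("type2", n)
  non_t2 <- unique(((seq_len(13L) - 1L) * 6L + 2L) %% n + 1L)[1:13]
  diabetes[non_t2[1:10]] <- "type1"
  diabetes[non_t2[11:13]] <- "other"

  # handedness layout reproducing the published cross-counts: 59
  # right-handed (48 with right-side infection), 16 left-handed (6 with
  # right-side infection); dominant side infected in 58/75
  dominant <- c(rep("right", 59), rep("left", 16))[seq_len(min(n, 75))]
  infected <- c(rep("right", 48), rep("left", 11), rep("right", 6),
                rep("left", 10))[seq_len(min(n, 75))]
  if (n > 75) { dominant <- rep_len(dominant, n); infected <- rep_len(infected, n) }

  sign_cfg <- config$sign_prevalences
  signs <- list()
  strides <- c(1L, 2L, 4L, 7L, 8L)
  offsets <- c(0L, 5L, 11L, 23L, 37L)
  for (j in seq_along(sign_cfg)) {
    k <- round(sign_cfg[[j]] * n)
    v <- rep(FALSE, n)
    if (k > 0) {
      idx <- unique(((seq_len(2L * k) - 1L) * strides[j] + offsets[j]) %% n + 1L)
      v[idx[seq_len(k)]] <- TRUE
    }
    signs[[names(sign_cfg)[j]]] <- v
  }

  visits <- integer(n)
  for (g in labels) {
    sel <- which(intervention == g)
    ref <- .fixture_visits[[g]]
    visits[sel] <- if (!is.null(ref) && length(ref) == length(sel)) ref
                   else rep(20L, length(sel))
  }

  # incapacity-for-work days: median 0 with a long tail out to the
  # published maximum of 102 days
  incap <- rep(0L, n)
  tail_days <- c(102L, 88L, 75L, 64L, 55L, 48L, 40L, 34L, 28L, 22L, 16L, 10L)
  incap[seq(2L, by = 6L, length.out = length(tail_days))] <- tail_days

  icu <- rep(0L, n)
  icu_days <- c(30L, 28L, 25L, 22L, 20L, 18L, 15L, 12L, 10L, 8L, 7L, 6L, 5L,
                4L, 3L, 2L)
  icu[seq(3L, by = 4L, length.out = length(icu_days))] <- icu_days

  patients <- data.frame(
    patient_id = id, sex = sex,
    age_years = ifelse(sex == "female", 61.5, 56.2),
    diabetes_type = diabetes, dominant_hand = dominant,
    infected_side = infected, intervention = intervention,
    stringsAsFactors = FALSE)
  for (s in names(signs)) patients[[paste0("sign_", s)]] <- signs[[s]]
  patients$hba1c_percent <- 8.3
  patients$glucose_mg_dl <- 324
  patients$sedimentation_mm_h <- 34
  patients$crp_mg_l <- 50
  patients$wbc_per_mcl <- 11440
  patients$clinic_days <- 21L
  patients$icu_days <- icu
  patients$outpatient_visits <- visits
  patients$incapacity_days <- incap
  patients <- patients[, .patient_cols()]

  base <- function(cat, amount, keep = rep(TRUE, n)) {
    data.frame(patient_id = id[keep], category = cat, amount = amount[keep],
               currency = config$currency, year = config$cost_year,
               stringsAsFactors = FALSE)
  }
  out_cost <- unname(.fixture_outpatient_cost[intervention])
  out_cost[is.na(out_cost)] <- 4382.00
  cost_items <- rbind(
    base("drug", rep(4473.00, n)),
    base("clinic_stay", rep(5534.00, n)),
    base("icu_stay", rep(1842.50, n), keep = icu > 0),
    base("outpatient", out_cost),
    base("surgical", rep(521.00, n)),
    base("incapacity", round(incap * config$daily_wage, 2), keep = incap > 0))
  cost_items <- cost_items[order(match(cost_items$patient_id, id),
                                 match(cost_items$category, cost_categories())), ]
  rownames(cost_items) <- NULL
  new_cohort(patients, cost_items)
}

#' Deterministic reference cohort
#'
#' Builds, without any random number generation, a 75-patient cohort that
#' reproduces every published marginal count exactly: 11 female / 64 male,
#' 62 type-2 diabetics, intervention group sizes 24/4/5/18/7/10/6/1, and 15
#' patients with 30 or more outpatient visits. Per-group outpatient-visit
#' layouts reproduce each group's published minimum, median and maximum
#' (and a pooled median of 20 visits); other continuous fields replicate
#' the published medians, since per-patient values were never published and
#' only the marginal counts are claimed exact.
#'
#' @param daily_wage Daily wage used to price incapacity days.
#' @return A `dhi_cohort` of 75 records.
#' @export
build_reference_fixture <- function(daily_wage = 9.82) {
  generate_cohort(cohort_config(n_patients = 75L, mode = "fixture",
                                daily_wage = daily_wage))
}
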