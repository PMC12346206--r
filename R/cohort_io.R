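# Cohort CSV interchange: one row per (patient x cost item), UTF-8,
# comma-separated, patient fields repeated on each of the patient's rows;
# patients without cost items carry one row with the cost fields empty.
# Amounts are written with 2 decimals; years as integers.

.cohort_csv_cols <- function() {
  c(.patient_cols(), "cost_category", "cost_amount", "cost_currency",
    "cost_year")
}

#' Write a cohort to CSV
#'
#' @param cohort A `dhi_cohort`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  pat <- cohort$patients
  items <- cohort$cost_items
  if (nrow(pat) == 0L) {
    empty <- stats::setNames(
      data.frame(matrix(character(0), 0, length(.cohort_csv_cols()))),
      .cohort_csv_cols())
    utils::write.csv(empty, path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(path))
  }
  orphans <- setdiff(pat$patient_id, items$patient_id)
  if (length(orphans)) {
    items <- rbind(items,
                   data.frame(patient_id = orphans, category = NA_character_,
                              amount = NA_real_, currency = NA_character_,
                              year = NA_integer_, stringsAsFactors = FALSE))
  }
  merged <- merge(pat, items, by = "patient_id", sort = FALSE)
  merged <- merged[order(match(merged$patient_id, pat$patient_id)), ]
  names(merged)[names(merged) == "category"] <- "cost_category"
  names(merged)[names(merged) == "amount"] <- "cost_amount"
  names(merged)[names(merged) == "currency"] <- "cost_currency"
  names(merged)[names(merged) == "year"] <- "cost_year"
  merged <- merged[, .cohort_csv_cols()]
  merged$cost_amount <- ifelse(is.na(merged$cost_amount), "",
                               sprintf("%.2f", merged$cost_amount))
  utils::write.csv(merged, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

.parse_fail <- function(row, fmt, ...) {
  stop_data("cohort CSV row %d: %s", row, sprintf(fmt, ...))
}

#' Read a cohort from CSV
#'
#' Validates every row: intervention labels must be canonical (the
#' published cost-table label variants are accepted and canonicalized),
#' categorical fields must be in range, amounts nonnegative, visits at
#' least 1, and day/lab fields nonnegative. Violations raise a data error
#' naming the offending row.
#'
#' @param path CSV file written by [write_cohort()].
#' @return A `dhi_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_data("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8",
                         colClasses = c(patient_id = "character"))
  missing <- setdiff(.cohort_csv_cols(), names(raw))
  if (length(missing))
    stop_data("cohort CSV missing columns: %s", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) {
    return(new_cohort(
      stats::setNames(data.frame(matrix(nrow = 0, ncol = length(.patient_cols()))),
                      .patient_cols()),
      .empty_cost_items()))
  }
  raw$intervention <- .canonical_intervention(raw$intervention)
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    if (!r$intervention %in% intervention_levels())
      .parse_fail(i, "unknown intervention label '%s'", r$intervention)
    if (!r$sex %in% c("female", "male"))
      .parse_fail(i, "invalid sex '%s'", r$sex)
    if (!r$diabetes_type %in% c("type1", "type2", "other"))
      .parse_fail(i, "invalid diabetes_type '%s'", r$diabetes_type)
    if (!r$dominant_hand %in% c("left", "right") ||
        !r$infected_side %in% c("left", "right"))
      .parse_fail(i, "hand/side fields must be 'left' or 'right'")
    if (is.na(r$outpatient_visits) || r$outpatient_visits < 1)
      .parse_fail(i, "outpatient_visits must be >= 1")
    for (f in c("age_years", "hba1c_percent", "glucose_mg_dl",
                "sedimentation_mm_h", "crp_mg_l", "wbc_per_mcl",
                "clinic_days", "icu_days", "incapacity_days")) {
      if (is.na(r[[f]]) || r[[f]] < 0)
        .parse_fail(i, "field %s must be nonnegative", f)
    }
    has_item <- !is.na(r$cost_category) && nzchar(r$cost_category)
    if (has_item) {
      if (!r$cost_category %in% cost_categories())
        .parse_fail(i, "unknown cost category '%s'", r$cost_category)
      if (is.na(r$cost_amount) || r$cost_amount < 0)
        .parse_fail(i, "cost amount must be nonnegative")
      if (is.na(r$cost_year))
        .parse_fail(i, "cost item missing year")
    }
  }
  first <- !duplicated(raw$patient_id)
  patients <- raw[first, .patient_cols()]
  rownames(patients) <- NULL
  has_item <- !is.na(raw$cost_category) & nzchar(raw$cost_category)
  items <- raw[has_item, c("patient_id", "cost_category", "cost_amount",
                           "cost_currency", "cost_year")]
  names(items) <- c("patient_id", "category", "amount", "currency", "year")
  items$year <- as.integer(items$year)
  rownames(items) <- NULL
  if (!nrow(items)) items <- .empty_cost_items()
  new_cohort(patients, items)
}

#' Read a cohort configuration from YAML
#'
#' The file mirrors the arguments of [cohort_config()]; distribution
#' entries are maps with a `family` key plus family parameters, e.g.
#' `{family: normal, mean: 6500, sd: 1200}`, with optional `bounds`
#' (2-element list), `truncate_at_zero`, `units`.
#'
#' @param path YAML file path.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  as_spec <- function(s) {
    if (is.null(s$family)) stop_config("distribution entry missing 'family'")
    args <- s[setdiff(names(s), c("family", "bounds", "truncate_at_zero",
                                  "units", "name"))]
    do.call(dist_spec, c(list(family = s$family), args,
                         list(bounds = if (!is.null(s$bounds))
                                unlist(s$bounds),
                              truncate_at_zero = isTRUE(s$truncate_at_zero),
                              units = s$units, name = s$name)))
  }
  args <- list(
    n_patients = y$n_patients %||% 75L,
    mode = y$mode %||% "stochastic",
    seed = y$seed %||% 1L,
    daily_wage = y$daily_wage %||% 9.82,
    currency = y$currency %||% "USD",
    cost_year = y$cost_year %||% 2022L)
  if (!is.null(y$sex_probs)) args$sex_probs <- unlist(y$sex_probs)
  if (!is.null(y$sex_counts)) args$sex_counts <- unlist(y$sex_counts)
  if (!is.null(y$group_probs)) args$group_probs <- unlist(y$group_probs)
  if (!is.null(y$group_counts)) args$group_counts <- unlist(y$group_counts)
  if (!is.null(y$sign_prevalences))
    args$sign_prevalences <- unlist(y$sign_prevalences)
  if (!is.null(y$lab_specs)) args$lab_specs <- lapply(y$lab_specs, as_spec)
  if (!is.null(y$visit_spec)) args$visit_spec <- as_spec(y$visit_spec)
  if (!is.null(y$cost_specs)) args$cost_specs <- lapply(y$cost_specs, as_spec)
  do.call(cohort_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
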