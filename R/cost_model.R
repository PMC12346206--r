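# Bottom-up cost aggregation: itemized per-patient resource-use costs are
# converted to a common unit (target-period USD) and summed by category;
# indirect costs follow the human-capital approach (missed workdays times
# a daily wage).

#' Human-capital indirect cost
#'
#' Prices productivity loss as missed workdays times a national average
#' daily wage, producing an `incapacity`-category cost item tagged with the
#' wage's currency and year.
#'
#' @param incapacity_days Nonnegative integer number of missed workdays.
#' @param daily_wage Wage per workday (nonnegative).
#' @param currency ISO code of the wage series.
#' @param year Calendar year of the wage series.
#' @return One-row cost-item data frame (`patient_id` left `NA`).
#' @export
indirect_cost <- function(incapacity_days, daily_wage, currency = "TRY",
                          year = 2022L) {
  if (!is.numeric(incapacity_days) || length(incapacity_days) != 1L ||
      is.na(incapacity_days) || incapacity_days < 0)
    stop_data("incapacity_days must be a single nonnegative number")
  if (daily_wage < 0) stop_data("daily_wage must be nonnegative")
  data.frame(patient_id = NA_character_, category = "incapacity",
             amount = incapacity_days * daily_wage,
             currency = currency, year = as.integer(year),
             stringsAsFactors = FALSE)
}

.breakdown_cols <- function() {
  c(cost_categories(), "subtotal_without_surgical", "total")
}

#' Per-patient cost breakdowns for a cohort
#'
#' Converts every cost item to target-period USD via the currency pipeline
#' and sums by category per patient. Adds `total` (sum over all
#' categories) and `subtotal_without_surgical` (total minus the
#' surgical-category sum), a row per patient even when a patient has no
#' cost items.
#'
#' @param cohort A `dhi_cohort`.
#' @param tables A [conversion_tables()].
#' @return Data frame with `patient_id`, one column per cost category,
#'   `subtotal_without_surgical`, and `total`, all in target-period USD.
#' @export
aggregate_cohort <- function(cohort, tables) {
  items <- cohort$cost_items
  ids <- cohort$patients$patient_id
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (cat in cost_categories()) out[[cat]] <- 0
  if (nrow(items)) {
    usd <- convert_amount(items$amount, items$currency, items$year, tables)
    agg <- tapply(usd, list(factor(items$patient_id, levels = ids),
                            factor(items$category, levels = cost_categories())),
                  sum, default = 0)
    for (cat in cost_categories()) out[[cat]] <- unname(agg[, cat])
  }
  out$total <- rowSums(out[, cost_categories(), drop = FALSE])
  out$subtotal_without_surgical <- out$total - out$surgical
  out[, c("patient_id", .breakdown_cols())]
}

#' Cost breakdown for one patient record
#'
#' @param cohort A `dhi_cohort`.
#' @param patient_id Identifier of one patient in the cohort.
#' @param tables A [conversion_tables()].
#' @return One-row breakdown data frame (see [aggregate_cohort()]).
#' @export
aggregate_patient <- function(cohort, patient_id, tables) {
  if (!patient_id %in% cohort$patients$patient_id)
    stop_data("unknown patient_id %s", patient_id)
  sub <- new_cohort(
    cohort$patients[cohort$patients$patient_id == patient_id, , drop = FALSE],
    cohort$cost_items[cohort$cost_items$patient_id == patient_id, , drop = FALSE])
  aggregate_cohort(sub, tables)
}

#' Cohort summary in the published table layout
#'
#' Per cost category (plus the subtotal and total rows), reports mean, SD
#' (sample, n-1 denominator), median, min and max, and a formatted
#' "mean +/- SD / median (min-max)" string. With a single patient the SD is
#' reported as 0 and flagged. Monetary rounding to 2 decimals happens only
#' in the formatted column; numeric columns are unrounded.
#'
#' @param breakdowns Output of [aggregate_cohort()] (at least one row), or
#'   any data frame of numeric columns to summarize.
#' @param columns Columns to summarize; defaults to the breakdown columns
#'   present.
#' @return Data frame with one row per summarized column and a
#'   `degenerate_n` flag.
#' @export
summarize_cohort <- function(breakdowns, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(.breakdown_cols(), names(breakdowns))
  if (nrow(breakdowns) < 1L) stop_data("cannot summarize an empty cohort")
  n <- nrow(breakdowns)
  rows <- lapply(columns, function(col) {
    x <- breakdowns[[col]]
    s <- if (n > 1L) stats::sd(x) else 0
    data.frame(component = col, n = n, mean = mean(x), sd = s,
               median = stats::median(x), min = min(x), max = max(x),
               degenerate_n = n == 1L,
               formatted = sprintf("%.2f ± %.2f/%.2f (%.2f–%.2f)",
                                   mean(x), s, stats::median(x), min(x), max(x)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort summary as CSV and aligned text
#'
#' @param summary Output of [summarize_cohort()].
#' @param csv_path,txt_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary.
#' @export
write_summary <- function(summary, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(summary, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    w <- max(nchar(summary$component))
    lines <- c(sprintf("%-*s  %s", w, "component",
                       "mean ± SD/median (min–max)"),
               sprintf("%-*s  %s", w, summary$component, summary$formatted))
    writeLines(lines, txt_path)
  }
  invisible(summary)
}
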