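# Three-step restatement of historical local-currency amounts in a common
# unit: (1) a multiplicative factor 1/fx[year] from the annual-average
# exchange rate, (2) multiply to get same-year US dollars, (3) inflate by
# the US CPI ratio to the target period (Q4 2022 by default). FX is always
# applied before CPI.

#' Currency conversion tables
#'
#' Holds the annual-average exchange rate series (local currency per USD)
#' and the US CPI series used to restate historical amounts in
#' target-period US dollars. CPI periods are `"YYYY"` annual averages plus
#' quarterly entries such as `"2022Q4"`; source-year amounts use their
#' year's annual average and only the target uses a quarterly index.
#'
#' @param fx Data frame with columns `year`, `rate` (local currency per
#'   USD, positive).
#' @param cpi Data frame with columns `period` (`"YYYY"` or `"YYYYQn"`) and
#'   `index` (positive).
#' @param local_currency ISO code of the local currency (default `"TRY"`).
#' @param target_period CPI period amounts are restated to (default
#'   `"2022Q4"`).
#' @return An object of class `conversion_tables`.
#' @export
conversion_tables <- function(fx, cpi, local_currency = "TRY",
                              target_period = "2022Q4") {
  if (!all(c("year", "rate") %in% names(fx)))
    stop_config("fx table must have columns 'year' and 'rate'")
  if (!all(c("period", "index") %in% names(cpi)))
    stop_config("cpi table must have columns 'period' and 'index'")
  fx$year <- as.integer(fx$year)
  cpi$period <- as.character(cpi$period)
  if (any(!is.finite(fx$rate)) || any(fx$rate <= 0))
    stop_config("fx rates must all be positive")
  if (any(!is.finite(cpi$index)) || any(cpi$index <= 0))
    stop_config("cpi indices must all be positive")
  if (anyDuplicated(fx$year)) stop_config("duplicate year in fx table")
  if (anyDuplicated(cpi$period)) stop_config("duplicate period in cpi table")
  if (!grepl("^[0-9]{4}(Q[1-4])?$", target_period))
    stop_config("target_period must look like 'YYYY' or 'YYYYQn'")
  if (!target_period %in% cpi$period)
    stop_config("target period %s missing from cpi table", target_period)
  structure(list(fx = fx[order(fx$year), c("year", "rate")],
                 cpi = cpi[order(cpi$period), c("period", "index")],
                 local_currency = local_currency,
                 target_period = target_period),
            class = "conversion_tables")
}

#' @export
print.conversion_tables <- function(x, ...) {
  cat(sprintf("<conversion_tables: %s/USD %d-%d, CPI target %s>\n",
              x$local_currency, min(x$fx$year), max(x$fx$year),
              x$target_period))
  invisible(x)
}

#' Read FX and CPI tables from CSV
#'
#' Strictly validated readers for the two table formats: the FX file has
#' columns `year,rate`; the CPI file has columns `period,index`.
#'
#' @param fx_path,cpi_path CSV file paths.
#' @param ... Passed to [conversion_tables()].
#' @return A `conversion_tables` object.
#' @export
read_conversion_tables <- function(fx_path, cpi_path, ...) {
  for (p in c(fx_path, cpi_path)) {
    if (!file.exists(p)) stop_data("conversion table file not found: %s", p)
  }
  fx <- utils::read.csv(fx_path, stringsAsFactors = FALSE)
  cpi <- utils::read.csv(cpi_path, stringsAsFactors = FALSE)
  conversion_tables(fx, cpi, ...)
}

#' Example conversion tables packaged for tests and demos
#'
#' Loads the packaged example FX (TRY per USD, annual averages) and US CPI
#' series. These are illustrative values shipped so the pipeline runs
#' offline; analyses of real data should supply the official ECB and BLS
#' series as CSVs.
#'
#' @return A `conversion_tables` object.
#' @export
example_conversion_tables <- function() {
  read_conversion_tables(
    system.file("extdata", "fx_try_usd.csv", package = "dhicost",
                mustWork = TRUE),
    system.file("extdata", "cpi_us.csv", package = "dhicost",
                mustWork = TRUE))
}

.cpi_index <- function(tables, period) {
  i <- match(as.character(period), tables$cpi$period)
  if (anyNA(i))
    stop_data("CPI period %s missing from table",
              paste(unique(period[is.na(i)]), collapse = ", "))
  tables$cpi$index[i]
}

#' Same-year USD conversion factor
#'
#' The multiplicative factor turning a local-currency amount into that
#' year's US dollars: `1 / fx[year]`.
#'
#' @param year Calendar year (vectorized).
#' @param tables A [conversion_tables()].
#' @return Positive numeric factor(s).
#' @export
conversion_factor <- function(year, tables) {
  i <- match(as.integer(year), tables$fx$year)
  if (anyNA(i))
    stop_data("FX rate for year %s missing from table",
              paste(unique(year[is.na(i)]), collapse = ", "))
  1 / tables$fx$rate[i]
}

#' Inflate same-year USD to the target period
#'
#' Multiplies by `cpi[target] / cpi[year]`, using the source year's annual
#' average index and the target period's index.
#'
#' @param usd_amount Amount in source-year USD (vectorized).
#' @param year Source calendar year.
#' @param tables A [conversion_tables()].
#' @return Amount in target-period USD.
#' @export
inflate_to_target <- function(usd_amount, year, tables) {
  usd_amount * .cpi_index(tables, tables$target_period) /
    .cpi_index(tables, as.character(year))
}

#' Convert a tagged amount to target-period USD
#'
#' End-to-end conversion: amounts in the tables' local currency are divided
#' by the year's average exchange rate, then CPI-inflated to the target
#' period; amounts already in USD skip the FX step. Conversion is linear in
#' the amount and monotone.
#'
#' @param amount Numeric amount(s).
#' @param currency ISO code(s); either the tables' local currency or
#'   `"USD"`.
#' @param year Calendar year(s) the amount was incurred.
#' @param tables A [conversion_tables()].
#' @return Amount(s) in target-period USD.
#' @export
convert_amount <- function(amount, currency, year, tables) {
  n <- max(length(amount), length(currency), length(year))
  amount <- rep_len(amount, n)
  currency <- rep_len(currency, n)
  year <- rep_len(as.integer(year), n)
  known <- currency %in% c("USD", tables$local_currency)
  if (any(!known))
    stop_data("unsupported currency %s (tables cover %s and USD)",
              paste(unique(currency[!known]), collapse = ", "),
              tables$local_currency)
  usd <- amount
  loc <- currency == tables$local_currency
  if (any(loc)) usd[loc] <- amount[loc] * conversion_factor(year[loc], tables)
  inflate_to_target(usd, year, tables)
}
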