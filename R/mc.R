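# Monte Carlo cost simulation with probabilistic sensitivity analysis.
#
# Each iteration draws the five uncertain inputs (hospitalization cost,
# surgical cost, antibiotic therapy duration, re-infection probability,
# lost workdays) and composes them linearly into a per-patient annual
# cost:
#
#   total = hospitalization + surgical
#         + antibiotic_days * antibiotic_cost_per_day
#         + I(reinfection)  * reinfection_episode_cost
#         + lost_workdays   * daily_wage
#
# The re-infection indicator is two-stage: a beta-distributed probability
# is drawn, then a Bernoulli event with that probability, so the
# uncertainty in the rate itself propagates into the totals. Totals are
# composed in the scenario currency (TRY by default, as the inputs are
# quoted) and converted to target-period USD afterwards.

.canonical_inputs <- c("hospitalization_cost", "surgical_cost",
                       "antibiotic_days", "reinfection_rate",
                       "lost_workdays")

#' Monte Carlo scenario definition
#'
#' Bundles the five uncertain input distributions with the unit-cost
#' coefficients that map sampled quantities onto money, the iteration
#' count and the seed. Defaults are the study scenario: triangular
#' hospitalization cost (min 8000, mode 12000, max 18000 TRY), normal
#' surgical cost (mean 6500, SD 1200 TRY), uniform antibiotic duration
#' (10-21 days), beta(3, 20) re-infection rate, and triangular lost
#' workdays (min 7, mode 14, max 28 days). The unit-cost coefficients are
#' not published; the defaults are documented placeholders and should be
#' set to local values for real analyses.
#'
#' @param inputs Named list of [dist_spec()]s; must contain all five
#'   canonical inputs (`hospitalization_cost`, `surgical_cost`,
#'   `antibiotic_days`, `reinfection_rate`, `lost_workdays`).
#' @param antibiotic_cost_per_day Cost of one antibiotic-therapy day.
#' @param reinfection_episode_cost Cost of treating one re-infection
#'   episode.
#' @param daily_wage Daily wage pricing one lost workday (human-capital
#'   approach).
#' @param currency Currency the inputs and coefficients are quoted in.
#' @param cost_year Calendar year of that quotation.
#' @param n_iterations Number of Monte Carlo iterations (default 10000).
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_model`.
#' @export
scenario_model <- function(inputs = default_scenario_inputs(),
                           antibiotic_cost_per_day = 250,
                           reinfection_episode_cost = 9000,
                           daily_wage = 500,
                           currency = "TRY",
                           cost_year = 2022L,
                           n_iterations = 10000L,
                           seed = 1L) {
  missing <- setdiff(.canonical_inputs, names(inputs))
  if (length(missing))
    stop_config("scenario inputs missing: %s", paste(missing, collapse = ", "))
  for (nm in names(inputs)) {
    if (!inherits(inputs[[nm]], "dist_spec"))
      stop_config("input '%s' is not a dist_spec", nm)
  }
  coef <- c(antibiotic_cost_per_day, reinfection_episode_cost, daily_wage)
  if (any(!is.finite(coef)) || any(coef < 0))
    stop_config("unit-cost coefficients must be nonnegative")
  if (!is.numeric(n_iterations) || n_iterations < 2)
    stop_config("n_iterations must be at least 2")
  structure(list(inputs = inputs,
                 coefficients = list(
                   antibiotic_cost_per_day = antibiotic_cost_per_day,
                   reinfection_episode_cost = reinfection_episode_cost,
                   daily_wage = daily_wage),
                 currency = currency, cost_year = as.integer(cost_year),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "scenario_model")
}

#' Default scenario input distributions
#'
#' @return Named list of the five canonical [dist_spec()]s.
#' @export
default_scenario_inputs <- function() {
  list(
    hospitalization_cost = dist_spec("triangular", min = 8000, mode = 12000,
                                     max = 18000, units = "TRY"),
    surgical_cost = dist_spec("normal", mean = 6500, sd = 1200,
                              units = "TRY", truncate_at_zero = TRUE),
    antibiotic_days = dist_spec("uniform", min = 10, max = 21,
                                units = "days"),
    reinfection_rate = dist_spec("beta", alpha = 3, beta = 20),
    lost_workdays = dist_spec("triangular", min = 7, mode = 14, max = 28,
                              units = "days"))
}

#' Read a scenario configuration from YAML
#'
#' Mirrors [scenario_model()]: an `inputs` map of distribution entries
#' (`family` plus parameters), a `coefficients` map, and optional
#' `currency`, `cost_year`, `n_iterations`, `seed`.
#'
#' @param path YAML file path.
#' @return A `scenario_model`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_config("scenario file not found: %s", path)
  y <- yaml::read_yaml(path)
  inputs <- default_scenario_inputs()
  for (nm in names(y$inputs)) {
    s <- y$inputs[[nm]]
    args <- s[setdiff(names(s), c("family", "bounds", "truncate_at_zero",
                                  "units"))]
    inputs[[nm]] <- do.call(dist_spec, c(
      list(family = s$family), args,
      list(bounds = if (!is.null(s$bounds)) unlist(s$bounds),
           truncate_at_zero = isTRUE(s$truncate_at_zero), units = s$units)))
  }
  co <- y$coefficients %||% list()
  scenario_model(inputs = inputs,
                 antibiotic_cost_per_day = co$antibiotic_cost_per_day %||% 250,
                 reinfection_episode_cost = co$reinfection_episode_cost %||% 9000,
                 daily_wage = co$daily_wage %||% 500,
                 currency = y$currency %||% "TRY",
                 cost_year = y$cost_year %||% 2022L,
                 n_iterations = y$n_iterations %||% 10000L,
                 seed = y$seed %||% 1L)
}

#' Run the Monte Carlo cost simulation
#'
#' Draws all inputs for `n_iterations` iterations, composes the linear
#' per-iteration total, converts to target-period USD, and summarizes as
#' the mean with a percentile 95% confidence interval (2.5th/97.5th
#' percentiles; a normal-approximation interval is available via
#' `ci_method`). Probabilistic sensitivity is the Spearman rank
#' correlation between each input's draws and the totals. Identical seeds
#' give bit-identical results.
#'
#' @param model A [scenario_model()].
#' @param tables A [conversion_tables()]; `NULL` keeps totals in the
#'   scenario currency.
#' @param ci_method `"percentile"` (default) or `"normal"`.
#' @param event_rule Passed to the re-infection event draw; see
#'   [sample_event()].
#' @return An object of class `simulation_result` with fields
#'   `iteration_totals`, `mean_total`, `ci95`, `sensitivity`, `draws`,
#'   `currency`, `seed`, `n_iterations`.
#' @export
run_simulation <- function(model, tables = NULL,
                           ci_method = c("percentile", "normal"),
                           event_rule = c("uniform", "integer_percent")) {
  if (!inherits(model, "scenario_model"))
    stop_config("model must be built with scenario_model()")
  ci_method <- match.arg(ci_method)
  event_rule <- match.arg(event_rule)
  n <- model$n_iterations
  co <- model$coefficients

  draws <- .with_seed(model$seed, {
    d <- lapply(model$inputs[.canonical_inputs], sample_dist, n = n)
    u <- stats::runif(n)
    d$reinfection_event <- if (event_rule == "uniform") {
      u < d$reinfection_rate
    } else {
      # spreadsheet-compatible two-digit rule (see sample_event)
      floor(u * 100) <= round(100 * d$reinfection_rate)
    }
    d
  })

  total_local <- draws$hospitalization_cost + draws$surgical_cost +
    draws$antibiotic_days * co$antibiotic_cost_per_day +
    as.numeric(draws$reinfection_event) * co$reinfection_episode_cost +
    draws$lost_workdays * co$daily_wage

  if (!is.null(tables)) {
    totals <- convert_amount(total_local, model$currency, model$cost_year,
                             tables)
    currency <- paste0("USD-", tables$target_period)
  } else {
    totals <- total_local
    currency <- sprintf("%s-%d", model$currency, model$cost_year)
  }

  mean_total <- mean(totals)
  ci <- if (ci_method == "percentile") {
    unname(stats::quantile(totals, c(0.025, 0.975), type = 7))
  } else {
    se <- stats::sd(totals) / sqrt(n)
    mean_total + c(-1, 1) * stats::qnorm(0.975) * se
  }
  sens <- vapply(.canonical_inputs, function(nm) {
    x <- draws[[nm]]
    if (stats::sd(x) == 0 || stats::sd(totals) == 0) return(0)
    stats::cor(x, totals, method = "spearman")
  }, numeric(1))

  structure(list(iteration_totals = totals, mean_total = mean_total,
                 ci95 = c(low = ci[1], high = ci[2]),
                 sensitivity = sens, draws = draws, currency = currency,
                 ci_method = ci_method, seed = model$seed, n_iterations = n),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %d iterations, %s>\n", x$n_iterations,
              x$currency))
  cat(sprintf("  mean total %.2f, 95%% CI [%.2f, %.2f] (%s)\n",
              x$mean_total, x$ci95[["low"]], x$ci95[["high"]], x$ci_method))
  s <- sort(abs(x$sensitivity), decreasing = TRUE)
  cat("  sensitivity (|Spearman rho|): ",
      paste(sprintf("%s=%.2f", names(s), s), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convergence diagnostics for a simulation run
#'
#' Splits the iteration sequence into consecutive batches and reports the
#' running mean and percentile-CI half-width after each batch, plus the
#' absolute and relative shift of the running mean over the final batch.
#' The run is flagged non-converged when the final relative shift exceeds
#' `tol`.
#'
#' @param result A `simulation_result`.
#' @param batch_size Iterations per batch; at most half the run.
#' @param tol Relative mean-shift tolerance (default 0.005).
#' @return Data frame with one row per batch and attribute `converged`.
#' @export
convergence_report <- function(result, batch_size = 1000L, tol = 0.005) {
  n <- result$n_iterations
  if (batch_size < 1L || n < 2L * batch_size)
    stop_config("batch_size must satisfy n_iterations >= 2 * batch_size")
  totals <- result$iteration_totals
  ends <- seq(batch_size, n, by = batch_size)
  if (ends[length(ends)] != n) ends <- c(ends, n)
  rows <- lapply(ends, function(e) {
    x <- totals[seq_len(e)]
    q <- stats::quantile(x, c(0.025, 0.975), type = 7)
    data.frame(iterations = e, running_mean = mean(x),
               ci_half_width = unname(q[2] - q[1]) / 2)
  })
  rep <- do.call(rbind, rows)
  k <- nrow(rep)
  shift <- if (k > 1) abs(rep$running_mean[k] - rep$running_mean[k - 1]) else 0
  rel <- if (rep$running_mean[k] != 0) shift / abs(rep$running_mean[k]) else 0
  rep$mean_shift <- c(NA, abs(diff(rep$running_mean)))
  attr(rep, "converged") <- rel <= tol
  attr(rep, "final_relative_shift") <- rel
  rep
}

#' Export a simulation result as JSON
#'
#' Full-precision export of summaries and per-input sensitivities;
#' iteration totals are included optionally (they can also be written as
#' CSV by the pipeline).
#'
#' @param result A `simulation_result`.
#' @param path Output file.
#' @param include_totals Include the full iteration vector (default
#'   `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_simulation_json <- function(result, path, include_totals = FALSE) {
  obj <- list(mean_total = result$mean_total,
              ci95 = as.list(result$ci95),
              ci_method = result$ci_method,
              sensitivity = as.list(result$sensitivity),
              currency = result$currency,
              seed = result$seed,
              n_iterations = result$n_iterations)
  if (include_totals) obj$iteration_totals <- result$iteration_totals
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
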