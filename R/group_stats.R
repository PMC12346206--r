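# Rank-based k-group comparison of visit counts and cost components
# across surgical-intervention groups. The tie-corrected H statistic is
# computed directly on average ranks (and cross-checked against
# stats::kruskal.test in the test suite); the null distribution comes from
# the chi-square approximation with k-1 degrees of freedom, from full
# enumeration of group assignments when feasible, or from random
# permutations.

.kw_h <- function(ranks, g, tie_correction) {
  N <- length(ranks)
  rs <- tapply(ranks, g, sum)
  ns <- tabulate(g)
  h <- 12 / (N * (N + 1)) * sum(rs^2 / ns) - 3 * (N + 1)
  if (tie_correction == 0) 0 else h / tie_correction
}

.tie_correction <- function(x) {
  N <- length(x)
  t <- table(x)
  1 - sum(t^3 - t) / (N^3 - N)
}

# number of distinct assignments of N pooled values to groups of sizes ns
.n_assignments <- function(ns) {
  exp(lgamma(sum(ns) + 1) - sum(lgamma(ns + 1)))
}

.enumerate_assignments <- function(ranks, ns, fun) {
  # recursively choose which pooled positions fall in each group
  out <- new.env()
  out$vals <- numeric(0)
  recurse <- function(avail, gi, assignment) {
    if (gi == length(ns)) {
      assignment[avail] <- gi
      out$vals <- c(out$vals, fun(assignment))
      return(invisible())
    }
    picks <- utils::combn(avail, ns[gi], simplify = FALSE)
    for (p in picks) {
      assignment[p] <- gi
      recurse(setdiff(avail, p), gi + 1L, assignment)
    }
  }
  recurse(seq_along(ranks), 1L, integer(length(ranks)))
  out$vals
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Computes the H statistic on average ranks with the standard tie
#' correction (division by `1 - sum(t^3 - t) / (N^3 - N)` over tie groups
#' of size `t`). The p-value uses the chi-square approximation with
#' `k - 1` degrees of freedom, or a permutation null: full enumeration of
#' all distinct group assignments when their number is at most
#' `exact_limit` (always the case for pooled n <= 12 at default settings),
#' otherwise `n_perm` random permutations with the add-one estimator
#' `(1 + #(H* >= H)) / (n_perm + 1)`.
#'
#' @param samples List (length >= 2) of numeric vectors, one per group.
#' @param method `"chi2_approx"` (default) or `"permutation"`.
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param exact_limit Maximum number of assignments enumerated exactly.
#' @param seed Optional seed for the random-permutation fallback.
#' @return List of class `kw_result`: `H`, `p_value`, `df`, `method`,
#'   `n`, `exact` (whether the permutation null was enumerated).
#' @export
kruskal_wallis <- function(samples, method = c("chi2_approx", "permutation"),
                           n_perm = 10000L, exact_limit = 1e5,
                           seed = NULL) {
  method <- match.arg(method)
  if (!is.list(samples) || length(samples) < 2L)
    stop_data("kruskal_wallis needs at least 2 groups")
  if (any(vapply(samples, length, 1L) == 0L))
    stop_data("kruskal_wallis: empty group")
  x <- unlist(samples, use.names = FALSE)
  if (length(x) < 3L) stop_data("kruskal_wallis needs at least 3 observations")
  g <- rep(seq_along(samples), vapply(samples, length, 1L))
  N <- length(x)
  k <- length(samples)
  ranks <- rank(x)
  tc <- .tie_correction(x)
  H <- .kw_h(ranks, g, tc)
  exact <- FALSE
  if (method == "chi2_approx") {
    p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
    if (tc == 0) p <- 1   # all pooled values tied: no evidence of separation
  } else {
    ns <- vapply(samples, length, 1L)
    stat <- function(assignment) .kw_h(ranks, assignment, tc)
    if (tc == 0) {
      p <- 1
    } else if (.n_assignments(ns) <= exact_limit) {
      hs <- .enumerate_assignments(ranks, ns, stat)
      p <- mean(hs >= H - 1e-12)
      exact <- TRUE
    } else {
      draw <- function() {
        perm <- sample.int(N)
        .kw_h(ranks[perm], g, tc)
      }
      hs <- if (is.null(seed)) replicate(n_perm, draw())
            else .with_seed(seed, replicate(n_perm, draw()))
      p <- (1 + sum(hs >= H - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(H = H, p_value = p, df = k - 1, method = method, n = N,
                 exact = exact),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g (%s%s)\n",
              x$H, x$df, x$p_value, x$method,
              if (x$exact) ", exact enumeration" else ""))
  invisible(x)
}

#' Compare a cohort outcome across surgical-intervention groups
#'
#' Groups the cohort by intervention and compares `value_field` across
#' groups with the tie-corrected Kruskal-Wallis test. `value_field` is
#' either `"outpatient_visits"` or a cost category (including `"total"`
#' and `"subtotal_without_surgical"`), in which case each patient's items
#' in that category are converted to target-period USD and summed first.
#' Groups of a single patient stay in the test (their rank is
#' well-defined) but are flagged and their SD is suppressed.
#'
#' @param cohort A `dhi_cohort`.
#' @param value_field Field to compare.
#' @param tables [conversion_tables()]; required for cost fields.
#' @param method,n_perm,seed Passed to [kruskal_wallis()].
#' @return Object of class `group_comparison`: a `groups` summary table
#'   plus `H`, `p_value`, `method`, `value_field`.
#' @export
compare_by_intervention <- function(cohort, value_field,
                                    tables = NULL,
                                    method = c("chi2_approx", "permutation"),
                                    n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  cost_fields <- c(cost_categories(), "total", "subtotal_without_surgical")
  if (value_field == "outpatient_visits") {
    values <- cohort$patients$outpatient_visits
  } else if (value_field %in% cost_fields) {
    if (is.null(tables))
      stop_data("conversion tables are required to compare cost field '%s'",
                value_field)
    values <- aggregate_cohort(cohort, tables)[[value_field]]
  } else {
    stop_data("unknown value field '%s'", value_field)
  }
  iv <- factor(cohort$patients$intervention, levels = intervention_levels())
  if (anyNA(iv)) stop_data("cohort contains non-canonical intervention labels")
  present <- levels(iv)[tabulate(iv, nbins = nlevels(iv)) > 0]
  samples <- lapply(present, function(g) values[iv == g])
  names(samples) <- present
  kw <- kruskal_wallis(samples, method = method, n_perm = n_perm, seed = seed)
  groups <- do.call(rbind, lapply(present, function(gl) {
    v <- samples[[gl]]
    data.frame(intervention = gl, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = stats::median(v), min = min(v), max = max(v),
               singleton = length(v) == 1L, stringsAsFactors = FALSE)
  }))
  groups$formatted <- ifelse(groups$singleton,
    sprintf("%.2f", groups$mean),
    sprintf("%.2f ± %.2f %.2f (%.2f–%.2f)", groups$mean, groups$sd,
            groups$median, groups$min, groups$max))
  structure(list(groups = groups, H = kw$H, p_value = kw$p_value,
                 df = kw$df, method = kw$method, exact = kw$exact,
                 value_field = value_field),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %s by surgical intervention\n", x$value_field))
  w <- max(nchar(x$groups$intervention))
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf("  %-*s  %2d  %s\n", w, x$groups$intervention[i],
                x$groups$n[i], x$groups$formatted[i]))
  }
  cat(sprintf("  K-W %.3f, p = %.3f (%s)\n", x$H, x$p_value, x$method))
  invisible(x)
}

#' Write a group comparison as CSV and aligned text
#'
#' @param comparison A `group_comparison`.
#' @param csv_path,txt_path Output paths (`NULL` skips).
#' @return Invisibly, the comparison.
#' @export
write_comparison <- function(comparison, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- comparison$groups[, c("intervention", "n", "mean", "sd", "median",
                                 "min", "max")]
    tab$H <- comparison$H
    tab$p_value <- comparison$p_value
    utils::write.csv(tab, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); on.exit({ sink(); close(con) })
    print(comparison)
  }
  invisible(comparison)
}
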