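#' Stochastic input specification
#'
#' A `dist_spec` describes one uncertain model input: a distribution family,
#' its parameters, optional truncation, and bookkeeping metadata (name,
#' units). Specs drive both the synthetic-cohort generator and the Monte
#' Carlo cost simulator, so the supported families cover the classic
#' probabilistic-sensitivity-analysis set (triangular, normal, uniform,
#' beta, bernoulli) plus two families used for cohort emulation: lognormal
#' (right-skewed nonnegative cost components) and negbinom (over-dispersed
#' visit counts, optionally shifted to a hard minimum).
#'
#' @param family One of `"triangular"`, `"normal"`, `"uniform"`, `"beta"`,
#'   `"bernoulli"`, `"lognormal"`, `"negbinom"`.
#' @param ... Family parameters:
#'   \describe{
#'     \item{triangular}{`min`, `mode`, `max` with `min <= mode <= max`}
#'     \item{normal}{`mean`, `sd` with `sd > 0`}
#'     \item{uniform}{`min`, `max` with `min < max`}
#'     \item{beta}{`alpha`, `beta`, both positive}
#'     \item{bernoulli}{`p` in `[0, 1]`}
#'     \item{lognormal}{either `meanlog`/`sdlog`, or `mean`/`sd` on the
#'       natural scale (moment-matched internally)}
#'     \item{negbinom}{`mu`, `size` (> 0), optional integer `shift` added
#'       to every draw (default 0)}
#'   }
#' @param name Optional label used in reports.
#' @param units Optional unit string (e.g. `"TRY"`, `"days"`).
#' @param truncate_at_zero If `TRUE`, negative draws are rejected and
#'   redrawn.
#' @param bounds Optional length-2 numeric `c(lower, upper)`; draws outside
#'   are rejected and redrawn (after at most 1000 rounds the survivors are
#'   clipped, so a badly mis-specified spec still terminates).
#'
#' @return An object of class `dist_spec`.
#' @examples
#' sample_dist(dist_spec("triangular", min = 8000, mode = 12000, max = 18000), 5)
#' @export
dist_spec <- function(family, ..., name = NULL, units = NULL,
                      truncate_at_zero = FALSE, bounds = NULL) {
  family <- match.arg(family, c("triangular", "normal", "uniform", "beta",
                                "bernoulli", "lognormal", "negbinom"))
  params <- list(...)
  num <- function(key) {
    v <- params[[key]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("dist_spec(%s): missing or non-numeric parameter '%s'",
                   family, key), call. = FALSE)
    as.numeric(v)
  }
  params <- switch(family,
    triangular = {
      p <- list(min = num("min"), mode = num("mode"), max = num("max"))
      if (!(p$min <= p$mode && p$mode <= p$max))
        stop("triangular requires min <= mode <= max", call. = FALSE)
      p
    },
    normal = {
      p <- list(mean = num("mean"), sd = num("sd"))
      if (p$sd <= 0) stop("normal requires sd > 0", call. = FALSE)
      p
    },
    uniform = {
      p <- list(min = num("min"), max = num("max"))
      if (p$min >= p$max) stop("uniform requires min < max", call. = FALSE)
      p
    },
    beta = {
      p <- list(alpha = num("alpha"), beta = num("beta"))
      if (p$alpha <= 0 || p$beta <= 0)
        stop("beta requires alpha > 0 and beta > 0", call. = FALSE)
      p
    },
    bernoulli = {
      p <- list(p = num("p"))
      if (p$p < 0 || p$p > 1) stop("bernoulli requires p in [0, 1]", call. = FALSE)
      p
    },
    lognormal = {
      if (!is.null(params$meanlog)) {
        p <- list(meanlog = num("meanlog"), sdlog = num("sdlog"))
      } else {
        m <- num("mean"); s <- num("sd")
        if (m <= 0 || s <= 0)
          stop("lognormal moment matching requires mean > 0 and sd > 0",
               call. = FALSE)
        s2 <- log(1 + (s / m)^2)
        p <- list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
      }
      if (p$sdlog <= 0) stop("lognormal requires sdlog > 0", call. = FALSE)
      p
    },
    negbinom = {
      p <- list(mu = num("mu"), size = num("size"),
                shift = if (is.null(params$shift)) 0 else num("shift"))
      if (p$mu <= 0 || p$size <= 0)
        stop("negbinom requires mu > 0 and size > 0", call. = FALSE)
      p
    })
  if (!is.null(bounds)) {
    if (!is.numeric(bounds) || length(bounds) != 2L || bounds[1] > bounds[2])
      stop("bounds must be c(lower, upper) with lower <= upper", call. = FALSE)
  }
  structure(list(family = family, params = params, name = name,
                 units = units, truncate_at_zero = isTRUE(truncate_at_zero),
                 bounds = bounds),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<dist_spec %s(%s)%s%s>\n",
              x$family, ps,
              if (!is.null(x$bounds))
                sprintf(" in [%g, %g]", x$bounds[1], x$bounds[2]) else "",
              if (x$truncate_at_zero) " >=0" else ""))
  invisible(x)
}

# raw (untruncated) draws; triangular uses the inverse CDF so one uniform
# deviate maps to one draw
.sample_raw <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
    triangular = {
      u <- stats::runif(n)
      a <- p$min; m <- p$mode; b <- p$max
      if (a == b) return(rep(a, n))
      fc <- (m - a) / (b - a)
      ifelse(u < fc,
             a + sqrt(u * (b - a) * (m - a)),
             b - sqrt((1 - u) * (b - a) * (b - m)))
    },
    normal   = stats::rnorm(n, p$mean, p$sd),
    uniform  = stats::runif(n, p$min, p$max),
    beta     = stats::rbeta(n, p$alpha, p$beta),
    bernoulli = as.numeric(stats::runif(n) < p$p),
    lognormal = stats::rlnorm(n, p$meanlog, p$sdlog),
    negbinom = p$shift + stats::rnbinom(n, size = p$size, mu = p$mu))
}

#' Draw from a stochastic input specification
#'
#' Draws use R's global random number stream, so a single `set.seed()` call
#' makes every downstream draw reproducible. Truncation (the `bounds` and
#' `truncate_at_zero` fields of the spec) is applied by rejection sampling.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  if (n == 0L) return(numeric(0))
  lo <- -Inf; hi <- Inf
  if (spec$truncate_at_zero) lo <- 0
  if (!is.null(spec$bounds)) {
    lo <- max(lo, spec$bounds[1]); hi <- min(hi, spec$bounds[2])
  }
  x <- .sample_raw(spec, n)
  if (is.finite(lo) || is.finite(hi)) {
    for (round in seq_len(1000L)) {
      bad <- which(x < lo | x > hi)
      if (!length(bad)) break
      x[bad] <- .sample_raw(spec, length(bad))
    }
    x <- pmin(pmax(x, lo), hi)
  }
  x
}

#' Theoretical mean of a spec's untruncated distribution
#'
#' Closed-form mean of the family, ignoring truncation. Used by the
#' convergence and sensitivity reports as a reference point.
#'
#' @param spec A [dist_spec()].
#' @return A single numeric value.
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    triangular = (p$min + p$mode + p$max) / 3,
    normal = p$mean,
    uniform = (p$min + p$max) / 2,
    beta = p$alpha / (p$alpha + p$beta),
    bernoulli = p$p,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    negbinom = p$shift + p$mu)
}

#' Sample a binary event
#'
#' Returns `TRUE` with probability `p`. The default rule draws a uniform
#' deviate `u` on (0, 1) and fires when `u < p`, which is exact for any
#' `p`. A two-digit integer rule is also available for compatibility with
#' spreadsheet-style simulations that draw an integer 00-99 and fire on
#' values up to `round(100 p)` inclusive; note that rule fires with
#' probability `(round(100 p) + 1) / 100` (e.g. 67% at a nominal 66%), which
#' is why it is not the default.
#'
#' @param p Event probability in `[0, 1]`.
#' @param n Number of draws.
#' @param rule `"uniform"` (exact, default) or `"integer_percent"`.
#' @return Logical vector of length `n`.
#' @export
sample_event <- function(p, n = 1L, rule = c("uniform", "integer_percent")) {
  rule <- match.arg(rule)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("event probability must be a single value in [0, 1]", call. = FALSE)
  if (rule == "uniform") {
    stats::runif(n) < p
  } else {
    r <- as.integer(floor(stats::runif(n) * 100))
    r <= round(100 * p)
  }
}
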