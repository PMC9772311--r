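#' Specify the distribution of one stochastic input
#'
#' Declares how a single exposure factor varies across the cohort (or across
#' uncertainty draws). Supported families and their parameters:
#'
#' * `point`: `value` — a degenerate constant.
#' * `normal`: `mean`, `sd` — questionnaire-style summaries (mean +/- SD).
#' * `lognormal`: `mean`, `gsd` — parameterised by the *arithmetic* mean and
#'   the geometric standard deviation, the natural summary pair for
#'   right-skewed occupational-hygiene concentration data. On the log scale
#'   `sdlog = log(gsd)` and `meanlog = log(mean) - sdlog^2 / 2`, so the
#'   arithmetic mean of draws matches `mean`.
#' * `uniform`: `low`, `high`.
#' * `triangular`: `low`, `mode`, `high`.
#'
#' `truncation = c(low, high)` rejects and resamples draws outside the
#' bounds. Physical factors are typically truncated at zero from below.
#'
#' @param variable Name of the exposure factor this spec describes
#'   (one of `C`, `IR`, `ED`, `EF`, `BW`, `ET`).
#' @param family Distribution family (see above).
#' @param ... Family-specific numeric parameters.
#' @param truncation Optional numeric `c(low, high)`; use `-Inf`/`Inf` for a
#'   one-sided bound.
#' @return A list of class `dist_spec`.
#' @examples
#' dist_spec("BW", "normal", mean = 74.45, sd = 13.68, truncation = c(0, Inf))
#' dist_spec("C", "lognormal", mean = 0.039, gsd = 2.5)
#' @export
dist_spec <- function(variable,
                      family = c("point", "normal", "lognormal", "uniform",
                                 "triangular"),
                      ..., truncation = NULL) {
  family <- match.arg(family)
  params <- list(...)
  need <- switch(family,
                 point = "value",
                 normal = c("mean", "sd"),
                 lognormal = c("mean", "gsd"),
                 uniform = c("low", "high"),
                 triangular = c("low", "mode", "high"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("family '", family, "' requires parameter(s): ",
         paste(missing, collapse = ", "))
  }
  params <- params[need]
  if (family == "normal" && params$sd <= 0) stop("'sd' must be positive")
  if (family == "lognormal") {
    if (params$mean <= 0) stop("lognormal 'mean' must be positive")
    if (params$gsd <= 1) stop("'gsd' must exceed 1 (use 'point' for gsd = 1)")
  }
  if (family == "uniform" && params$low >= params$high) {
    stop("'low' must be below 'high'")
  }
  if (family == "triangular" &&
      !(params$low <= params$mode && params$mode <= params$high &&
        params$low < params$high)) {
    stop("triangular requires low <= mode <= high with low < high")
  }
  if (!is.null(truncation)) {
    if (length(truncation) != 2L || truncation[1L] >= truncation[2L]) {
      stop("'truncation' must be c(low, high) with low < high")
    }
  }
  structure(list(variable = variable, family = family, params = params,
                 truncation = truncation),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  tr <- if (is.null(x$truncation)) "" else
    sprintf(" truncated [%g, %g]", x$truncation[1L], x$truncation[2L])
  cat(sprintf("<dist_spec> %s ~ %s(%s)%s\n", x$variable, x$family, p, tr))
  invisible(x)
}

rtriangular <- function(n, low, mode, high) {
  # inverse-CDF draw; handles degenerate mode-at-edge cases
  u <- stats::runif(n)
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

draw_family <- function(spec, n) {
  p <- spec$params
  switch(spec$family,
         point = rep(p$value, n),
         normal = stats::rnorm(n, p$mean, p$sd),
         lognormal = {
           sdlog <- log(p$gsd)
           stats::rlnorm(n, meanlog = log(p$mean) - sdlog^2 / 2,
                         sdlog = sdlog)
         },
         uniform = stats::runif(n, p$low, p$high),
         triangular = rtriangular(n, p$low, p$mode, p$high))
}

#' Draw from a distribution spec
#'
#' Samples `n` values from the declared family using the current RNG state
#' (seed upstream with `set.seed()` for reproducibility). Truncation is
#' enforced by rejection: out-of-bounds draws are replaced by fresh draws,
#' with a retry budget of `max_rounds` resampling passes — unbiased, and
#' cheap for the mild truncations typical of exposure factors. A truncation
#' region that retains essentially no probability mass exhausts the budget
#' and raises an error.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws; >= 1.
#' @param max_rounds Maximum rejection-resampling passes (default 1000).
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n, max_rounds = 1000L) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  x <- draw_family(spec, n)
  if (is.null(spec$truncation)) return(x)
  lo <- spec$truncation[1L]
  hi <- spec$truncation[2L]
  if (spec$family == "point") {
    if (spec$params$value < lo || spec$params$value > hi) {
      stop("point value lies outside its truncation bounds")
    }
    return(x)
  }
  bad <- which(x < lo | x > hi)
  rounds <- 0L
  while (length(bad)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop("truncation [", lo, ", ", hi, "] for '", spec$variable,
           "' retains too little probability mass (rejection budget ",
           "exhausted after ", max_rounds, " rounds)")
    }
    x[bad] <- draw_family(spec, length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Monte Carlo run configuration
#'
#' @param n_iterations Number of iterations (default 10000).
#' @param seed Optional integer master seed; `NULL` uses the current RNG
#'   state.
#' @param percentiles Probabilities reported by [summarize_draws()]
#'   (default 5th, 50th, 95th).
#' @return A list of class `mc_config`.
#' @export
mc_config <- function(n_iterations = 10000L, seed = NULL,
                      percentiles = c(0.05, 0.5, 0.95)) {
  if (n_iterations < 1) stop("'n_iterations' must be >= 1")
  if (any(percentiles <= 0) || any(percentiles >= 1)) {
    stop("'percentiles' must lie strictly in (0, 1)")
  }
  structure(list(n_iterations = as.integer(n_iterations), seed = seed,
                 percentiles = sort(percentiles)),
            class = "mc_config")
}
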