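#' Specification of a synthetic occupational cohort
#'
#' Describes a simulated personal-sampling study: a cohort of workers with
#' questionnaire exposure factors, and per-shift sorbent-tube records for
#' each analyte. Defaults emulate the bundled carpet-factory conditions: 75
#' workers, 3 samples each, 22 field blanks, questionnaire factors normal at
#' the cohort mean +/- SD truncated above zero, and right-skewed lognormal
#' shift concentrations with arithmetic means 0.039 mg/m3 (1,3-butadiene)
#' and 12.108 mg/m3 (styrene) at a geometric standard deviation of 2.5.
#'
#' Sorbent masses are generated by inverting the reduction formula —
#' `mass_front = C_true * recovery * flow * duration + blank` — so that
#' [concentration_from_record()] recovers `C_true` exactly when
#' `mass_noise_gsd = 1`. Setting `mass_noise_gsd > 1` multiplies the net
#' mass by lognormal noise with that GSD, separating inversion correctness
#' from measurement-noise behaviour. Blanks are a fixed small fraction of
#' the analyte's typical front mass (default 0.5%, consistent with field
#' blanks below 1% of sample values).
#'
#' @param n_workers Number of workers (default 75).
#' @param samples_per_worker Consecutive samples per worker shift (default 3).
#' @param n_blanks Field blanks collected (default 22).
#' @param factor_distributions Named list of [dist_spec()] for `BW`, `ED`,
#'   `EF`, `ET`.
#' @param concentration_distributions Named list (by analyte) of
#'   [dist_spec()] for the true shift concentration.
#' @param recovery Named vector of desorption efficiencies by analyte.
#' @param flow_rate Pump flow in L/min (default 0.2).
#' @param duration_range Sampling-duration bounds in minutes
#'   (default c(70, 120)).
#' @param blank_fraction Blank mass as a fraction of the analyte's typical
#'   front mass (default 0.005).
#' @param mass_noise_gsd Multiplicative lognormal noise GSD on net sorbent
#'   mass; 1 (default) disables noise.
#' @param seed Optional integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_workers = 75L, samples_per_worker = 3L,
                        n_blanks = 22L,
                        factor_distributions = default_factor_distributions(),
                        concentration_distributions =
                          default_concentration_distributions(),
                        recovery = c(BD = 0.87, ST = 0.89),
                        flow_rate = 0.2, duration_range = c(70, 120),
                        blank_fraction = 0.005, mass_noise_gsd = 1,
                        seed = NULL) {
  if (n_workers < 1L || samples_per_worker < 1L || n_blanks < 0L) {
    stop("counts must be positive (n_blanks may be 0)")
  }
  if (any(recovery <= 0) || any(recovery > 1)) {
    stop("'recovery' values must lie in (0, 1]")
  }
  if (duration_range[1L] >= duration_range[2L]) {
    stop("'duration_range' must be c(low, high) with low < high")
  }
  if (mass_noise_gsd < 1) stop("'mass_noise_gsd' must be >= 1")
  analytes <- names(concentration_distributions)
  if (is.null(analytes) || !all(analytes %in% names(recovery))) {
    stop("every analyte in 'concentration_distributions' needs a recovery")
  }
  structure(list(
    n_workers = as.integer(n_workers),
    samples_per_worker = as.integer(samples_per_worker),
    n_blanks = as.integer(n_blanks),
    factor_distributions = factor_distributions,
    concentration_distributions = concentration_distributions,
    recovery = recovery, flow_rate = flow_rate,
    duration_range = duration_range, blank_fraction = blank_fraction,
    mass_noise_gsd = mass_noise_gsd, seed = seed
  ), class = "cohort_spec")
}

#' Default questionnaire-factor distributions (cohort means +/- SD)
#' @return Named list of [dist_spec()] for `BW`, `ED`, `EF`, `ET`.
#' @export
default_factor_distributions <- function() {
  pos <- c(0, Inf)
  list(
    BW = dist_spec("BW", "normal", mean = 74.45, sd = 13.68,
                   truncation = pos),
    ED = dist_spec("ED", "normal", mean = 29.66, sd = 1.60, truncation = pos),
    EF = dist_spec("EF", "normal", mean = 301.06, sd = 12.87,
                   truncation = c(0, 366)),
    ET = dist_spec("ET", "normal", mean = 10.81, sd = 1.89,
                   truncation = c(0, 24))
  )
}

#' Default shift-concentration distributions for the bundled analytes
#' @param gsd Geometric standard deviation (default 2.5).
#' @return Named list of lognormal [dist_spec()] by analyte.
#' @export
default_concentration_distributions <- function(gsd = 2.5) {
  list(
    BD = dist_spec("C", "lognormal", mean = 0.039, gsd = gsd),
    ST = dist_spec("C", "lognormal", mean = 12.108, gsd = gsd)
  )
}

dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
         point = p$value,
         normal = p$mean,
         lognormal = p$mean,
         uniform = (p$low + p$high) / 2,
         triangular = (p$low + p$mode + p$high) / 3)
}

#' Generate a synthetic sampling study
#'
#' Draws worker questionnaire factors, then for every worker, analyte and
#' shift slot draws a true breathing-zone concentration and a uniform
#' sampling duration, and constructs the sorbent-tube record whose reduction
#' reproduces that concentration (see [cohort_spec()] for the mass
#' equation). The generating parameters are returned alongside the data as
#' `truth`, enabling parameter-recovery checks.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `synthetic_study`: `workers` (data.frame of
#'   `worker_id`, `BW`, `ED`, `EF`, `ET`), `records` (a [sampling_records()]
#'   table), `blanks` (data.frame of blank masses by analyte), `truth` (the
#'   spec plus the per-record true concentrations).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(derive_subseed(spec$seed, "cohort"))
  nw <- spec$n_workers
  ids <- sprintf("W%03d", seq_len(nw))
  workers <- data.frame(worker_id = ids, stringsAsFactors = FALSE)
  for (v in c("BW", "ED", "EF", "ET")) {
    workers[[v]] <- sample_dist(spec$factor_distributions[[v]], nw)
  }

  analytes <- names(spec$concentration_distributions)
  ns <- spec$samples_per_worker
  rec_list <- lapply(analytes, function(a) {
    n <- nw * ns
    c_true <- sample_dist(spec$concentration_distributions[[a]], n)
    duration <- stats::runif(n, spec$duration_range[1L],
                             spec$duration_range[2L])
    recov <- spec$recovery[[a]]
    typical_mass <- dist_mean(spec$concentration_distributions[[a]]) *
      recov * spec$flow_rate * mean(spec$duration_range)
    blank <- spec$blank_fraction * typical_mass
    net <- c_true * recov * spec$flow_rate * duration
    if (spec$mass_noise_gsd > 1) {
      sdlog <- log(spec$mass_noise_gsd)
      net <- net * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    }
    data.frame(worker_id = rep(ids, each = ns), analyte = a,
               mass_front = net + blank, mass_rear = 0,
               blank_mass = blank, flow_rate = spec$flow_rate,
               duration = duration, recovery = recov, c_true = c_true,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec_list)
  c_true <- rec$c_true
  rec$c_true <- NULL
  class(rec) <- c("sampling_records", "data.frame")

  blanks <- if (spec$n_blanks == 0L) {
    data.frame(blank_id = character(0), analyte = character(0),
               mass = numeric(0), stringsAsFactors = FALSE)
  } else do.call(rbind, lapply(analytes, function(a) {
    typical_mass <- dist_mean(spec$concentration_distributions[[a]]) *
      spec$recovery[[a]] * spec$flow_rate * mean(spec$duration_range)
    data.frame(blank_id = sprintf("B%02d", seq_len(spec$n_blanks)),
               analyte = a, mass = rep(spec$blank_fraction * typical_mass,
                                       spec$n_blanks),
               stringsAsFactors = FALSE)
  }))

  structure(list(workers = workers, records = rec, blanks = blanks,
                 truth = list(spec = spec, c_true = c_true)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d workers, %d records (%s)\n",
              nrow(x$workers), nrow(x$records),
              paste(unique(x$records$analyte), collapse = ", ")))
  invisible(x)
}

#' Parameter recovery report for a synthetic study
#'
#' Runs the sample-processing reduction on the study's records, estimates
#' the cohort mean concentration per analyte and the questionnaire-factor
#' means, and compares each estimate to the generating value. An estimate is
#' flagged consistent when it lies within `k` standard errors of the truth
#' (SE estimated from the sample; for skewed concentration data this is the
#' usual normal-theory SE of the mean).
#'
#' @param study A [generate_cohort()] result.
#' @param k Number of standard errors defining consistency (default 3).
#' @return A `data.frame` with columns `quantity`, `truth`, `estimate`,
#'   `se`, `rel_error`, `within_k_se`.
#' @export
recover_parameters <- function(study, k = 3) {
  stopifnot(inherits(study, "synthetic_study"))
  spec <- study$truth$spec
  shift <- shift_concentrations(study$records)
  rows <- lapply(names(spec$concentration_distributions), function(a) {
    truth <- dist_mean(spec$concentration_distributions[[a]])
    x <- shift$concentration[shift$analyte == a]
    data.frame(quantity = paste0("mean_C_", a), truth = truth,
               estimate = mean(x), se = stats::sd(x) / sqrt(length(x)),
               stringsAsFactors = FALSE)
  })
  for (v in c("BW", "ED", "EF", "ET")) {
    truth <- dist_mean(spec$factor_distributions[[v]])
    x <- study$workers[[v]]
    rows <- c(rows, list(data.frame(
      quantity = paste0("mean_", v), truth = truth, estimate = mean(x),
      se = stats::sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  out$rel_error <- (out$estimate - out$truth) / out$truth
  # a degenerate (zero-variance) spec recovers exactly up to float roundoff
  out$within_k_se <- ifelse(
    out$se == 0,
    abs(out$estimate - out$truth) <= 1e-9 * pmax(abs(out$truth), 1e-300),
    abs(out$estimate - out$truth) <= k * out$se
  )
  out
}
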