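#' Assemble a pipeline run configuration
#'
#' One object drives the whole analysis: which analytes to assess (each with
#' its gas constants, toxicological profile and concentration source), the
#' fixed exposure factors, the Monte Carlo settings, and the acceptability
#' thresholds. Concentrations come from one of three sources, in order of
#' precedence: a table of measured sampling `records`, a synthetic
#' [cohort_spec()], or the preset mean concentration carried by each analyte
#' entry.
#'
#' @param analytes Named list; each element a list with `gas`
#'   ([gas_spec()]), `tox` ([tox_profile()]), `mean_concentration`,
#'   `recovery`, such as returned by [analyte_preset()].
#' @param fixed An [exposure_factors()] set supplying non-stochastic factors
#'   and the averaging times.
#' @param specs_fun Function `(mean_c) -> named list of dist_spec` building
#'   each analyte's distribution set; default [replication_specs()] with a
#'   fixed concentration.
#' @param mc An [mc_config()].
#' @param cr_threshold,hq_threshold Acceptability thresholds.
#' @param records Optional [sampling_records()] table of measurements.
#' @param cohort Optional [cohort_spec()] to simulate a study.
#' @param output_dir Optional directory; when set, [run_pipeline()] writes
#'   summary/sensitivity CSVs and a JSON manifest there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(analytes, fixed = cohort_mean_factors(),
                       specs_fun = function(mean_c)
                         replication_specs(mean_c, c_mode = "fixed"),
                       mc = mc_config(),
                       cr_threshold = 1e-6, hq_threshold = 1,
                       records = NULL, cohort = NULL, output_dir = NULL) {
  problems <- character(0)
  if (is.null(names(analytes)) || any(!nzchar(names(analytes)))) {
    problems <- c(problems, "'analytes' must be a named list")
  }
  for (a in names(analytes)) {
    if (!inherits(analytes[[a]]$tox, "tox_profile")) {
      problems <- c(problems,
                    sprintf("analyte '%s' lacks a tox_profile", a))
    }
  }
  if (!inherits(fixed, "exposure_factors")) {
    problems <- c(problems, "'fixed' must be an exposure_factors set")
  }
  if (!inherits(mc, "mc_config")) {
    problems <- c(problems, "'mc' must be an mc_config")
  }
  if (cr_threshold <= 0) problems <- c(problems, "cr_threshold must be > 0")
  if (hq_threshold <= 0) problems <- c(problems, "hq_threshold must be > 0")
  if (!is.null(cohort) && !inherits(cohort, "cohort_spec")) {
    problems <- c(problems, "'cohort' must be a cohort_spec")
  }
  if (length(problems)) {
    stop("invalid run_config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(list(analytes = analytes, fixed = fixed, specs_fun = specs_fun,
                 mc = mc, cr_threshold = cr_threshold,
                 hq_threshold = hq_threshold, records = records,
                 cohort = cohort, output_dir = output_dir),
            class = "run_config")
}

#' The bundled carpet-factory replication configuration
#'
#' Both preset analytes at the cohort-mean exposure factors, factor
#' uncertainty per [replication_specs()], 10,000 iterations.
#'
#' @param seed Integer master seed.
#' @param c_mode Concentration handling: `"fixed"` at the measured mean
#'   (default) or `"lognormal"`.
#' @param n_iterations Monte Carlo iterations (default 10000).
#' @return A [run_config()].
#' @export
replication_config <- function(seed = NULL, c_mode = c("fixed", "lognormal"),
                               n_iterations = 10000L) {
  c_mode <- match.arg(c_mode)
  run_config(
    analytes = list(BD = analyte_preset("BD"), ST = analyte_preset("ST")),
    specs_fun = function(mean_c) replication_specs(mean_c, c_mode = c_mode),
    mc = mc_config(n_iterations = n_iterations, seed = seed)
  )
}

#' Run the full risk-assessment pipeline
#'
#' Per analyte: obtain a mean shift concentration (from measured records, a
#' simulated cohort, or the preset), build the distribution set, propagate
#' through the dose/risk equations by Monte Carlo, and attribute output
#' variance to inputs. When `cfg$output_dir` is set, writes
#' `risk_summary.csv` (one row per analyte and metric, publication-table
#' layout), `sensitivity.csv`, and `manifest.json` recording the seed,
#' iteration count and package version.
#'
#' @param cfg A [run_config()].
#' @return A list of class `risk_bundle`: `mc` (named list of `mc_result`),
#'   `summaries` (combined CR/HQ summary table), `sensitivity` (named list
#'   of per-metric `sensitivity_result` lists), `shift_concentrations`
#'   (when records were processed), `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  shift <- NULL
  if (!is.null(cfg$records)) {
    shift <- shift_concentrations(cfg$records)
  } else if (!is.null(cfg$cohort)) {
    cohort <- cfg$cohort
    if (is.null(cohort$seed)) cohort$seed <- cfg$mc$seed
    study <- generate_cohort(cohort)
    shift <- shift_concentrations(study$records)
  }

  mc_results <- list()
  sens <- list()
  summaries <- NULL
  for (a in names(cfg$analytes)) {
    entry <- cfg$analytes[[a]]
    mean_c <- if (!is.null(shift) && a %in% shift$analyte) {
      mean(shift$concentration[shift$analyte == a])
    } else {
      entry$mean_concentration
    }
    specs <- cfg$specs_fun(mean_c)
    res <- mc_propagate(specs, cfg$fixed, entry$tox, cfg$mc,
                        cr_threshold = cfg$cr_threshold,
                        hq_threshold = cfg$hq_threshold)
    mc_results[[a]] <- res
    inputs <- res$draws[, c("C", "IR", "ED", "EF", "BW", "ET")]
    # a fully deterministic run has no variance to attribute
    any_stochastic <- any(vapply(inputs, function(x)
      length(unique(x)) >= 2L, logical(1L)))
    sens[[a]] <- if (any_stochastic) {
      list(
        CR = contribution_to_variance(inputs, res$draws$CR,
                                      metric = "CR", analyte = a),
        HQ = contribution_to_variance(inputs, res$draws$HQ,
                                      metric = "HQ", analyte = a)
      )
    } else {
      NULL
    }
    summaries <- rbind(summaries, res$cr_summary, res$hq_summary)
  }
  rownames(summaries) <- NULL

  manifest <- list(
    package = "inhalrisk",
    version = as.character(utils::packageVersion("inhalrisk")),
    seed = cfg$mc$seed, n_iterations = cfg$mc$n_iterations,
    analytes = names(cfg$analytes),
    cr_threshold = cfg$cr_threshold, hq_threshold = cfg$hq_threshold,
    concentration_source = if (!is.null(cfg$records)) "records"
      else if (!is.null(cfg$cohort)) "synthetic_cohort" else "preset"
  )

  bundle <- structure(list(mc = mc_results, summaries = summaries,
                           sensitivity = sens,
                           shift_concentrations = shift,
                           manifest = manifest),
                      class = "risk_bundle")

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summaries,
                     file.path(cfg$output_dir, "risk_summary.csv"),
                     row.names = FALSE)
    if (length(sens)) {
      sens_tab <- do.call(rbind, lapply(names(sens), function(a) {
        do.call(rbind, lapply(names(sens[[a]]), function(m) {
          cbind(analyte = a, metric = m, sensitivity_table(sens[[a]][[m]]))
        }))
      }))
      utils::write.csv(sens_tab, file.path(cfg$output_dir, "sensitivity.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  bundle
}

#' Publication-style summary table
#'
#' Formats the bundle's CR/HQ summaries as Min / Max / Mean +/- SD / P95
#' columns in 3-significant-figure scientific notation, with a flag marking
#' rows whose mean exceeds the acceptability threshold. Display rounding
#' only: the underlying CSVs and summaries keep full precision.
#'
#' @param bundle A [run_pipeline()] result.
#' @return A `data.frame` with one row per analyte and metric.
#' @export
render_tables <- function(bundle) {
  stopifnot(inherits(bundle, "risk_bundle"))
  s <- bundle$summaries
  if (is.null(s) || !nrow(s)) {
    return(data.frame(analyte = character(0), metric = character(0),
                      Min = character(0), Max = character(0),
                      `Mean ± SD` = character(0), P95 = character(0),
                      exceeds = logical(0), check.names = FALSE))
  }
  fmt <- function(x) formatC(x, format = "e", digits = 2)
  data.frame(
    analyte = s$analyte, metric = s$metric,
    Min = fmt(s$min), Max = fmt(s$max),
    `Mean ± SD` = paste0(fmt(s$mean), " ± ", fmt(s$sd)),
    P95 = fmt(s$p95),
    exceeds = s$exceedance_fraction > 0.5,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' @export
print.risk_bundle <- function(x, ...) {
  cat("<risk_bundle>\n")
  print(render_tables(x))
  invisible(x)
}

#' Write a run configuration skeleton to YAML
#'
#' Serialises the numeric and label content of a [run_config()] (analyte
#' constants, fixed factors, Monte Carlo settings, thresholds) so a run can
#' be reproduced or edited by hand; [read_run_config()] restores it. The
#' distribution-building function itself is not serialised — the YAML
#' carries its `c_mode` choice instead.
#'
#' @param cfg A [run_config()].
#' @param path Output YAML path.
#' @param c_mode Concentration mode recorded in the file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path, c_mode = "fixed") {
  stopifnot(inherits(cfg, "run_config"))
  x <- list(
    analytes = lapply(cfg$analytes, function(e) list(
      molar_mass = e$gas$molar_mass, molar_volume = e$gas$molar_volume,
      SF = e$tox$SF, RfC = e$tox$RfC, cancer_class = e$tox$cancer_class,
      mean_concentration = e$mean_concentration, recovery = e$recovery
    )),
    fixed = unclass(cfg$fixed),
    mc = list(n_iterations = cfg$mc$n_iterations, seed = cfg$mc$seed,
              percentiles = cfg$mc$percentiles),
    thresholds = list(cr = cfg$cr_threshold, hq = cfg$hq_threshold),
    c_mode = c_mode
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()] (or hand-edited in
#'   the same layout).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  analytes <- lapply(names(x$analytes), function(a) {
    e <- x$analytes[[a]]
    list(gas = gas_spec(a, e$molar_mass, e$molar_volume),
         tox = tox_profile(a, e$SF, e$RfC,
                           if (is.null(e$cancer_class)) NA_character_
                           else e$cancer_class),
         mean_concentration = e$mean_concentration, recovery = e$recovery)
  })
  names(analytes) <- names(x$analytes)
  f <- x$fixed
  c_mode <- if (is.null(x$c_mode)) "fixed" else x$c_mode
  run_config(
    analytes = analytes,
    fixed = exposure_factors(C = f$C, IR = f$IR, ED = f$ED, EF = f$EF,
                             BW = f$BW, ET = f$ET, AT_days = f$AT_days,
                             AT_hours = f$AT_hours),
    specs_fun = function(mean_c) replication_specs(mean_c, c_mode = c_mode),
    mc = mc_config(n_iterations = x$mc$n_iterations, seed = x$mc$seed,
                   percentiles = unlist(x$mc$percentiles)),
    cr_threshold = x$thresholds$cr, hq_threshold = x$thresholds$hq
  )
}
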