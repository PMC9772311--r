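#' Build a table of personal sorbent-tube sampling records
#'
#' One row per sample: analyte masses recovered from the front and rear
#' (backup) sorbent sections, the field-blank mass, pump metadata, and the
#' desorption efficiency (recovery) used to correct the measured mass. All
#' arguments are vectorised and recycled to a common length.
#'
#' @param worker_id Worker identifier(s).
#' @param analyte Analyte name(s).
#' @param mass_front Front-section mass in micrograms; >= 0.
#' @param mass_rear Rear (backup) section mass in micrograms; >= 0.
#' @param blank_mass Field-blank mass in micrograms; >= 0.
#' @param flow_rate Pump flow in L/min; > 0.
#' @param duration Sampling duration in minutes; > 0.
#' @param recovery Desorption efficiency as a fraction in (0, 1].
#' @return A `data.frame` of class `sampling_records`.
#' @export
sampling_records <- function(worker_id, analyte, mass_front, mass_rear,
                             blank_mass, flow_rate, duration, recovery) {
  r <- data.frame(worker_id = as.character(worker_id),
                  analyte = as.character(analyte),
                  mass_front = mass_front, mass_rear = mass_rear,
                  blank_mass = blank_mass, flow_rate = flow_rate,
                  duration = duration, recovery = recovery,
                  stringsAsFactors = FALSE)
  validate_sampling_records(r)
  class(r) <- c("sampling_records", "data.frame")
  r
}

validate_sampling_records <- function(r) {
  if (any(r$mass_front < 0) || any(r$mass_rear < 0) || any(r$blank_mass < 0)) {
    stop("sorbent and blank masses must be non-negative")
  }
  if (any(r$flow_rate <= 0)) stop("'flow_rate' must be positive (L/min)")
  if (any(r$duration <= 0)) stop("'duration' must be positive (min)")
  if (any(r$recovery <= 0) || any(r$recovery > 1)) {
    stop("'recovery' must lie in (0, 1]")
  }
  invisible(r)
}

#' Breathing-zone concentration from a sampling record
#'
#' Blank-corrected, recovery-corrected mass divided by the sampled air
#' volume:
#' `max(0, mass_front + mass_rear - blank_mass) / (recovery * flow * duration)`.
#' The numerator is floored at zero because a blank exceeding the sample mass
#' is measurement noise, not a negative concentration. With masses in
#' micrograms and volume in litres the result is ug/L, numerically identical
#' to mg/m3.
#'
#' @param r A [sampling_records()] table (or any data.frame with the same
#'   columns).
#' @return Numeric vector of concentrations in mg/m3, one per record.
#' @export
concentration_from_record <- function(r) {
  validate_sampling_records(r)
  net <- pmax(0, r$mass_front + r$mass_rear - r$blank_mass)
  net / (r$recovery * r$flow_rate * r$duration)
}

#' Flag sorbent-tube breakthrough
#'
#' A sample is flagged when the rear (backup) section holds more than
#' `threshold` times the front-section mass, indicating front-section
#' saturation and a likely underestimate. The conventional criterion is 10%.
#' Empty tubes (front mass zero) are never flagged.
#'
#' @param r A [sampling_records()] table.
#' @param threshold Rear/front mass fraction in (0, 1); default 0.10.
#' @return Logical vector, one flag per record.
#' @export
breakthrough_flag <- function(r, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must lie in (0, 1)")
  r$mass_front > 0 & r$mass_rear > threshold * r$mass_front
}

#' Average within-shift samples to one concentration per worker
#'
#' Workers typically wear several consecutive tubes over a shift; this
#' reduces the records of one worker and analyte to a single shift
#' concentration. The default is the duration-weighted mean, which equals
#' the concentration of the pooled air volume when flow rates are equal;
#' `weighted = FALSE` gives the plain arithmetic mean of per-record
#' concentrations. The breakthrough flag is the OR across records.
#'
#' @param r A [sampling_records()] table holding records of exactly one
#'   worker and one analyte.
#' @param weighted Duration-weight the mean (default `TRUE`)?
#' @param breakthrough_threshold Passed to [breakthrough_flag()].
#' @return One-row `data.frame` with `worker_id`, `analyte`, `concentration`
#'   (mg/m3), `n_samples` and `breakthrough_flagged`.
#' @export
shift_average <- function(r, weighted = TRUE, breakthrough_threshold = 0.10) {
  if (nrow(r) < 1L) stop("at least one record is required")
  if (length(unique(r$worker_id)) != 1L || length(unique(r$analyte)) != 1L) {
    stop("all records must share one worker_id and one analyte")
  }
  conc <- concentration_from_record(r)
  w <- if (weighted) r$duration else rep(1, nrow(r))
  data.frame(worker_id = r$worker_id[1L], analyte = r$analyte[1L],
             concentration = sum(w * conc) / sum(w),
             n_samples = nrow(r),
             breakthrough_flagged = any(breakthrough_flag(
               r, breakthrough_threshold)),
             stringsAsFactors = FALSE)
}

#' Shift concentrations for every worker and analyte in a record table
#'
#' Applies [shift_average()] within each worker-analyte group.
#'
#' @inheritParams shift_average
#' @return A `data.frame` with one row per worker and analyte, ordered by
#'   analyte then worker.
#' @export
shift_concentrations <- function(r, weighted = TRUE,
                                 breakthrough_threshold = 0.10) {
  validate_sampling_records(r)
  groups <- split(r, list(r$analyte, r$worker_id), drop = TRUE)
  out <- do.call(rbind, lapply(groups, shift_average, weighted = weighted,
                               breakthrough_threshold = breakthrough_threshold))
  out <- out[order(out$analyte, out$worker_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read sampling records from CSV
#'
#' Expects the documented header `worker_id, analyte, mass_front_ug,
#' mass_rear_ug, blank_ug, flow_lpm, duration_min, recovery`.
#'
#' @param path CSV file path.
#' @return A [sampling_records()] table.
#' @export
read_sampling_records <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("worker_id", "analyte", "mass_front_ug", "mass_rear_ug",
            "blank_ug", "flow_lpm", "duration_min", "recovery")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("sampling-record CSV is missing columns: ",
         paste(missing, collapse = ", "))
  }
  sampling_records(x$worker_id, x$analyte, x$mass_front_ug, x$mass_rear_ug,
                   x$blank_ug, x$flow_lpm, x$duration_min, x$recovery)
}

#' Write sampling records to CSV with the documented header
#'
#' @param r A [sampling_records()] table.
#' @param path Output CSV path.
#' @export
write_sampling_records <- function(r, path) {
  out <- data.frame(worker_id = r$worker_id, analyte = r$analyte,
                    mass_front_ug = r$mass_front, mass_rear_ug = r$mass_rear,
                    blank_ug = r$blank_mass, flow_lpm = r$flow_rate,
                    duration_min = r$duration, recovery = r$recovery)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
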