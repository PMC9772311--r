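#' Define a gas species for unit conversion
#'
#' Bundles the molar mass and the molar-volume convention used to convert
#' between ppm (volume mixing ratio) and mg/m3 (mass concentration). The
#' default molar volume of 24.45 L/mol corresponds to the conventional
#' industrial-hygiene reference state of 25 degrees C and 1 atm; regulatory
#' tables occasionally use other conventions (e.g. 24.0 or 24.2 L/mol), so
#' the value is a field, never hard-coded.
#'
#' @param name Analyte name, e.g. `"BD"` (1,3-butadiene) or `"ST"` (styrene).
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param molar_volume Molar volume in L/mol at the chosen reference
#'   temperature and pressure; must be positive. Default 24.45.
#' @return An object of class `gas_spec`.
#' @examples
#' bd <- gas_spec("BD", molar_mass = 54.09)
#' ppm_to_mgm3(1, bd) # about 2.21 mg/m3
#' @export
gas_spec <- function(name, molar_mass, molar_volume = 24.45) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0) {
    stop("'molar_mass' must be a single positive number (g/mol)")
  }
  if (!is.numeric(molar_volume) || length(molar_volume) != 1L ||
      molar_volume <= 0) {
    stop("'molar_volume' must be a single positive number (L/mol)")
  }
  structure(
    list(name = name, molar_mass = molar_mass, molar_volume = molar_volume),
    class = "gas_spec"
  )
}

#' @export
print.gas_spec <- function(x, ...) {
  cat(sprintf("<gas_spec> %s: M = %g g/mol, Vm = %g L/mol\n",
              x$name, x$molar_mass, x$molar_volume))
  invisible(x)
}

#' Convert a gas-phase concentration from ppm to mg/m3
#'
#' Uses `c_mgm3 = c_ppm * molar_mass / molar_volume`. Vectorised over `c_ppm`.
#'
#' @param c_ppm Concentration(s) in ppm (volume mixing ratio); must be >= 0.
#' @param gas A [gas_spec()].
#' @return Concentration(s) in mg/m3.
#' @export
ppm_to_mgm3 <- function(c_ppm, gas) {
  stopifnot(inherits(gas, "gas_spec"))
  if (any(!is.finite(c_ppm)) || any(c_ppm < 0)) {
    stop("ppm concentration must be finite and non-negative")
  }
  c_ppm * gas$molar_mass / gas$molar_volume
}

#' Convert a gas-phase concentration from mg/m3 to ppm
#'
#' Exact inverse of [ppm_to_mgm3()]; the round trip is the identity to
#' machine precision. Vectorised over `c_mgm3`.
#'
#' @param c_mgm3 Concentration(s) in mg/m3; must be >= 0.
#' @param gas A [gas_spec()].
#' @return Concentration(s) in ppm.
#' @export
mgm3_to_ppm <- function(c_mgm3, gas) {
  stopifnot(inherits(gas, "gas_spec"))
  if (any(!is.finite(c_mgm3)) || any(c_mgm3 < 0)) {
    stop("mg/m3 concentration must be finite and non-negative")
  }
  c_mgm3 * gas$molar_volume / gas$molar_mass
}

#' Brief & Scala reduction factor for extended daily shifts
#'
#' Occupational exposure limits assume an 8-hour workday followed by 16 hours
#' of recovery. For longer shifts the Brief & Scala model reduces the limit
#' by `(8/h) * (24 - h)/16`, accounting both for the increased dose and the
#' shortened recovery period. The factor equals 1 at h = 8 and decreases
#' strictly as the shift lengthens.
#'
#' @param hours_per_day Shift length in hours; must satisfy 0 < h < 24.
#' @return Dimensionless reduction factor in (0, Inf).
#' @examples
#' brief_scala_daily(8)     # 1: standard shift, no adjustment
#' brief_scala_daily(12)    # 0.5
#' @export
brief_scala_daily <- function(hours_per_day) {
  if (any(!is.finite(hours_per_day)) ||
      any(hours_per_day <= 0) || any(hours_per_day >= 24)) {
    stop("'hours_per_day' must lie strictly between 0 and 24")
  }
  (8 / hours_per_day) * (24 - hours_per_day) / 16
}

#' Brief & Scala reduction factor for extended work weeks
#'
#' Weekly form of the Brief & Scala adjustment: `(40/h) * (168 - h)/128`,
#' where 40 h is the standard work week and 128 h the standard weekly
#' recovery time.
#'
#' @param hours_per_week Weekly working hours; must satisfy 0 < h < 168.
#' @return Dimensionless reduction factor.
#' @export
brief_scala_weekly <- function(hours_per_week) {
  if (any(!is.finite(hours_per_week)) ||
      any(hours_per_week <= 0) || any(hours_per_week >= 168)) {
    stop("'hours_per_week' must lie strictly between 0 and 168")
  }
  (40 / hours_per_week) * (168 - hours_per_week) / 128
}

#' Define an occupational exposure limit
#'
#' @param agency Issuing body: one of `"OSHA"`, `"ACGIH"`, `"NIOSH"`,
#'   `"EOHCI"`.
#' @param limit_type One of `"TWA"`, `"STEL"`, `"IDLH"`.
#' @param value_ppm Limit value in ppm; must be >= 0.
#' @param analyte Optional analyte name the limit applies to.
#' @param schedule_hours_per_day Workday length the limit assumes (default 8).
#' @param schedule_days_per_week Work week the limit assumes (default 5).
#' @return An object of class `oel_spec`.
#' @export
oel_spec <- function(agency, limit_type, value_ppm, analyte = NA_character_,
                     schedule_hours_per_day = 8, schedule_days_per_week = 5) {
  agency <- match.arg(agency, c("OSHA", "ACGIH", "NIOSH", "EOHCI"))
  limit_type <- match.arg(limit_type, c("TWA", "STEL", "IDLH"))
  if (!is.numeric(value_ppm) || length(value_ppm) != 1L || value_ppm < 0) {
    stop("'value_ppm' must be a single non-negative number")
  }
  if (schedule_hours_per_day <= 0 || schedule_hours_per_day > 24) {
    stop("'schedule_hours_per_day' must lie in (0, 24]")
  }
  structure(
    list(agency = agency, limit_type = limit_type, value_ppm = value_ppm,
         analyte = analyte,
         schedule_hours_per_day = schedule_hours_per_day,
         schedule_days_per_week = schedule_days_per_week),
    class = "oel_spec"
  )
}

#' @export
print.oel_spec <- function(x, ...) {
  cat(sprintf("<oel_spec> %s %s%s: %g ppm (schedule %g h/d, %g d/wk)\n",
              x$agency, x$limit_type,
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$value_ppm, x$schedule_hours_per_day,
              x$schedule_days_per_week))
  invisible(x)
}

#' Apply a schedule-adjustment factor to an exposure limit
#'
#' Multiplies the limit value by a reduction factor (typically from
#' [brief_scala_daily()] or [brief_scala_weekly()]), preserving agency and
#' limit type.
#'
#' @param oel An [oel_spec()].
#' @param factor Positive dimensionless multiplier.
#' @return A new `oel_spec` with the adjusted value.
#' @export
adjust_oel <- function(oel, factor) {
  stopifnot(inherits(oel, "oel_spec"))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("'factor' must be a single positive number")
  }
  oel$value_ppm <- oel$value_ppm * factor
  oel
}

#' Load the bundled occupational-exposure-limit registry
#'
#' Reads a plain-text YAML table of published limits (agency, analyte, limit
#' type, value in ppm). The bundled registry carries the limits relevant to
#' 1,3-butadiene and styrene; supply `path` to use your own.
#'
#' @param path Path to a YAML registry; defaults to the copy shipped with the
#'   package.
#' @return A `data.frame` with columns `agency`, `analyte`, `limit_type`,
#'   `value_ppm`.
#' @export
oel_registry <- function(path = system.file("extdata", "oel_limits.yaml",
                                            package = "inhalrisk")) {
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(raw$limits, function(x) {
    data.frame(agency = x$agency, analyte = x$analyte,
               limit_type = x$limit_type, value_ppm = as.numeric(x$value_ppm),
               stringsAsFactors = FALSE)
  }))
}
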