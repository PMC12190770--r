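#' Convert measured optical power to irradiance
#'
#' Irradiance is power divided by the illuminated (or sensor) area, with
#' explicit unit bookkeeping: powers in W, mW or uW; areas in m2, mm2, cm2
#' or um2. All internal arithmetic is SI (W, m2).
#'
#' @param power Measured power.
#' @param area Active detector / illuminated area (> 0).
#' @param power_unit One of `"W"`, `"mW"`, `"uW"`.
#' @param area_unit One of `"m2"`, `"cm2"`, `"mm2"`, `"um2"`.
#' @return Irradiance in W/m2.
#' @export
irradiance_from_power <- function(power, area, power_unit = c("W", "mW", "uW"),
                                  area_unit = c("m2", "cm2", "mm2", "um2")) {
  power_unit <- match.arg(power_unit)
  area_unit <- match.arg(area_unit)
  if (any(area <= 0)) abort("`area` must be > 0.")
  if (any(power < 0)) abort("`power` must be >= 0.")
  p_si <- power * switch(power_unit, W = 1, mW = 1e-3, uW = 1e-6)
  a_si <- area * switch(area_unit, m2 = 1, cm2 = 1e-4, mm2 = 1e-6, um2 = 1e-12)
  p_si / a_si
}

#' Light dosage (fluence) from irradiance and duration
#'
#' The time integral of irradiance: `J/m2 = W/m2 x s`. Durations may be
#' given in seconds or minutes.
#'
#' @param irradiance_W_m2 Irradiance in W/m2 (>= 0).
#' @param duration_s Duration in seconds (>= 0).
#' @param duration_min Alternative duration in minutes.
#' @return Dosage in J/m2.
#' @export
dosage <- function(irradiance_W_m2, duration_s = NULL, duration_min = NULL) {
  if (is.null(duration_s) && is.null(duration_min)) {
    abort("Supply `duration_s` or `duration_min`.")
  }
  duration_s <- duration_s %||% (duration_min * 60)
  if (any(irradiance_W_m2 < 0) || any(duration_s < 0)) {
    abort("Irradiance and duration must be non-negative.")
  }
  irradiance_W_m2 * duration_s
}

#' Effective irradiance of a scanned ROI
#'
#' For laser-scanned spatial activation, the time-averaged irradiance over
#' the scan region is the delivered power divided by the scanned ROI area,
#' scaled by the duty (dwell) fraction of the exposure period during which
#' the scan runs.
#'
#' @param power Laser power measured at the sample plane.
#' @param roi_area Scanned ROI area.
#' @param power_unit,area_unit Units as in [irradiance_from_power()].
#' @param dwell_fraction Fraction of the exposure period spent scanning
#'   (default 1: continuous re-scan).
#' @return Effective irradiance in W/m2.
#' @export
roi_scan_irradiance <- function(power, roi_area, power_unit = c("W", "mW", "uW"),
                                area_unit = c("m2", "cm2", "mm2", "um2"),
                                dwell_fraction = 1) {
  if (dwell_fraction < 0 || dwell_fraction > 1) {
    abort("`dwell_fraction` must be in [0, 1].")
  }
  irradiance_from_power(power, roi_area, power_unit, area_unit) * dwell_fraction
}

#' Exposure table: irradiance, duration, dosage
#'
#' Tabulates the light dosage delivered by each irradiance step of an
#' exposure ladder, as reported alongside irradiance-dependence experiments.
#'
#' @param irradiance_W_m2 Vector of irradiances (W/m2).
#' @param duration_min Exposure duration (min), scalar or vector.
#' @return A tibble: `irradiance_W_m2`, `duration_min`, `dosage_J_m2`.
#' @export
exposure_table <- function(irradiance_W_m2, duration_min) {
  tibble::tibble(
    irradiance_W_m2 = irradiance_W_m2,
    duration_min = rep_len(duration_min, length(irradiance_W_m2)),
    dosage_J_m2 = dosage(irradiance_W_m2,
                         duration_s = rep_len(duration_min, length(irradiance_W_m2)) * 60)
  )
}
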