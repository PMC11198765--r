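#' Angular resolution of the pan axis
#'
#' Degrees of pan rotation per microstep at the output: 360 divided by
#' (motor steps x microstepping denominator x gear ratio). For the reference
#' device (200 steps, 1/4 microstepping, 3:1 belt) this is 0.15 degrees; at
#' 1/16 microstepping it reaches the 0.0375-degree maximum.
#'
#' @param config A [scanner_config()].
#' @return Degrees per pan microstep.
#' @export
#' @examples
#' pan_resolution_deg(default_scanner_config())            # 0.15
#' pan_resolution_deg(default_scanner_config(pan_microstep = 16))  # 0.0375
pan_resolution_deg <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  360 / microsteps_per_output_rev(config$pan)
}

#' Angular resolution of the tilt axis
#'
#' Degrees of tilt per microstep: (360 / motor steps) x (1/m) / gear ratio.
#' Direct drive at 1/4 microstepping gives 0.45 degrees per revolution of the
#' head; 1/8 gives the 0.225-degree maximum.
#'
#' @inheritParams pan_resolution_deg
#' @return Degrees per tilt microstep.
#' @export
tilt_resolution_deg <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  360 / microsteps_per_output_rev(config$tilt)
}

#' Distance measurements per head revolution
#'
#' One pulse is taken at every pan microstep, so a full revolution yields
#' motor steps x microstepping x gear ratio measurements (2400 for the
#' reference device).
#'
#' @inheritParams pan_resolution_deg
#' @return Integer pulse count per revolution.
#' @export
points_per_revolution <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  microsteps_per_output_rev(config$pan)
}

#' Duration of one head revolution
#'
#' Points per revolution times the step interval. With the 3.3 ms step used
#' at the 300 Hz sensor cap and 2400 points per revolution this is 7.92 s.
#'
#' @inheritParams pan_resolution_deg
#' @return Seconds per revolution.
#' @export
revolution_period_s <- function(config) {
  points_per_revolution(config) * config$step_duration_s
}

#' Number of head revolutions in a scan
#'
#' The tilt sweep divided by the tilt resolution, rounded up so the sweep is
#' covered in full (the final revolution may overshoot the end tilt by less
#' than one tilt step); exact integer quotients are kept as-is.
#'
#' @inheritParams pan_resolution_deg
#' @return Integer revolution count.
#' @export
#' @examples
#' num_revolutions(default_scanner_config())  # 289 for -40 to +90 at 0.45 deg
num_revolutions <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  span <- config$tilt_end_deg - config$tilt_start_deg
  if (span <= 0) stop("empty tilt range", call. = FALSE)
  res <- tilt_resolution_deg(config)
  n <- span / res
  # tolerate floating error at exact integer quotients before rounding up
  if (abs(n - round(n)) < 1e-9) as.integer(round(n)) else as.integer(ceiling(n))
}

#' Total scan duration
#'
#' @inheritParams pan_resolution_deg
#' @return Seconds for the complete scan (revolutions x revolution period).
#' @export
scan_duration_s <- function(config) {
  num_revolutions(config) * revolution_period_s(config)
}

#' Total scheduled pulses in a scan
#'
#' @inheritParams pan_resolution_deg
#' @return Integer count (revolutions x points per revolution); 693,600 for
#'   the reference configuration, 1,387,200 at 1/8 pan microstepping.
#' @export
total_points <- function(config) {
  num_revolutions(config) * points_per_revolution(config)
}

#' Minimum step interval allowed by the rangefinder
#'
#' The step interval that saturates the sensor's maximum sampling rate
#' (1/300 s, i.e. 3.3 ms at one-decimal display).
#'
#' @param rangefinder A [rangefinder_spec()].
#' @return Seconds.
#' @export
min_step_duration_s <- function(rangefinder = rangefinder_spec()) {
  stopifnot(inherits(rangefinder, "rangefinder_spec"))
  1 / rangefinder$max_sample_rate_hz
}

#' Laser footprint diameter at range
#'
#' The illuminated spot grows linearly with range as divergence x distance;
#' the reference sensor's 8 mrad divergence gives an 8 cm footprint at 10 m.
#' Reported for diagnostics only: the simulator is a single-ray model and
#' does not mix returns across the footprint.
#'
#' @param distance_m Range(s) in meters.
#' @param divergence_rad Full beam divergence in radians.
#' @return Footprint diameter(s) in meters.
#' @export
footprint_m <- function(distance_m, divergence_rad = 0.008) {
  if (any(distance_m < 0)) stop("distance_m must be >= 0", call. = FALSE)
  divergence_rad * distance_m
}

#' Build the full scan schedule
#'
#' Expands a configuration into the time-ordered sequence of commanded laser
#' orientations: the head spins continuously in the pan direction, one pulse
#' per microstep, and the tilt advances by one tilt step at each bearing
#' wrap, so every revolution holds a constant tilt. Bearings are computed in
#' closed form from the step index (not by accumulation), which is what keeps
#' dead-reckoning orientation drift-free.
#'
#' @inheritParams pan_resolution_deg
#' @param max_entries Safety cap on the schedule size.
#' @return A `scan_schedule`: a [data.table::data.table] with columns
#'   `time_ms`, `bearing_deg`, `tilt_deg`, `revolution` (0-based), carrying
#'   the configuration as attribute `config`.
#' @export
#' @examples
#' sch <- build_schedule(default_scanner_config(tilt_end_deg = -39.1))
#' head(sch, 3)
build_schedule <- function(config, max_entries = 1e8) {
  stopifnot(inherits(config, "scanner_config"))
  n_rev <- num_revolutions(config)
  ppr <- points_per_revolution(config)
  n <- as.numeric(n_rev) * ppr
  if (n > max_entries)
    stop(sprintf("schedule of %.0f entries exceeds the safety cap (%.0f)",
                 n, max_entries), call. = FALSE)
  idx <- seq_len(n) - 1
  pan_sign <- if (config$pan$positive_direction == "counterclockwise") -1 else 1
  rev_idx <- idx %/% ppr
  # tilt always advances start -> end; pan spins in the axis' positive sense
  sch <- data.table::data.table(
    time_ms = idx * (config$step_duration_s * 1000),
    bearing_deg = (config$start_bearing_deg +
                     pan_sign * (idx %% ppr) * pan_resolution_deg(config)) %% 360,
    tilt_deg = config$tilt_start_deg + rev_idx * tilt_resolution_deg(config),
    revolution = as.integer(rev_idx))
  data.table::setattr(sch, "config", config)
  data.table::setattr(sch, "class", c("scan_schedule", class(sch)))
  sch[]
}

#' One-line summary of the scan plan
#'
#' @inheritParams pan_resolution_deg
#' @return A list with the planned resolutions, revolution period and count,
#'   scan duration and total points (also printed by the `plan` CLI command).
#' @export
scan_plan <- function(config) {
  list(pan_resolution_deg = pan_resolution_deg(config),
       tilt_resolution_deg = tilt_resolution_deg(config),
       points_per_revolution = points_per_revolution(config),
       revolution_period_s = revolution_period_s(config),
       num_revolutions = num_revolutions(config),
       scan_duration_s = scan_duration_s(config),
       scan_duration_min = scan_duration_s(config) / 60,
       total_points = total_points(config))
}
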