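#' Stepper motor specification
#'
#' Describes the motor itself: the number of full steps per motor shaft
#' revolution (200 for the common NEMA 17 class used in economical scanner
#' builds).
#'
#' @param steps_per_rev Integer number of full steps per motor revolution.
#' @return An object of class `motor_spec`.
#' @export
#' @examples
#' motor_spec(200)
motor_spec <- function(steps_per_rev = 200L) {
  steps_per_rev <- as.integer(steps_per_rev)
  if (length(steps_per_rev) != 1L || is.na(steps_per_rev) || steps_per_rev <= 0L)
    stop("steps_per_rev must be a single positive integer", call. = FALSE)
  structure(list(steps_per_rev = steps_per_rev), class = "motor_spec")
}

#' Gimbal axis configuration
#'
#' One axis of the pan-tilt gimbal: its motor, the microstepping denominator
#' set on the driver (the driver subdivides each full step into 1/m
#' microsteps), the output gear ratio, and the sign convention for positive
#' motion.
#'
#' @param motor A [motor_spec()].
#' @param microstep_denominator Microstepping denominator m; one of 1, 2, 4,
#'   8, 16 (A4988-class drivers).
#' @param gear_ratio Output-to-motor rotation ratio (pan axis: 3 for a 3:1
#'   belt drive; tilt axis: 1 for direct drive). Must make the number of
#'   microsteps per output revolution an exact integer.
#' @param positive_direction `"clockwise"`/`"counterclockwise"` for a pan
#'   axis, `"up"`/`"down"` for a tilt axis.
#' @return An object of class `axis_config`.
#' @export
#' @examples
#' axis_config(motor_spec(200), 4, gear_ratio = 3)   # the pan axis
#' axis_config(motor_spec(200), 4, gear_ratio = 1, positive_direction = "up")
axis_config <- function(motor = motor_spec(),
                        microstep_denominator = 4L,
                        gear_ratio = 1,
                        positive_direction = c("clockwise", "counterclockwise",
                                               "up", "down")) {
  stopifnot(inherits(motor, "motor_spec"))
  microstep_denominator <- as.integer(microstep_denominator)
  if (!microstep_denominator %in% c(1L, 2L, 4L, 8L, 16L))
    stop("microstep_denominator must be one of 1, 2, 4, 8, 16", call. = FALSE)
  if (!is.numeric(gear_ratio) || length(gear_ratio) != 1L || gear_ratio < 1)
    stop("gear_ratio must be a single number >= 1", call. = FALSE)
  positive_direction <- match.arg(positive_direction)
  ax <- structure(list(motor = motor,
                       microstep_denominator = microstep_denominator,
                       gear_ratio = gear_ratio,
                       positive_direction = positive_direction),
                  class = "axis_config")
  microsteps_per_output_rev(ax)  # validates integrality
  ax
}

# microsteps needed for one full revolution of the axis *output*
microsteps_per_output_rev <- function(axis) {
  n <- axis$motor$steps_per_rev * axis$microstep_denominator * axis$gear_ratio
  if (abs(n - round(n)) > 1e-9)
    stop("configuration error: microsteps per output revolution (",
         format(n), ") is not an integer", call. = FALSE)
  as.integer(round(n))
}

#' Laser rangefinder specification
#'
#' Performance figures of the ranging sensor: maximum range, distance
#' quantization, 1-sigma ranging accuracy in the near and far regimes (the
#' LIDAR-Lite v3HP class datasheet states +/-5 cm below 2 m and +/-2.5 cm
#' beyond), the boundary between the regimes, and the maximum outdoor
#' sampling rate.
#'
#' @param max_range_m Maximum range in meters.
#' @param distance_resolution_m Distance quantization step in meters.
#' @param accuracy_near_m 1-sigma accuracy below `near_far_boundary_m`, meters.
#' @param accuracy_far_m 1-sigma accuracy beyond `near_far_boundary_m`, meters.
#' @param near_far_boundary_m Boundary between the accuracy regimes, meters.
#' @param max_sample_rate_hz Maximum sustainable sampling rate, Hz.
#' @return An object of class `rangefinder_spec`.
#' @export
rangefinder_spec <- function(max_range_m = 40,
                             distance_resolution_m = 0.01,
                             accuracy_near_m = 0.05,
                             accuracy_far_m = 0.025,
                             near_far_boundary_m = 2,
                             max_sample_rate_hz = 300) {
  v <- c(max_range_m, distance_resolution_m, accuracy_near_m, accuracy_far_m,
         near_far_boundary_m, max_sample_rate_hz)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all rangefinder_spec fields must be strictly positive", call. = FALSE)
  if (accuracy_near_m < accuracy_far_m)
    stop("accuracy_near_m must be >= accuracy_far_m", call. = FALSE)
  structure(list(max_range_m = max_range_m,
                 distance_resolution_m = distance_resolution_m,
                 accuracy_near_m = accuracy_near_m,
                 accuracy_far_m = accuracy_far_m,
                 near_far_boundary_m = near_far_boundary_m,
                 max_sample_rate_hz = max_sample_rate_hz),
            class = "rangefinder_spec")
}

#' Laser mount offset and software alignment trims
#'
#' The laser sits off the pan axis (a deliberate weight-balancing choice in
#' the hardware), which shifts every measured point and must be corrected in
#' software. Offsets are expressed in the rotating-head frame at bearing 0:
#' `forward_m` along the beam azimuth (north at bearing 0), `lateral_m`
#' perpendicular to it (east at bearing 0), `vertical_m` up from the scanner
#' reference origin. `bearing_trim_deg`/`tilt_trim_deg` are the software
#' alignment corrections applied to the assumed orientation when the laser
#' cannot be perfectly aligned mechanically.
#'
#' @param lateral_m,forward_m,vertical_m Signed offsets in meters.
#' @param bearing_trim_deg,tilt_trim_deg Signed trim angles in degrees.
#' @return An object of class `offset_spec`.
#' @export
#' @examples
#' offset_spec()                 # ideal on-axis laser: identity correction
#' offset_spec(lateral_m = 0.05) # laser 5 cm right of the pan axis
offset_spec <- function(lateral_m = 0, forward_m = 0, vertical_m = 0,
                        bearing_trim_deg = 0, tilt_trim_deg = 0) {
  v <- c(lateral_m, forward_m, vertical_m, bearing_trim_deg, tilt_trim_deg)
  if (length(v) != 5L || any(!is.finite(v)))
    stop("all offset_spec fields must be single finite numbers", call. = FALSE)
  structure(list(lateral_m = lateral_m, forward_m = forward_m,
                 vertical_m = vertical_m, bearing_trim_deg = bearing_trim_deg,
                 tilt_trim_deg = tilt_trim_deg),
            class = "offset_spec")
}

is_zero_offset <- function(offset) {
  all(unlist(offset) == 0)
}

#' Full scanner configuration
#'
#' The complete parameterization of the instrument: the two gimbal axes, the
#' step timing, the tilt sweep in the horizontal coordinate convention
#' (zenith = +90 deg, horizon = 0, nadir = -90), the start bearing (0 = north,
#' the field alignment convention), the rangefinder and the laser mount
#' offsets.
#'
#' @param pan,tilt [axis_config()] objects for the two axes.
#' @param step_duration_s Time between consecutive microsteps, seconds. Must
#'   not undercut 1 / max sampling rate of the rangefinder.
#' @param tilt_start_deg,tilt_end_deg Tilt sweep limits, degrees; start < end,
#'   both within \[-90, +90\].
#' @param start_bearing_deg Bearing at scan start, degrees clockwise from
#'   north.
#' @param rangefinder A [rangefinder_spec()].
#' @param mount_offset An [offset_spec()].
#' @return An object of class `scanner_config`.
#' @seealso [default_scanner_config()] for the reference device.
#' @export
scanner_config <- function(pan, tilt, step_duration_s,
                           tilt_start_deg, tilt_end_deg,
                           start_bearing_deg = 0,
                           rangefinder = rangefinder_spec(),
                           mount_offset = offset_spec()) {
  stopifnot(inherits(pan, "axis_config"), inherits(tilt, "axis_config"),
            inherits(rangefinder, "rangefinder_spec"),
            inherits(mount_offset, "offset_spec"))
  if (!is.numeric(step_duration_s) || length(step_duration_s) != 1L ||
      step_duration_s <= 0)
    stop("step_duration_s must be a single positive number", call. = FALSE)
  # the cap is conventionally quoted to 0.1 ms (3.3 ms at 300 Hz); accept
  # steps within half a display unit of the exact 1/rate bound
  min_step <- 1 / rangefinder$max_sample_rate_hz - 5e-5
  if (step_duration_s < min_step - 1e-12)
    stop(sprintf(
      "step_duration_s = %g s undercuts the sensor sampling cap (minimum %.4g s at %g Hz)",
      step_duration_s, min_step, rangefinder$max_sample_rate_hz), call. = FALSE)
  if (!(tilt_start_deg >= -90 && tilt_start_deg < tilt_end_deg &&
        tilt_end_deg <= 90))
    stop("need -90 <= tilt_start_deg < tilt_end_deg <= 90", call. = FALSE)
  structure(list(pan = pan, tilt = tilt,
                 step_duration_s = step_duration_s,
                 tilt_start_deg = tilt_start_deg,
                 tilt_end_deg = tilt_end_deg,
                 start_bearing_deg = start_bearing_deg %% 360,
                 rangefinder = rangefinder,
                 mount_offset = mount_offset),
            class = "scanner_config")
}

#' Reference device configuration
#'
#' The bundled configuration reproducing the reference build: 200-step
#' motors, 3:1 pan belt drive, direct tilt drive, 1/4 microstepping on both
#' axes, the 3.3 ms step interval used at the 300 Hz sampling cap, a tilt
#' sweep from -40 deg to the zenith, a 40 m / 1 cm rangefinder, and an
#' on-axis (zero-offset) laser. Individual fields can be overridden.
#'
#' @param pan_microstep,tilt_microstep Microstepping denominators.
#' @param step_duration_s Step interval in seconds (3.3 ms literal).
#' @param tilt_start_deg,tilt_end_deg Tilt sweep limits in degrees.
#' @param mount_offset An [offset_spec()].
#' @return A [scanner_config()].
#' @export
#' @examples
#' cfg <- default_scanner_config()
#' pan_resolution_deg(cfg)   # 0.15 degrees between consecutive pulses
#' total_points(cfg)         # 693,600 scheduled pulses
default_scanner_config <- function(pan_microstep = 4L, tilt_microstep = 4L,
                                   step_duration_s = 0.0033,
                                   tilt_start_deg = -40, tilt_end_deg = 90,
                                   mount_offset = offset_spec()) {
  scanner_config(
    pan  = axis_config(motor_spec(200L), pan_microstep, gear_ratio = 3,
                       positive_direction = "clockwise"),
    tilt = axis_config(motor_spec(200L), tilt_microstep, gear_ratio = 1,
                       positive_direction = "up"),
    step_duration_s = step_duration_s,
    tilt_start_deg = tilt_start_deg, tilt_end_deg = tilt_end_deg,
    start_bearing_deg = 0,
    rangefinder = rangefinder_spec(),
    mount_offset = mount_offset)
}

#' @export
print.scanner_config <- function(x, ...) {
  cat("<scanner_config>\n")
  cat(sprintf("  pan : %d steps x m=%d x gear %g:1 -> %.4f deg/step\n",
              x$pan$motor$steps_per_rev, x$pan$microstep_denominator,
              x$pan$gear_ratio, pan_resolution_deg(x)))
  cat(sprintf("  tilt: %d steps x m=%d x gear %g:1 -> %.4f deg/step\n",
              x$tilt$motor$steps_per_rev, x$tilt$microstep_denominator,
              x$tilt$gear_ratio, tilt_resolution_deg(x)))
  cat(sprintf("  step %.4g ms; tilt %g to %g deg; start bearing %g deg\n",
              x$step_duration_s * 1000, x$tilt_start_deg, x$tilt_end_deg,
              x$start_bearing_deg))
  cat(sprintf("  rangefinder: %g m range, %g cm resolution, %g Hz cap\n",
              x$rangefinder$max_range_m,
              x$rangefinder$distance_resolution_m * 100,
              x$rangefinder$max_sample_rate_hz))
  invisible(x)
}

#' Read or write a scanner configuration as YAML
#'
#' The on-disk dialect is plain YAML mirroring the constructor arguments; see
#' `system.file("extdata", "default_scanner.yaml", package = "panoscan")` for
#' the bundled reference device file.
#'
#' @param path File path.
#' @return `read_scanner_config()` returns a [scanner_config()];
#'   `write_scanner_config()` returns `path` invisibly.
#' @export
read_scanner_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  need <- c("pan", "tilt", "step_duration_s", "tilt_start_deg", "tilt_end_deg")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("config file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rf <- do.call(rangefinder_spec, y$rangefinder %||% list())
  off <- do.call(offset_spec, y$mount_offset %||% list())
  mk_axis <- function(a, dir_default) {
    axis_config(motor_spec(a$steps_per_rev %||% 200L),
                a$microstep_denominator %||% 4L,
                a$gear_ratio %||% 1,
                a$positive_direction %||% dir_default)
  }
  scanner_config(pan = mk_axis(y$pan, "clockwise"),
                 tilt = mk_axis(y$tilt, "up"),
                 step_duration_s = y$step_duration_s,
                 tilt_start_deg = y$tilt_start_deg,
                 tilt_end_deg = y$tilt_end_deg,
                 start_bearing_deg = y$start_bearing_deg %||% 0,
                 rangefinder = rf, mount_offset = off)
}

#' @rdname read_scanner_config
#' @param config A [scanner_config()].
#' @export
write_scanner_config <- function(config, path) {
  stopifnot(inherits(config, "scanner_config"))
  y <- list(
    pan = list(steps_per_rev = config$pan$motor$steps_per_rev,
               microstep_denominator = config$pan$microstep_denominator,
               gear_ratio = config$pan$gear_ratio,
               positive_direction = config$pan$positive_direction),
    tilt = list(steps_per_rev = config$tilt$motor$steps_per_rev,
                microstep_denominator = config$tilt$microstep_denominator,
                gear_ratio = config$tilt$gear_ratio,
                positive_direction = config$tilt$positive_direction),
    step_duration_s = config$step_duration_s,
    tilt_start_deg = config$tilt_start_deg,
    tilt_end_deg = config$tilt_end_deg,
    start_bearing_deg = config$start_bearing_deg,
    rangefinder = unclass(config$rangefinder),
    mount_offset = unclass(config$mount_offset))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
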