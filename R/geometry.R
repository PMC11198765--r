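# Frame convention, used everywhere: east-north-up Cartesian axes; bearing in
# degrees clockwise from north in [0, 360); tilt in degrees with zenith = +90,
# horizon = 0, nadir = -90. Degrees at every interface, radians internally.

deg2rad <- function(d) d * (pi / 180)
rad2deg <- function(r) r * (180 / pi)

#' Laser orientation
#'
#' @param bearing_deg Bearing, degrees clockwise from north; reduced mod 360.
#' @param tilt_deg Tilt, degrees in \[-90, +90\]; out-of-range raises.
#' @return An `orientation` object.
#' @export
orientation <- function(bearing_deg = 0, tilt_deg = 0) {
  if (!is.finite(bearing_deg) || !is.finite(tilt_deg))
    stop("orientation angles must be finite", call. = FALSE)
  if (tilt_deg < -90 || tilt_deg > 90)
    stop("tilt_deg outside the physical range [-90, 90]", call. = FALSE)
  structure(list(bearing_deg = bearing_deg %% 360, tilt_deg = tilt_deg),
            class = "orientation")
}

#' Stepper step event
#'
#' A batch of identical microsteps on one axis, as recorded by the controller
#' during a scan.
#'
#' @param axis `"pan"` or `"tilt"`.
#' @param direction `+1` for the axis' positive sense (clockwise pan / upward
#'   tilt), `-1` otherwise.
#' @param count Number of microsteps (>= 1).
#' @return A `step_event` object.
#' @export
step_event <- function(axis = c("pan", "tilt"), direction = 1L, count = 1L) {
  axis <- match.arg(axis)
  if (!direction %in% c(-1L, 1L)) stop("direction must be +1 or -1", call. = FALSE)
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1", call. = FALSE)
  structure(list(axis = axis, direction = as.integer(direction), count = count),
            class = "step_event")
}

#' Dead-reckoning orientation from stepper movements
#'
#' Computes the laser orientation after a sequence of recorded stepper
#' movements, starting from a known initial orientation: each pan microstep
#' advances the bearing by the pan resolution (signed), each tilt microstep
#' the tilt by the tilt resolution. Because steps are discrete counts, the
#' result is path-independent and accumulates no drift - the property that
#' lets the scanner do without an inertial sensor.
#'
#' @param initial An [orientation()].
#' @param events A list of [step_event()]s (a single event is accepted).
#' @param config A [scanner_config()] providing the per-step resolutions.
#' @return The final [orientation()]; raises if the tilt leaves
#'   \[-90, +90\].
#' @export
#' @examples
#' cfg <- default_scanner_config()
#' backtrack(orientation(0, 0), step_event("pan", +1, 1), cfg)  # bearing 0.15
backtrack <- function(initial, events, config) {
  stopifnot(inherits(initial, "orientation"), inherits(config, "scanner_config"))
  if (inherits(events, "step_event")) events <- list(events)
  pan_res <- pan_resolution_deg(config)
  tilt_res <- tilt_resolution_deg(config)
  pan_steps <- 0; tilt_steps <- 0
  for (ev in events) {
    stopifnot(inherits(ev, "step_event"))
    if (ev$axis == "pan") pan_steps <- pan_steps + ev$direction * ev$count
    else tilt_steps <- tilt_steps + ev$direction * ev$count
  }
  tilt <- initial$tilt_deg + tilt_steps * tilt_res
  if (tilt < -90 - 1e-9 || tilt > 90 + 1e-9)
    stop(sprintf("backtracked tilt %.4f deg leaves the physical range [-90, 90]",
                 tilt), call. = FALSE)
  orientation((initial$bearing_deg + pan_steps * pan_res) %% 360,
              min(90, max(-90, tilt)))
}

#' Horizontal coordinates to Cartesian
#'
#' Maps (bearing, tilt, distance) to east-north-up meters:
#' x = d cos(tilt) sin(bearing), y = d cos(tilt) cos(bearing),
#' z = d sin(tilt). Vectorized over all arguments.
#'
#' @param bearing_deg Bearing(s), degrees clockwise from north.
#' @param tilt_deg Tilt(s), degrees (zenith +90, horizon 0, nadir -90).
#' @param distance_m Range(s), meters, >= 0.
#' @return A data.frame with columns `x`, `y`, `z` (meters).
#' @export
#' @examples
#' to_cartesian(0, 0, 10)    # 10 m due north on the horizon
#' to_cartesian(90, 0, 10)   # due east
to_cartesian <- function(bearing_deg, tilt_deg, distance_m) {
  if (any(distance_m < 0)) stop("distance_m must be >= 0", call. = FALSE)
  b <- deg2rad(bearing_deg); t <- deg2rad(tilt_deg)
  data.frame(x = distance_m * cos(t) * sin(b),
             y = distance_m * cos(t) * cos(b),
             z = distance_m * sin(t))
}

#' Cartesian to horizontal coordinates
#'
#' Inverse of [to_cartesian()]. On the zenith/nadir singularity (x = y = 0)
#' the bearing is reported as 0 by convention. Vectorized.
#'
#' @param x,y,z East, north, up coordinates in meters.
#' @return A data.frame with columns `bearing_deg` (in \[0, 360)),
#'   `tilt_deg`, `distance_m`; raises on a zero vector.
#' @export
from_cartesian <- function(x, y, z) {
  d <- sqrt(x^2 + y^2 + z^2)
  if (any(d == 0)) stop("zero vector has no orientation", call. = FALSE)
  h <- sqrt(x^2 + y^2)
  bearing <- ifelse(h == 0, 0, rad2deg(atan2(x, y)) %% 360)
  data.frame(bearing_deg = bearing,
             tilt_deg = rad2deg(atan2(z, h)),
             distance_m = d)
}

#' Off-axis mount offset correction
#'
#' The laser origin is displaced from the pan axis; as the head spins the
#' origin traces a circle, shifting every naive reconstruction. The
#' correction places the point at o(bearing) + d * u(bearing + bearing trim,
#' tilt + tilt trim), where o is the mount offset vector rotated about the
#' vertical axis by the trim-corrected bearing and u is the beam unit
#' vector. With a zero [offset_spec()] this reduces exactly to
#' [to_cartesian()]. Vectorized over records.
#'
#' @inheritParams to_cartesian
#' @param offset An [offset_spec()].
#' @return A data.frame with columns `x`, `y`, `z` (meters).
#' @export
correct_offset <- function(bearing_deg, tilt_deg, distance_m,
                           offset = offset_spec()) {
  stopifnot(inherits(offset, "offset_spec"))
  if (is_zero_offset(offset))
    return(to_cartesian(bearing_deg, tilt_deg, distance_m))
  if (any(distance_m < 0)) stop("distance_m must be >= 0", call. = FALSE)
  b_eff <- bearing_deg + offset$bearing_trim_deg
  t_eff <- tilt_deg + offset$tilt_trim_deg
  br <- deg2rad(b_eff)
  # rotate the head-frame origin (lateral = east at bearing 0, forward =
  # north at bearing 0) clockwise by the bearing
  ox <- offset$lateral_m * cos(br) + offset$forward_m * sin(br)
  oy <- -offset$lateral_m * sin(br) + offset$forward_m * cos(br)
  beam <- to_cartesian(b_eff, t_eff, distance_m)
  data.frame(x = ox + beam$x, y = oy + beam$y, z = offset$vertical_m + beam$z)
}

#' Laser origin position for given bearings
#'
#' Where the laser aperture sits (relative to the scanner reference origin)
#' when the head points at the given bearing; used by the simulator to cast
#' rays from the physically correct origin.
#'
#' @param bearing_deg Bearing(s), degrees.
#' @param offset An [offset_spec()].
#' @return A data.frame with columns `x`, `y`, `z`.
#' @keywords internal
laser_origin <- function(bearing_deg, offset = offset_spec()) {
  br <- deg2rad(bearing_deg + offset$bearing_trim_deg)
  data.frame(x = offset$lateral_m * cos(br) + offset$forward_m * sin(br),
             y = -offset$lateral_m * sin(br) + offset$forward_m * cos(br),
             z = rep(offset$vertical_m, length.out = length(br)))
}
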