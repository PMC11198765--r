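# Solid angle of the band between two tilt angles (degrees), clamped to the
# physical range: 2*pi*(sin(t2) - sin(t1)) steradians.
band_solid_angle <- function(t1_deg, t2_deg) {
  t1 <- deg2rad(pmax(-90, pmin(90, t1_deg)))
  t2 <- deg2rad(pmax(-90, pmin(90, t2_deg)))
  2 * pi * (sin(t2) - sin(t1))
}

#' Point density over the scan sphere
#'
#' Bins a schedule's pulses into tilt bands and reports the count, the band
#' solid angle and the resulting density in points per steradian. With a
#' fixed pan microstepping every revolution has the same pulse count while
#' the band solid angle shrinks as cos(tilt), so density is lowest along the
#' horizon and rises toward zenith and nadir - the non-uniformity the
#' adaptive plan corrects.
#'
#' @param schedule A [build_schedule()] or [scan_window()] result.
#' @param band_width_deg Tilt band width, degrees (> 0).
#' @return A `density_profile` data.table with columns `tilt_lo_deg`,
#'   `tilt_hi_deg`, `points`, `solid_angle_sr`, `density_pts_per_sr`.
#' @export
density_profile <- function(schedule, band_width_deg = 5) {
  if (!nrow(schedule)) stop("empty schedule", call. = FALSE)
  if (band_width_deg <= 0) stop("band width must be > 0", call. = FALSE)
  w <- band_width_deg
  lo <- floor(min(schedule$tilt_deg) / w) * w
  hi <- max(schedule$tilt_deg)
  edges <- seq(lo, hi + w, by = w)
  band <- findInterval(schedule$tilt_deg, edges, rightmost.closed = FALSE)
  counts <- tabulate(band, nbins = length(edges) - 1)
  out <- data.table::data.table(
    tilt_lo_deg = edges[-length(edges)],
    tilt_hi_deg = edges[-1],
    points = counts)
  out <- out[out$points > 0 | (out$tilt_lo_deg < hi & out$tilt_hi_deg > lo), ]
  data.table::set(out, j = "solid_angle_sr",
                  value = band_solid_angle(out$tilt_lo_deg, out$tilt_hi_deg))
  data.table::set(out, j = "density_pts_per_sr",
                  value = out$points / out$solid_angle_sr)
  data.table::setattr(out, "class", c("density_profile", class(out)))
  out[]
}

# per-revolution ring densities for a given tilt sequence and ring counts
ring_density <- function(tilt_deg, points, tilt_res_deg) {
  sa <- band_solid_angle(tilt_deg - tilt_res_deg / 2,
                         tilt_deg + tilt_res_deg / 2)
  points / sa
}

#' Tilt-adaptive microstepping plan for uniform density
#'
#' With a fixed pan microstepping, rings near the zenith and nadir are
#' heavily oversampled because their solid angle shrinks as cos(tilt). This
#' plan picks, for every revolution at tilt t, the pan microstepping
#' denominator from the hardware set (1, 2, 4, 8, 16, capped at the config's
#' own) whose ring pulse count best approximates the horizon count times
#' cos(t) (ties resolved toward the denser option). The result equalizes
#' density over the sphere and shortens the scan by skipping redundant
#' pulses.
#'
#' @param config A [scanner_config()].
#' @return An `adaptive_plan` list: `rings` (data.table with `revolution`,
#'   `tilt_deg`, `microstep`, `points`), totals and durations for the fixed
#'   and adaptive plans, and the achieved density coefficients of variation.
#' @export
uniform_density_plan <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  m_fixed <- config$pan$microstep_denominator
  avail <- c(1L, 2L, 4L, 8L, 16L)
  avail <- avail[avail <= m_fixed]
  base <- config$pan$motor$steps_per_rev * config$pan$gear_ratio  # pts/rev at m=1
  n_rev <- num_revolutions(config)
  tres <- tilt_resolution_deg(config)
  tilt <- config$tilt_start_deg + (seq_len(n_rev) - 1) * tres
  n_target <- base * m_fixed * cos(deg2rad(pmax(-90, pmin(90, tilt))))
  pick <- vapply(n_target, function(tgt) {
    err <- abs(base * avail - tgt)
    best <- which(err == min(err))
    avail[best[length(best)]]  # tie toward the denser option
  }, integer(1))
  rings <- data.table::data.table(
    revolution = seq_len(n_rev) - 1L,
    tilt_deg = tilt,
    microstep = pick,
    points = as.integer(round(base * pick)))
  fixed_points <- as.integer(round(base * m_fixed))
  dens_fixed <- ring_density(tilt, rep(fixed_points, n_rev), tres)
  dens_adapt <- ring_density(tilt, rings$points, tres)
  cv <- function(x) stats::sd(x) / mean(x)
  structure(list(
    rings = rings,
    fixed_total_points = fixed_points * n_rev,
    adaptive_total_points = sum(rings$points),
    fixed_duration_s = fixed_points * n_rev * config$step_duration_s,
    adaptive_duration_s = sum(rings$points) * config$step_duration_s,
    fixed_density_cv = cv(dens_fixed),
    adaptive_density_cv = cv(dens_adapt)),
    class = "adaptive_plan")
}

#' @export
print.adaptive_plan <- function(x, ...) {
  cat("<adaptive_plan>\n")
  cat(sprintf("  fixed   : %d points, %.1f min, density CV %.3f\n",
              x$fixed_total_points, x$fixed_duration_s / 60,
              x$fixed_density_cv))
  cat(sprintf("  adaptive: %d points, %.1f min, density CV %.3f\n",
              x$adaptive_total_points, x$adaptive_duration_s / 60,
              x$adaptive_density_cv))
  cat(sprintf("  scan time saved: %.1f%%\n",
              100 * (1 - x$adaptive_duration_s / x$fixed_duration_s)))
  invisible(x)
}

#' Restricted scan window schedule
#'
#' Builds a schedule covering only a bearing/tilt window instead of the full
#' panorama: the head sweeps the bearing window back and forth (stepper
#' motors run equally well in either direction; the turnaround is taken as
#' instantaneous), the tilt advances one step per sweep, and the per-step
#' timing and angular spacing are exactly those of the full scan. The
#' bearing window may wrap through north (e.g. 350 to 10 degrees);
#' `bearing_min == bearing_max` means the full circle.
#'
#' @param config A [scanner_config()].
#' @param bearing_min_deg,bearing_max_deg Bearing window, degrees clockwise
#'   from north.
#' @param tilt_min_deg,tilt_max_deg Tilt window, degrees; defaults to the
#'   config's full sweep.
#' @return A `scan_schedule` (as from [build_schedule()]) with attribute
#'   `window`.
#' @export
scan_window <- function(config, bearing_min_deg = 0, bearing_max_deg = 0,
                        tilt_min_deg = config$tilt_start_deg,
                        tilt_max_deg = config$tilt_end_deg) {
  stopifnot(inherits(config, "scanner_config"))
  res <- pan_resolution_deg(config)
  tres <- tilt_resolution_deg(config)
  w <- (bearing_max_deg - bearing_min_deg) %% 360
  if (w == 0) w <- 360
  ratio <- w / res
  n_pan <- if (abs(ratio - round(ratio)) < 1e-6) as.integer(round(ratio))
  else as.integer(floor(ratio)) + 1L
  # revolutions of the full sweep whose tilt falls inside the window
  n_rev_full <- num_revolutions(config)
  tilts_all <- config$tilt_start_deg + (seq_len(n_rev_full) - 1) * tres
  tilts <- tilts_all[tilts_all >= tilt_min_deg - 1e-9 &
                       tilts_all <= tilt_max_deg + 1e-9]
  if (!length(tilts) || n_pan < 1)
    stop("empty scan window", call. = FALSE)
  n <- length(tilts) * n_pan
  idx <- seq_len(n) - 1
  k <- idx %% n_pan
  rev_idx <- idx %/% n_pan
  # back-and-forth: odd sweeps run the bearing sequence in reverse
  k_eff <- ifelse(rev_idx %% 2 == 1, n_pan - 1 - k, k)
  sch <- data.table::data.table(
    time_ms = idx * (config$step_duration_s * 1000),
    bearing_deg = (bearing_min_deg + k_eff * res) %% 360,
    tilt_deg = tilts[rev_idx + 1],
    revolution = as.integer(rev_idx))
  data.table::setattr(sch, "config", config)
  data.table::setattr(sch, "window",
                      c(bearing_min_deg = bearing_min_deg,
                        bearing_max_deg = bearing_max_deg,
                        tilt_min_deg = tilt_min_deg,
                        tilt_max_deg = tilt_max_deg))
  data.table::setattr(sch, "class", c("scan_schedule", class(sch)))
  sch[]
}
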