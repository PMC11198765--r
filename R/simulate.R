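#' Rangefinder noise model
#'
#' The measurement model of the ranging sensor: a range-dependent 1-sigma
#' Gaussian error (the near/far datasheet accuracy figures) followed by
#' quantization to the sensor's distance resolution (round half up). Built
#' from a [rangefinder_spec()] by default.
#'
#' @param quantization_m Distance quantization step, meters.
#' @param sd_near_m 1-sigma error below `boundary_m`, meters.
#' @param sd_far_m 1-sigma error beyond `boundary_m`, meters.
#' @param boundary_m Near/far regime boundary, meters.
#' @param seed Integer seed making simulated scans reproducible.
#' @return A `noise_model` object.
#' @export
#' @examples
#' noise_model(seed = 7)                    # datasheet defaults
#' noise_model(sd_near_m = 0, sd_far_m = 0) # quantization only
noise_model <- function(quantization_m = 0.01, sd_near_m = 0.05,
                        sd_far_m = 0.025, boundary_m = 2, seed = 1L) {
  v <- c(quantization_m, sd_near_m, sd_far_m, boundary_m)
  if (any(v < 0)) stop("noise model fields must be nonnegative", call. = FALSE)
  structure(list(quantization_m = quantization_m, sd_near_m = sd_near_m,
                 sd_far_m = sd_far_m, boundary_m = boundary_m,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' @rdname noise_model
#' @param rangefinder A [rangefinder_spec()].
#' @export
noise_from_rangefinder <- function(rangefinder = rangefinder_spec(), seed = 1L) {
  noise_model(quantization_m = rangefinder$distance_resolution_m,
              sd_near_m = rangefinder$accuracy_near_m,
              sd_far_m = rangefinder$accuracy_far_m,
              boundary_m = rangefinder$near_far_boundary_m, seed = seed)
}

# apply Gaussian error + quantization to true distances; draws in input order
apply_noise <- function(true_distance_m, noise) {
  sd <- ifelse(true_distance_m < noise$boundary_m, noise$sd_near_m,
               noise$sd_far_m)
  d <- true_distance_m + stats::rnorm(length(true_distance_m), 0, sd)
  q <- noise$quantization_m
  if (q > 0) d <- floor(d / q + 0.5) * q  # round half up
  pmax(d, 0)
}

#' Cast rays against a scene
#'
#' Computes, for each ray, the distance to the first intersection with the
#' terrain surface, a trunk cylinder or a crown surface, up to `max_range_m`.
#' Terrain intersections use bounded ray marching with bisection refinement
#' to below a millimeter (planar terrain has a closed form, used unless
#' `force_march`); trunk and crown intersections are closed-form quadrics.
#' A miss is a value (`NA` distance), not an error.
#'
#' @param origin Numeric length-3 vector or n x 3 matrix of ray origins (m).
#' @param direction Matching unit direction vector(s).
#' @param scene A [scene()].
#' @param max_range_m Maximum range, meters.
#' @param march_step_m Coarse marching step for non-planar terrain, meters.
#' @param force_march Use the marching path even on planar terrain (for
#'   cross-checking against the closed form).
#' @param seed Seed for the foliage-penetration draws of porous crowns (see
#'   [tree_primitive()]); irrelevant for opaque crowns.
#' @return A list with `distance_m` (NA on miss) and `hit` (factor:
#'   `"terrain"`, `"trunk"`, `"crown"`, `NA` on miss).
#' @export
#' @examples
#' sc <- scene(terrain_plane())
#' ray_cast(c(0, 0, 1.5), c(0, 0, -1), sc)$distance_m  # 1.5
ray_cast <- function(origin, direction, scene, max_range_m = 40,
                     march_step_m = 0.25, force_march = FALSE, seed = 0L) {
  stopifnot(inherits(scene, "scene"))
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 3)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 3)
  stopifnot(ncol(origin) == 3, ncol(direction) == 3,
            nrow(origin) == nrow(direction))
  nrm <- sqrt(rowSums(direction^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("direction vectors must be unit length", call. = FALSE)
  res <- raycast_cpp(origin, direction,
                     scene_terrain_type(scene), scene_terrain_params(scene),
                     scene_hills_matrix(scene), scene_trees_matrix(scene),
                     max_range_m, scene_band(scene)[1], scene_band(scene)[2],
                     march_step_m, force_march, as.numeric(seed))
  hit <- factor(ifelse(res$hit >= 0L,
                       c("terrain", "trunk", "crown")[pmax(res$hit, 0L) + 1L],
                       NA_character_),
                levels = c("terrain", "trunk", "crown"))
  list(distance_m = res$distance, hit = hit)
}

scene_terrain_type <- function(scene) {
  if (scene$terrain$type == "plane") 0L else 1L
}
scene_terrain_params <- function(scene) {
  if (scene$terrain$type == "plane")
    c(scene$terrain$z0, scene$terrain$sx, scene$terrain$sy)
  else scene$terrain$z0
}
scene_hills_matrix <- function(scene) {
  if (scene$terrain$type == "plane") matrix(0, 0, 4)
  else as.matrix(scene$terrain$hills[, c("x", "y", "amp", "sigma")])
}
scene_trees_matrix <- function(scene) {
  tr <- scene$trees
  if (!nrow(tr)) return(matrix(0, 0, 9))
  ext <- tr$crown_extinction_per_m %||% rep(Inf, nrow(tr))
  cbind(tr$x, tr$y, tr$base_z, tr$trunk_radius_m, tr$trunk_height_m,
        tr$total_height_m, ifelse(tr$crown == "cone", 1, 0), tr$crown_radius_m,
        pmin(ext, 1e6))
}
scene_band <- function(scene) {
  pad <- 0.01
  if (scene$terrain$type == "plane") {
    ex <- scene$extent
    zc <- terrain_height(scene$terrain, ex[c(1, 2, 1, 2)], ex[c(3, 3, 4, 4)])
    # planar terrain extends beyond the extent; widen generously
    c(min(zc) - 10, max(zc) + 10)
  } else {
    b <- terrain_band(scene$terrain)
    c(b[1] - pad, b[2] + pad)
  }
}

#' Place the scanner on the terrain
#'
#' @param scene A [scene()].
#' @param x,y Tripod position, meters.
#' @param height_m Sensor height above the ground, meters (tripod height).
#' @return Length-3 numeric position (x, y, z).
#' @export
scanner_position <- function(scene, x = 0, y = 0, height_m = 1.5) {
  c(x, y, terrain_height(scene$terrain, x, y) + height_m)
}

#' Simulate a full scan
#'
#' Runs the virtual instrument: for every schedule entry a ray is cast from
#' the (offset-corrected) laser origin along the commanded orientation; hits
#' get the rangefinder's Gaussian error and centimeter quantization and are
#' recorded in the raw scan table; misses (no return within range) are
#' dropped unless `keep_misses` (then recorded with distance -1 for
#' diagnostics). Deterministic given the noise seed.
#'
#' @param config A [scanner_config()].
#' @param scene A [scene()].
#' @param position Scanner reference origin (x, y, z), e.g. from
#'   [scanner_position()]; must be above the terrain.
#' @param noise A [noise_model()]; `NULL` for an error-free instrument
#'   (quantization still applied via the config's rangefinder resolution).
#' @param schedule Optional pre-built [build_schedule()] (e.g. a restricted
#'   [scan_window()]); defaults to the config's full schedule.
#' @param keep_misses Keep no-return pulses with distance -1.
#' @return A `raw_scan`: data.table with columns `time_ms`, `bearing_deg`,
#'   `tilt_deg`, `distance_m` plus a `target` truth column
#'   (terrain/trunk/crown) from the simulator; attributes `config`,
#'   `position`, `seed`, `n_pulses`, `n_misses`.
#' @export
simulate_scan <- function(config, scene, position = scanner_position(scene),
                          noise = noise_from_rangefinder(config$rangefinder),
                          schedule = NULL, keep_misses = FALSE) {
  stopifnot(inherits(config, "scanner_config"), inherits(scene, "scene"))
  if (position[3] <= terrain_height(scene$terrain, position[1], position[2]))
    stop("scanner position is on or below the terrain", call. = FALSE)
  if (is.null(schedule)) schedule <- build_schedule(config)
  off <- config$mount_offset
  o <- laser_origin(schedule$bearing_deg, off)
  origin <- cbind(position[1] + o$x, position[2] + o$y, position[3] + o$z)
  dirs <- as.matrix(to_cartesian(schedule$bearing_deg + off$bearing_trim_deg,
                                 schedule$tilt_deg + off$tilt_trim_deg, 1))
  canopy_seed <- if (is.null(noise)) 0L else noise$seed
  cast <- ray_cast(origin, dirs, scene,
                   max_range_m = config$rangefinder$max_range_m,
                   seed = canopy_seed)
  d_true <- cast$distance_m
  hit <- !is.na(d_true)
  d_meas <- rep(NA_real_, length(d_true))
  if (is.null(noise)) {
    q <- config$rangefinder$distance_resolution_m
    d_meas[hit] <- floor(d_true[hit] / q + 0.5) * q
    seed_used <- NA_integer_
  } else {
    rng <- local_rng(noise$seed)
    on.exit(rng())
    d_meas[hit] <- apply_noise(d_true[hit], noise)
    seed_used <- noise$seed
  }
  raw <- data.table::data.table(
    time_ms = schedule$time_ms,
    bearing_deg = schedule$bearing_deg,
    tilt_deg = schedule$tilt_deg,
    distance_m = d_meas,
    target = cast$hit)
  n_total <- nrow(raw)
  n_miss <- sum(!hit)
  if (keep_misses) {
    data.table::set(raw, i = which(!hit), j = "distance_m", value = -1)
  } else {
    raw <- raw[hit, ]
  }
  data.table::setattr(raw, "config", config)
  data.table::setattr(raw, "position", as.numeric(position))
  data.table::setattr(raw, "seed", seed_used)
  data.table::setattr(raw, "n_pulses", n_total)
  data.table::setattr(raw, "n_misses", n_miss)
  data.table::setattr(raw, "class", c("raw_scan", class(raw)))
  raw[]
}

#' Read and write raw scan tables
#'
#' The canonical on-disk dialect of the scanner's raw record format: a plain
#' text table, one pulse per line, header `time_ms bearing_deg tilt_deg
#' distance_m`, tab-separated, with time to 1 decimal (ms), angles to 4 and
#' distances to 2. The simulator's `target` truth column is not part of the
#' format and is not written.
#'
#' @param raw A `raw_scan` from [simulate_scan()] (or a data.frame with the
#'   four canonical columns).
#' @param path File path.
#' @return `write_raw_scan()` returns `path` invisibly; `read_raw_scan()`
#'   returns a `raw_scan` data.table.
#' @export
write_raw_scan <- function(raw, path) {
  need <- c("time_ms", "bearing_deg", "tilt_deg", "distance_m")
  if (!all(need %in% names(raw)))
    stop("raw scan must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lines <- sprintf("%.1f\t%.4f\t%.4f\t%.2f", raw$time_ms, raw$bearing_deg,
                   raw$tilt_deg, raw$distance_m)
  writeLines(c(paste(need, collapse = "\t"), lines), path)
  invisible(path)
}

#' @rdname write_raw_scan
#' @export
read_raw_scan <- function(path) {
  if (!file.exists(path)) stop("raw scan file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  need <- c("time_ms", "bearing_deg", "tilt_deg", "distance_m")
  if (!identical(strsplit(header, "\t")[[1]], need))
    stop("not a raw scan file (expected header '",
         paste(need, collapse = "\\t"), "'): ", path, call. = FALSE)
  raw <- suppressWarnings(data.table::fread(path, sep = "\t", header = TRUE))
  for (col in need) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed raw scan record at line ", bad[1] + 1L, " of ", path,
           call. = FALSE)
    data.table::set(raw, j = col, value = v)
  }
  data.table::setattr(raw, "class", c("raw_scan", class(raw)))
  raw[]
}

#' @export
print.raw_scan <- function(x, ...) {
  cat(sprintf("<raw_scan> %d records (%s misses dropped of %s pulses)\n",
              nrow(x),
              format(attr(x, "n_misses") %||% NA),
              format(attr(x, "n_pulses") %||% NA)))
  NextMethod()
}
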