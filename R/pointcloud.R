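#' Point cloud container
#'
#' A Cartesian point cloud: a data.table with columns `x`, `y`, `z` (meters,
#' east-north-up) and optionally `t_ms` (time of measurement), `label`
#' (ground / vegetation / unclassified), `scan_id` (provenance) and
#' `target` (simulator truth).
#'
#' @param x A data.frame with at least `x`, `y`, `z`.
#' @return A `point_cloud` data.table.
#' @export
point_cloud <- function(x = data.frame(x = numeric(0), y = numeric(0),
                                       z = numeric(0))) {
  stopifnot(all(c("x", "y", "z") %in% names(x)))
  pc <- data.table::as.data.table(x)
  if (nrow(pc) && any(!is.finite(pc$x) | !is.finite(pc$y) | !is.finite(pc$z)))
    stop("point cloud coordinates must be finite", call. = FALSE)
  if (!is.null(pc$label)) {
    pc$label <- factor(as.character(pc$label),
                       levels = c("ground", "vegetation", "unclassified"))
  }
  data.table::setattr(pc, "class", c("point_cloud", class(pc)))
  pc[]
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points\n", nrow(x)))
  if (!is.null(x$label)) {
    tb <- table(x$label)
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}

#' Reconstruct a Cartesian point cloud from a raw scan
#'
#' Converts each raw record (time, bearing, tilt, distance) to a Cartesian
#' point via the off-axis mount offset correction; count and order are
#' preserved, as is the per-point time. Records flagged as misses
#' (distance -1, if the scan kept them) are rejected.
#'
#' @param raw A `raw_scan` (from [simulate_scan()] or [read_raw_scan()]).
#' @param offset An [offset_spec()]; defaults to the mount offset of the
#'   config carried by the scan, or zero.
#' @param max_range_m Records beyond this range are treated as corrupt;
#'   defaults to the carried config's rangefinder range (40 m otherwise).
#' @return A [point_cloud()] with columns `x`, `y`, `z`, `t_ms` (and
#'   `target` if the scan carries simulator truth).
#' @export
reconstruct <- function(raw, offset = NULL, max_range_m = NULL) {
  need <- c("time_ms", "bearing_deg", "tilt_deg", "distance_m")
  if (!all(need %in% names(raw)))
    stop("raw scan must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  cfg <- attr(raw, "config")
  if (is.null(offset))
    offset <- if (!is.null(cfg)) cfg$mount_offset else offset_spec()
  if (is.null(max_range_m))
    max_range_m <- if (!is.null(cfg)) cfg$rangefinder$max_range_m else 40
  bad <- which(!is.finite(raw$distance_m) | raw$distance_m < 0 |
                 raw$distance_m > max_range_m)
  if (length(bad))
    stop(sprintf("invalid distance %.2f m in raw record %d (valid range 0..%g m)",
                 raw$distance_m[bad[1]], bad[1], max_range_m), call. = FALSE)
  p <- correct_offset(raw$bearing_deg, raw$tilt_deg, raw$distance_m, offset)
  pos <- attr(raw, "position")
  if (!is.null(pos)) {
    p$x <- p$x + pos[1]; p$y <- p$y + pos[2]; p$z <- p$z + pos[3]
  }
  p$t_ms <- raw$time_ms
  if (!is.null(raw$target)) p$target <- raw$target
  point_cloud(p)
}

#' Rigid transform (rotation about the vertical axis plus translation)
#'
#' The registration degrees of freedom of a leveled tripod scanner: a yaw
#' rotation and a 3D translation. Used to place single scans into a common
#' frame before merging (the alignment itself is assumed known).
#'
#' @param rotation_deg Rotation about the vertical axis, degrees clockwise
#'   from above (same sense as bearing).
#' @param dx,dy,dz Translation, meters.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation_deg = 0, dx = 0, dy = 0, dz = 0) {
  stopifnot(is.finite(rotation_deg), is.finite(dx), is.finite(dy), is.finite(dz))
  structure(list(rotation_deg = rotation_deg, dx = dx, dy = dy, dz = dz),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param cloud A [point_cloud()].
#' @param transform A `rigid_transform`.
#' @return `apply_transform()` returns the transformed [point_cloud()];
#'   `invert_transform()` the inverse `rigid_transform`.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  out <- data.table::copy(cloud)
  a <- deg2rad(transform$rotation_deg)
  # clockwise-from-above rotation in the east-north plane
  x2 <- cloud$x * cos(a) + cloud$y * sin(a)
  y2 <- -cloud$x * sin(a) + cloud$y * cos(a)
  data.table::set(out, j = "x", value = x2 + transform$dx)
  data.table::set(out, j = "y", value = y2 + transform$dy)
  data.table::set(out, j = "z", value = cloud$z + transform$dz)
  out
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(transform) {
  a <- deg2rad(transform$rotation_deg)
  # rotate the negated translation back into the source frame
  dx2 <- -(transform$dx * cos(-a) + transform$dy * sin(-a))
  dy2 <- -(-transform$dx * sin(-a) + transform$dy * cos(-a))
  rigid_transform(-transform$rotation_deg, dx2, dy2, -transform$dz)
}

#' Merge point clouds under known rigid transforms
#'
#' Concatenates the transformed clouds; counts are additive and no
#' deduplication is performed. Each input keeps (or receives) a `scan_id`
#' provenance column.
#'
#' @param clouds List of [point_cloud()]s.
#' @param transforms List of [rigid_transform()]s of the same length, or
#'   `NULL` for identities.
#' @return A merged [point_cloud()].
#' @export
merge_clouds <- function(clouds, transforms = NULL) {
  stopifnot(is.list(clouds))
  if (is.null(transforms))
    transforms <- replicate(length(clouds), rigid_transform(), simplify = FALSE)
  if (length(clouds) != length(transforms))
    stop("clouds and transforms must have the same length", call. = FALSE)
  if (!length(clouds)) return(point_cloud())
  parts <- lapply(seq_along(clouds), function(i) {
    ci <- apply_transform(clouds[[i]], transforms[[i]])
    if (is.null(ci$scan_id))
      data.table::set(ci, j = "scan_id", value = rep(i, nrow(ci)))
    ci
  })
  point_cloud(data.table::rbindlist(parts, fill = TRUE))
}

#' Read and write ASCII XYZ point clouds
#'
#' Space-separated `x y z [t_ms]` with 3-decimal meters (and 1-decimal
#' milliseconds), no header.
#'
#' @param cloud A [point_cloud()].
#' @param path File path.
#' @param time Write the `t_ms` column if present.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` a
#'   [point_cloud()].
#' @export
write_xyz <- function(cloud, path, time = !is.null(cloud$t_ms)) {
  lines <- if (time && !is.null(cloud$t_ms))
    sprintf("%.3f %.3f %.3f %.1f", cloud$x, cloud$y, cloud$z, cloud$t_ms)
  else sprintf("%.3f %.3f %.3f", cloud$x, cloud$y, cloud$z)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    return(point_cloud())
  dt <- tryCatch(
    data.table::fread(path, sep = " ", header = FALSE, fill = FALSE),
    error = function(e) stop("not a valid ASCII XYZ file (", conditionMessage(e),
                             "): ", path, call. = FALSE))
  if (!ncol(dt) %in% c(3L, 4L) || !all(vapply(dt, is.numeric, TRUE)))
    stop("not a valid ASCII XYZ file (expected 3 or 4 numeric columns): ",
         path, call. = FALSE)
  names(dt) <- c("x", "y", "z", if (ncol(dt) == 4L) "t_ms")
  point_cloud(dt)
}
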