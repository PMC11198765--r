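#' Elevation raster
#'
#' A regular grid of meters: `values` is an ny x nx matrix with row 1 at the
#' southern edge; cell (i, j) has its center at
#' (x0 + (j - 0.5) cell, y0 + (i - 0.5) cell). `NA` marks nodata.
#'
#' @param values Numeric matrix (rows = south to north).
#' @param origin `c(x0, y0)`: the lower-left corner, meters.
#' @param cell_size_m Cell edge, meters (> 0).
#' @return A `lidar_raster` object.
#' @export
lidar_raster <- function(values, origin, cell_size_m) {
  stopifnot(is.matrix(values), length(origin) == 2, cell_size_m > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size_m = cell_size_m),
            class = "lidar_raster")
}

#' @export
print.lidar_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<lidar_raster> %d x %d cells of %g m; %.1f%% nodata; range [%.2f, %.2f] m\n",
              nrow(v), ncol(v), x$cell_size_m, 100 * mean(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

# bilinear interpolation at arbitrary coordinates, nodata-aware: where any
# of the four surrounding centers is NA, fall back to the nearest valid one
# of them; NA where none is valid or outside the grid.
raster_interpolate <- function(raster, x, y) {
  v <- raster$values
  ny <- nrow(v); nx <- ncol(v); cs <- raster$cell_size_m
  gx <- (x - raster$origin[1]) / cs - 0.5  # 0-based fractional column
  gy <- (y - raster$origin[2]) / cs - 0.5
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  val <- function(i, j) {
    ok <- i >= 0 & i < ny & j >= 0 & j < nx
    out <- rep(NA_real_, length(i))
    out[ok] <- v[cbind(i[ok] + 1L, j[ok] + 1L)]
    out
  }
  v00 <- val(i0, j0); v01 <- val(i0, j0 + 1)
  v10 <- val(i0 + 1, j0); v11 <- val(i0 + 1, j0 + 1)
  w00 <- (1 - fx) * (1 - fy); w01 <- fx * (1 - fy)
  w10 <- (1 - fx) * fy; w11 <- fx * fy
  out <- w00 * v00 + w01 * v01 + w10 * v10 + w11 * v11
  # fallback: nearest valid neighbor among the four
  bad <- is.na(out)
  if (any(bad)) {
    cand <- cbind(v00[bad], v01[bad], v10[bad], v11[bad])
    wt <- cbind(w00[bad], w01[bad], w10[bad], w11[bad])
    wt[is.na(cand)] <- -1
    pick <- max.col(wt, ties.method = "first")
    repl <- cand[cbind(seq_len(nrow(cand)), pick)]
    out[bad] <- repl
  }
  out
}

#' Ground filter parameters
#'
#' Tuning of the deterministic grid-based ground classifier (see
#' [classify_ground()]).
#'
#' @param cell_size_m Analysis grid cell, meters.
#' @param max_slope_deg Steepest terrain slope the filter will follow,
#'   degrees.
#' @param height_tolerance_m Points within this height of the estimated
#'   ground surface are labeled ground, meters.
#' @param iterations Maximum slope-limited erosion sweeps (the filter stops
#'   earlier on convergence).
#' @return A `ground_filter_params` object.
#' @export
ground_filter_params <- function(cell_size_m = 0.5, max_slope_deg = 30,
                                 height_tolerance_m = 0.15, iterations = 50L) {
  if (any(c(cell_size_m, max_slope_deg, height_tolerance_m, iterations) <= 0))
    stop("all ground filter parameters must be positive", call. = FALSE)
  structure(list(cell_size_m = cell_size_m, max_slope_deg = max_slope_deg,
                 height_tolerance_m = height_tolerance_m,
                 iterations = as.integer(iterations)),
            class = "ground_filter_params")
}

# shift a matrix by (di, dj), padding with NA
shift_mat <- function(m, di, dj) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  si <- max(1, 1 - di):min(ny, ny - di)
  sj <- max(1, 1 - dj):min(nx, nx - dj)
  out[si + di, sj + dj] <- m[si, sj]
  out
}

#' Classify ground vs vegetation points
#'
#' A deterministic grid-based ground filter (used here in place of the cloth
#' simulation filter found in full LiDAR processing suites): per-cell minima
#' seed a candidate ground surface, empty cells are filled by neighborhood
#' interpolation, the surface is then eroded under a slope constraint until
#' convergence (which removes minima that sit on vegetation, e.g. cells that
#' only see crown returns), and finally every point within the height
#' tolerance of the interpolated surface is labeled ground, the rest
#' vegetation.
#'
#' @param cloud A non-degenerate [point_cloud()].
#' @param params A [ground_filter_params()].
#' @return The cloud with a `label` column (`"ground"`/`"vegetation"`); the
#'   estimated ground surface is attached as attribute `"ground_surface"`
#'   (a [lidar_raster()]).
#' @export
classify_ground <- function(cloud, params = ground_filter_params()) {
  stopifnot(inherits(params, "ground_filter_params"))
  if (!nrow(cloud)) stop("empty point cloud", call. = FALSE)
  rngx <- range(cloud$x); rngy <- range(cloud$y)
  if (diff(rngx) == 0 && diff(rngy) == 0)
    stop("degenerate cloud: all points at the same planimetric position",
         call. = FALSE)
  cs <- params$cell_size_m
  nx <- max(1L, as.integer(ceiling((rngx[2] - rngx[1]) / cs + 1e-9)))
  ny <- max(1L, as.integer(ceiling((rngy[2] - rngy[1]) / cs + 1e-9)))
  j <- pmin(nx, as.integer(floor((cloud$x - rngx[1]) / cs)) + 1L)
  i <- pmin(ny, as.integer(floor((cloud$y - rngy[1]) / cs)) + 1L)
  cell <- (j - 1L) * ny + i
  minz <- rep(NA_real_, nx * ny)
  agg <- tapply(cloud$z, cell, min)
  minz[as.integer(names(agg))] <- agg
  m <- matrix(minz, ny, nx)

  # fill empty cells by repeated neighbor averaging
  guard <- 0L
  while (anyNA(m) && guard < 10000L) {
    guard <- guard + 1L
    nb <- list(shift_mat(m, 1, 0), shift_mat(m, -1, 0),
               shift_mat(m, 0, 1), shift_mat(m, 0, -1))
    s <- Reduce(`+`, lapply(nb, function(a) ifelse(is.na(a), 0, a)))
    k <- Reduce(`+`, lapply(nb, function(a) !is.na(a)))
    fill <- is.na(m) & k > 0
    m[fill] <- (s / pmax(k, 1))[fill]
  }
  if (anyNA(m)) stop("could not interpolate the seed ground surface",
                     call. = FALSE)

  # slope-limited erosion: true terrain satisfies the slope bound between
  # neighboring cells and is preserved; vegetation islands get pulled down
  allow <- tan(deg2rad(params$max_slope_deg)) * cs
  for (it in seq_len(params$iterations)) {
    nb <- list(shift_mat(m, 1, 0), shift_mat(m, -1, 0),
               shift_mat(m, 0, 1), shift_mat(m, 0, -1))
    nb_min <- Reduce(pmin2_na, nb)
    m_new <- pmin(m, nb_min + allow, na.rm = TRUE)
    if (max(abs(m_new - m)) < 1e-6) { m <- m_new; break }
    m <- m_new
  }
  surface <- lidar_raster(m, c(rngx[1], rngy[1]), cs)
  g <- raster_interpolate(surface, cloud$x, cloud$y)
  lab <- ifelse(cloud$z <= g + params$height_tolerance_m, "ground",
                "vegetation")
  out <- data.table::copy(cloud)
  data.table::set(out, j = "label",
                  value = factor(lab, levels = c("ground", "vegetation",
                                                 "unclassified")))
  data.table::setattr(out, "ground_surface", surface)
  out
}

pmin2_na <- function(a, b) pmin(a, b, na.rm = TRUE)

# deterministic sub-micron jitter to break cocircular grid degeneracies in
# the triangulation; far below all stated interpolation tolerances
dt_jitter <- function(n) {
  h <- (seq_len(n) * 2654435761) %% 4096
  (h / 4096 - 0.5) * 2e-7
}

#' Digital terrain model by TIN interpolation
#'
#' Delaunay-triangulates the ground points and linearly interpolates each
#' cell center on its containing triangle; cells outside the convex hull are
#' nodata. With `thin = TRUE` (the default) the input is first reduced to
#' the lowest point per output cell, which bounds the triangulation size on
#' large clouds without changing the surface at the raster scale.
#'
#' @param ground_points A [point_cloud()] of ground points (>= 3,
#'   non-collinear). If a `label` column is present only `"ground"` rows are
#'   used.
#' @param cell_size_m Output cell size, meters.
#' @param thin Keep only the lowest point per cell before triangulating.
#' @return A [lidar_raster()] of terrain elevation.
#' @export
build_dtm <- function(ground_points, cell_size_m = 0.25, thin = TRUE) {
  pts <- ground_points
  if (!is.null(pts$label)) pts <- pts[pts$label == "ground", ]
  if (nrow(pts) < 3)
    stop("need at least 3 ground points to build a DTM", call. = FALSE)
  tin_raster(pts$x, pts$y, pts$z, cell_size_m, thin = thin, keep = "lowest")
}

# shared TIN-to-raster path for DTM and CHM
tin_raster <- function(x, y, z, cell_size_m, thin = TRUE,
                       keep = c("lowest", "highest")) {
  keep <- match.arg(keep)
  if (thin) {
    cs <- cell_size_m
    cx <- floor(x / cs); cy <- floor(y / cs)
    key <- paste(cx, cy)
    ord <- order(key, if (keep == "lowest") z else -z)
    first <- !duplicated(key[ord])
    sel <- ord[first]
    x <- x[sel]; y <- y[sel]; z <- z[sel]
  }
  if (length(x) < 3) stop("not enough distinct points for a TIN", call. = FALSE)
  xj <- x + dt_jitter(length(x))
  yj <- y + rev(dt_jitter(length(y)))
  tri <- delaunay_cpp(xj, yj)
  if (nrow(tri) == 0)
    stop("points are collinear; cannot triangulate", call. = FALSE)
  x0 <- min(x); y0 <- min(y)
  nx <- max(1L, as.integer(ceiling((max(x) - x0) / cell_size_m - 1e-9)))
  ny <- max(1L, as.integer(ceiling((max(y) - y0) / cell_size_m - 1e-9)))
  vals <- tin_rasterize_cpp(xj, yj, z, tri, x0, y0, cell_size_m, nx, ny)
  lidar_raster(vals, c(x0, y0), cell_size_m)
}

#' Normalize a cloud by a terrain model
#'
#' Subtracts the interpolated terrain elevation from every point, turning
#' elevations into heights above ground; ground points map to approximately
#' zero. Points falling outside the DTM's interpolated area are dropped and
#' counted (attribute `"n_dropped"`).
#'
#' @param cloud A [point_cloud()].
#' @param dtm A [lidar_raster()] from [build_dtm()].
#' @return The normalized [point_cloud()] (original elevation kept in
#'   column `z_abs`).
#' @export
normalize_height <- function(cloud, dtm) {
  stopifnot(inherits(dtm, "lidar_raster"))
  g <- raster_interpolate(dtm, cloud$x, cloud$y)
  keep <- !is.na(g)
  if (!any(keep))
    stop("no overlap between the cloud and the terrain model", call. = FALSE)
  out <- data.table::copy(cloud)[keep, ]
  data.table::set(out, j = "z_abs", value = out$z)
  data.table::set(out, j = "z", value = out$z - g[keep])
  data.table::setattr(out, "n_dropped", sum(!keep))
  out
}

#' Canopy height model
#'
#' Selects the highest point per cell, builds a TIN over those apex points
#' and linearly interpolates every cell center; empty cells inside the hull
#' are filled by the interpolation. Input must be a height-normalized cloud;
#' if a `label` column is present only vegetation points are used.
#'
#' @param normalized_cloud A [point_cloud()] from [normalize_height()].
#' @param cell_size_m Output cell size, meters.
#' @return A [lidar_raster()] of canopy height above ground.
#' @export
build_chm <- function(normalized_cloud, cell_size_m = 0.25) {
  pts <- normalized_cloud
  if (!is.null(pts$label)) pts <- pts[pts$label == "vegetation", ]
  if (!nrow(pts))
    stop("no vegetation points; cannot build a CHM", call. = FALSE)
  tin_raster(pts$x, pts$y, pts$z, cell_size_m, thin = TRUE, keep = "highest")
}

#' Estimate tree heights from a CHM
#'
#' Reads, for each tree position, the maximum canopy height within a search
#' radius - the standard plot-level height extraction when stem positions
#' are known.
#'
#' @param chm A [lidar_raster()] from [build_chm()].
#' @param positions A data.frame with columns `x`, `y` (meters), one row per
#'   tree.
#' @param search_radius_m Neighborhood radius, meters.
#' @return Numeric vector of heights (meters), one per position.
#' @export
estimate_tree_heights <- function(chm, positions, search_radius_m = 2) {
  stopifnot(inherits(chm, "lidar_raster"),
            all(c("x", "y") %in% names(positions)))
  v <- chm$values
  ny <- nrow(v); nx <- ncol(v); cs <- chm$cell_size_m
  cx <- chm$origin[1] + (seq_len(nx) - 0.5) * cs
  cy <- chm$origin[2] + (seq_len(ny) - 0.5) * cs
  vapply(seq_len(nrow(positions)), function(k) {
    px <- positions$x[k]; py <- positions$y[k]
    if (px < chm$origin[1] || px > chm$origin[1] + nx * cs ||
        py < chm$origin[2] || py > chm$origin[2] + ny * cs)
      stop(sprintf("tree position (%.2f, %.2f) is outside the raster", px, py),
           call. = FALSE)
    jj <- which(abs(cx - px) <= search_radius_m)
    ii <- which(abs(cy - py) <= search_radius_m)
    sub <- v[ii, jj, drop = FALSE]
    d2 <- outer((cy[ii] - py)^2, (cx[jj] - px)^2, `+`)
    vals <- sub[d2 <= search_radius_m^2 & !is.na(sub)]
    if (!length(vals))
      stop(sprintf("no canopy data within %.2f m of (%.2f, %.2f)",
                   search_radius_m, px, py), call. = FALSE)
    max(vals)
  }, numeric(1))
}

#' Read and write ESRI ASCII rasters
#'
#' The plain-text grid dialect (`NCOLS`/`NROWS`/`XLLCORNER`/`YLLCORNER`/
#' `CELLSIZE`/`NODATA_VALUE` header, rows north to south).
#'
#' @param raster A [lidar_raster()].
#' @param path File path.
#' @param digits Decimal places written.
#' @return `write_esri_ascii()` returns `path` invisibly; `read_esri_ascii()`
#'   a [lidar_raster()].
#' @export
write_esri_ascii <- function(raster, path, digits = 3) {
  stopifnot(inherits(raster, "lidar_raster"))
  v <- raster$values
  hdr <- c(sprintf("NCOLS %d", ncol(v)), sprintf("NROWS %d", nrow(v)),
           sprintf("XLLCORNER %.6f", raster$origin[1]),
           sprintf("YLLCORNER %.6f", raster$origin[2]),
           sprintf("CELLSIZE %.6f", raster$cell_size_m),
           "NODATA_VALUE -9999")
  rows <- vapply(rev(seq_len(nrow(v))), function(i) {
    r <- v[i, ]
    r[is.na(r)] <- -9999
    paste(formatC(r, format = "f", digits = digits), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (k in 1:6) {
    parts <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII raster (missing header fields): ", path,
         call. = FALSE)
  nodata <- hdr[["NODATA_VALUE"]] %||% -9999
  body <- lines[7:(6 + hdr$NROWS)]
  v <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (ncol(v) != hdr$NCOLS || nrow(v) != hdr$NROWS)
    stop("raster body does not match header dimensions: ", path, call. = FALSE)
  v[v == nodata] <- NA
  lidar_raster(v[rev(seq_len(nrow(v))), , drop = FALSE],
               c(hdr$XLLCORNER, hdr$YLLCORNER), hdr$CELLSIZE)
}

#' Run the full product chain
#'
#' Ground classification, DTM, height normalization and CHM in one call -
#' the standard processing sequence from a merged point cloud to vegetation
#' structure rasters.
#'
#' @param cloud A [point_cloud()].
#' @param ground_params A [ground_filter_params()].
#' @param dtm_cell_m,chm_cell_m Raster cell sizes, meters.
#' @return A list with `classified` (labeled cloud), `dtm`, `normalized`
#'   (height-normalized cloud) and `chm`.
#' @export
process_cloud <- function(cloud, ground_params = ground_filter_params(),
                          dtm_cell_m = 0.25, chm_cell_m = 0.25) {
  classified <- classify_ground(cloud, ground_params)
  dtm <- build_dtm(classified, cell_size_m = dtm_cell_m)
  normalized <- normalize_height(classified, dtm)
  chm <- build_chm(normalized, cell_size_m = chm_cell_m)
  list(classified = classified, dtm = dtm, normalized = normalized, chm = chm)
}
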