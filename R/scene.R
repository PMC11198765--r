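#' Synthetic scene: terrain surface plus tree primitives
#'
#' A virtual world for the scan simulator. The terrain is a continuous
#' surface z = f(x, y) - either a sloped plane or a sum of Gaussian hills -
#' and the vegetation is a set of tree primitives (vertical trunk cylinder
#' topped by an ellipsoid or cone crown). This mimics the structure of the
#' kind of demonstration site such scanners are used on: irregular ground
#' and trees, with no understorey.
#'
#' @param terrain A terrain description from [terrain_plane()] or
#'   [terrain_hills()].
#' @param trees A data.frame of tree primitives from [tree_primitive()]
#'   (rows can be `rbind`ed); may be empty.
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)` in meters.
#' @return A `scene` object.
#' @export
scene <- function(terrain = terrain_plane(), trees = NULL,
                  extent = c(-20, 20, -20, 20)) {
  stopifnot(inherits(terrain, "terrain"), length(extent) == 4,
            extent[1] < extent[2], extent[3] < extent[4])
  if (is.null(trees)) trees <- empty_trees()
  stopifnot(is.data.frame(trees))
  if (nrow(trees) > 0) {
    inside <- trees$x >= extent[1] & trees$x <= extent[2] &
      trees$y >= extent[3] & trees$y <= extent[4]
    if (!all(inside)) stop("all trees must lie inside the extent", call. = FALSE)
    # anchor each tree's base on the terrain
    trees$base_z <- terrain_height(terrain, trees$x, trees$y)
  }
  structure(list(terrain = terrain, trees = trees, extent = as.numeric(extent)),
            class = "scene")
}

#' Planar terrain
#'
#' z = z0 + sx * x + sy * y.
#'
#' @param z0 Elevation at the origin, meters.
#' @param sx,sy Slopes (dz/dx, dz/dy), dimensionless.
#' @return A `terrain` object.
#' @export
terrain_plane <- function(z0 = 0, sx = 0, sy = 0) {
  structure(list(type = "plane", z0 = z0, sx = sx, sy = sy), class = "terrain")
}

#' Undulating terrain from Gaussian hills
#'
#' z = z0 + sum of amp_i * exp(-((x-x_i)^2 + (y-y_i)^2) / (2 sigma_i^2)).
#'
#' @param z0 Base elevation, meters.
#' @param hills A data.frame with columns `x`, `y`, `amp`, `sigma` (meters).
#' @return A `terrain` object.
#' @export
terrain_hills <- function(z0 = 0,
                          hills = data.frame(x = 0, y = 0, amp = 0.5, sigma = 5)) {
  stopifnot(all(c("x", "y", "amp", "sigma") %in% names(hills)),
            all(hills$sigma > 0))
  structure(list(type = "gaussians", z0 = z0, hills = hills), class = "terrain")
}

#' Evaluate the terrain surface
#'
#' @param terrain A `terrain` object.
#' @param x,y Coordinates in meters (vectorized).
#' @return Elevation(s) in meters.
#' @export
terrain_height <- function(terrain, x, y) {
  stopifnot(inherits(terrain, "terrain"))
  if (terrain$type == "plane") {
    terrain$z0 + terrain$sx * x + terrain$sy * y
  } else {
    z <- rep(terrain$z0, length.out = max(length(x), length(y)))
    for (i in seq_len(nrow(terrain$hills))) {
      h <- terrain$hills[i, ]
      z <- z + h$amp * exp(-((x - h$x)^2 + (y - h$y)^2) / (2 * h$sigma^2))
    }
    z
  }
}

# conservative elevation bounds over the extent, used to clip ray marching
terrain_band <- function(terrain) {
  if (terrain$type == "plane") NULL  # computed from extent corners at call time
  else {
    amps <- terrain$hills$amp
    c(terrain$z0 + sum(pmin(amps, 0)), terrain$z0 + sum(pmax(amps, 0)))
  }
}

#' Tree primitive
#'
#' A vertical trunk cylinder topped by a crown: an ellipsoid of revolution
#' (horizontal semi-axis `crown_radius_m`, vertical semi-axis
#' `(total_height_m - trunk_height_m) / 2`) or a cone with its apex at the
#' tree top and base radius `crown_radius_m` at the trunk top. Heights are
#' measured from the terrain at the tree base.
#'
#' @param x,y Base position, meters.
#' @param total_height_m Tree top height above its base.
#' @param trunk_height_m Height of the bare trunk (crown base).
#' @param trunk_radius_m Trunk radius, meters.
#' @param crown_radius_m Maximum crown radius, meters.
#' @param crown `"ellipsoid"` or `"cone"`.
#' @param crown_extinction_per_m Foliage extinction coefficient of the crown
#'   volume (per meter). `Inf` (the default) makes the crown an opaque
#'   surface; finite values make it a porous Beer-Lambert medium, as real
#'   foliage is to a laser: a ray traversing a chord of length L passes
#'   through with probability exp(-k L), and a registered return is drawn
#'   from the corresponding exponential depth. Typical broadleaf crowns have
#'   k around 0.5-1 per meter.
#' @return A one-row data.frame; rows from several calls can be `rbind`ed
#'   and passed to [scene()].
#' @export
tree_primitive <- function(x, y, total_height_m, trunk_height_m = 0.35 * total_height_m,
                           trunk_radius_m = 0.15, crown_radius_m = 2,
                           crown = c("ellipsoid", "cone"),
                           crown_extinction_per_m = Inf) {
  crown <- match.arg(crown)
  if (any(c(total_height_m, trunk_height_m, trunk_radius_m, crown_radius_m) <= 0))
    stop("tree dimensions must be positive", call. = FALSE)
  if (total_height_m < trunk_height_m)
    stop("total_height_m must be >= trunk_height_m", call. = FALSE)
  if (crown_extinction_per_m <= 0)
    stop("crown_extinction_per_m must be positive (Inf = opaque)",
         call. = FALSE)
  data.frame(x = x, y = y, base_z = 0,
             trunk_radius_m = trunk_radius_m, trunk_height_m = trunk_height_m,
             total_height_m = total_height_m, crown_radius_m = crown_radius_m,
             crown = crown, crown_extinction_per_m = crown_extinction_per_m,
             stringsAsFactors = FALSE)
}

empty_trees <- function() {
  tree_primitive(0, 0, 1)[0, ]
}

#' Demonstration scene generator
#'
#' A reproducible synthetic vegetation patch: gently undulating terrain
#' (Gaussian hills, amplitude within +/-1 m), scattered trees with
#' ellipsoid crowns, no understorey - the structure of a small campus
#' woodland plot. The ground-truth tree table (positions and heights) is
#' attached as attribute `"trees"` for recovery experiments.
#'
#' @param seed Integer seed; the scene is a pure function of it.
#' @param n_trees Number of trees (>= 0).
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)`; default a
#'   25 m x 25 m patch centered on the origin.
#' @param clearing_radius_m Trees are kept at least this far from the origin
#'   so a tripod can stand at the patch center.
#' @return A [scene()]; `attr(, "trees")` holds the truth table with columns
#'   `id`, `x`, `y`, `height_m`.
#' @export
#' @examples
#' sc <- make_demo_scene(seed = 1, n_trees = 7)
#' attr(sc, "trees")
make_demo_scene <- function(seed = 1L, n_trees = 7L,
                            extent = c(-12.5, 12.5, -12.5, 12.5),
                            clearing_radius_m = 4) {
  if (n_trees < 0) stop("n_trees must be >= 0", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  # irregular soil: a handful of broad hills, net amplitude below 1 m
  n_h <- 6L
  hills <- data.frame(
    x = stats::runif(n_h, extent[1], extent[2]),
    y = stats::runif(n_h, extent[3], extent[4]),
    amp = stats::runif(n_h, -0.45, 0.45),
    sigma = stats::runif(n_h, 4, 9))
  terr <- terrain_hills(z0 = 0, hills = hills)
  trees <- empty_trees()
  if (n_trees > 0) {
    xs <- numeric(0); ys <- numeric(0)
    margin <- 1.5; min_spacing <- 4
    tries <- 0L
    while (length(xs) < n_trees && tries < 20000L) {
      tries <- tries + 1L
      px <- stats::runif(1, extent[1] + margin, extent[2] - margin)
      py <- stats::runif(1, extent[3] + margin, extent[4] - margin)
      if (sqrt(px^2 + py^2) < clearing_radius_m) next
      if (length(xs) && min(sqrt((xs - px)^2 + (ys - py)^2)) < min_spacing) next
      xs <- c(xs, px); ys <- c(ys, py)
    }
    if (length(xs) < n_trees)
      stop("could not place ", n_trees, " trees with the requested spacing",
           call. = FALSE)
    h <- stats::runif(n_trees, 6, 14)
    # moderately open stand with near-isometric crowns: crown depth
    # 0.35-0.5 of height, crown diameter 0.3-0.44 of height; broad enough
    # to be realistic, open enough that individual trees stay resolvable
    trees <- do.call(rbind, lapply(seq_len(n_trees), function(i) {
      tree_primitive(xs[i], ys[i], total_height_m = h[i],
                     trunk_height_m = stats::runif(1, 0.5, 0.65) * h[i],
                     trunk_radius_m = stats::runif(1, 0.10, 0.25),
                     crown_radius_m = stats::runif(1, 0.15, 0.22) * h[i],
                     crown = "ellipsoid", crown_extinction_per_m = 0.7)
    }))
  }
  sc <- scene(terrain = terr, trees = trees, extent = extent)
  truth <- if (nrow(sc$trees)) {
    data.frame(id = seq_len(nrow(sc$trees)), x = sc$trees$x, y = sc$trees$y,
               height_m = sc$trees$total_height_m)
  } else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    height_m = numeric(0))
  attr(sc, "trees") <- truth
  attr(sc, "seed") <- as.integer(seed)
  sc
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s terrain, %d tree(s), extent [%g, %g] x [%g, %g] m\n",
              x$terrain$type, nrow(x$trees),
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  invisible(x)
}

# run code under a private RNG stream; returns the restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
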