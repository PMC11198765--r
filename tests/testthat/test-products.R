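test_that("a flat-plane-only cloud is labeled entirely ground", {
  set.seed(21)
  pts <- point_cloud(data.frame(x = runif(3000, -10, 10),
                                y = runif(3000, -10, 10), z = 0))
  cls <- classify_ground(pts)
  expect_true(all(cls$label == "ground"))
})

test_that("points well above the surface are labeled vegetation", {
  set.seed(22)
  n <- 3000
  ground <- data.frame(x = runif(n, -10, 10), y = runif(n, -10, 10), z = 0)
  canopy <- data.frame(x = runif(500, -5, 5), y = runif(500, -5, 5), z = 2)
  cls <- classify_ground(point_cloud(rbind(ground, canopy)))
  expect_true(all(cls$label[cls$z == 2] == "vegetation"))
  expect_true(all(cls$label[cls$z == 0] == "ground"))
})

test_that("degenerate clouds are rejected by the ground filter", {
  pts <- point_cloud(data.frame(x = rep(1, 10), y = rep(2, 10), z = 1:10))
  expect_error(classify_ground(pts), "degenerate")
  expect_error(classify_ground(point_cloud()), "empty")
})

test_that("TIN interpolation reproduces any linear surface exactly", {
  # three points defining z = x: every in-hull cell equals its x coordinate
  tri_pts <- point_cloud(data.frame(x = c(0, 10, 0), y = c(0, 0, 10),
                                    z = c(0, 10, 0)))
  dtm <- build_dtm(tri_pts, cell_size_m = 0.5, thin = FALSE)
  v <- dtm$values
  cx <- dtm$origin[1] + (seq_len(ncol(v)) - 0.5) * dtm$cell_size_m
  xs <- matrix(cx, nrow(v), ncol(v), byrow = TRUE)
  inside <- !is.na(v)
  expect_gt(sum(inside), 50)
  expect_lt(max(abs(v[inside] - xs[inside])), 1e-6)
  # a richer scattered sample of another plane
  set.seed(23)
  xy <- data.frame(x = runif(400, 0, 20), y = runif(400, 0, 20))
  p2 <- point_cloud(cbind(xy, z = 1 + 0.2 * xy$x - 0.1 * xy$y))
  dtm2 <- build_dtm(p2, cell_size_m = 0.5, thin = FALSE)
  v2 <- dtm2$values
  cx2 <- dtm2$origin[1] + (seq_len(ncol(v2)) - 0.5) * 0.5
  cy2 <- dtm2$origin[2] + (seq_len(nrow(v2)) - 0.5) * 0.5
  want <- 1 + 0.2 * matrix(cx2, nrow(v2), ncol(v2), byrow = TRUE) -
    0.1 * matrix(cy2, nrow(v2), ncol(v2))
  ok <- !is.na(v2)
  expect_lt(max(abs(v2[ok] - want[ok])), 1e-6)
})

test_that("cells outside the convex hull are nodata and few points trigger errors", {
  tri_pts <- point_cloud(data.frame(x = c(0, 10, 0), y = c(0, 0, 10),
                                    z = c(0, 0, 0)))
  dtm <- build_dtm(tri_pts, cell_size_m = 0.5, thin = FALSE)
  # the far corner of the bounding box lies outside the triangle
  expect_true(is.na(dtm$values[nrow(dtm$values), ncol(dtm$values)]))
  expect_error(build_dtm(point_cloud(data.frame(x = 1:2, y = 1:2, z = 0))),
               "at least 3")
  collinear <- point_cloud(data.frame(x = 1:10, y = 1:10, z = 0))
  expect_error(build_dtm(collinear, thin = FALSE), "collinear")
})

test_that("a noiseless simulated flat terrain yields a centimeter-accurate DTM", {
  cfg <- tiny_config()
  raw <- simulate_scan(cfg, flat_scene(), position = c(0, 0, 1.5), noise = NULL)
  cloud <- reconstruct(raw)
  dtm <- build_dtm(cloud, cell_size_m = 0.5)
  expect_lt(max(abs(dtm$values), na.rm = TRUE), 0.01)
})

test_that("height normalization zeroes the ground and preserves offsets", {
  set.seed(24)
  n <- 2000
  gx <- runif(n, 0, 20); gy <- runif(n, 0, 20)
  ground <- data.frame(x = gx, y = gy, z = 0.5 + 0.1 * gx)
  dtm <- build_dtm(point_cloud(ground), cell_size_m = 0.5, thin = FALSE)
  # a point 5 m above the sloped terrain normalizes to 5
  probe <- point_cloud(data.frame(x = 10, y = 10, z = 0.5 + 1 + 5))
  norm <- normalize_height(probe, dtm)
  expect_equal(norm$z, 5, tolerance = 0.02)
  # ground points themselves map to ~0
  norm_g <- normalize_height(point_cloud(ground), dtm)
  expect_lt(mean(abs(norm_g$z)), 0.01)
  # points outside the hull are dropped and counted
  far <- point_cloud(data.frame(x = c(10, 500), y = c(10, 500), z = c(2, 2)))
  norm_f <- normalize_height(far, dtm)
  expect_equal(nrow(norm_f), 1L)
  expect_equal(attr(norm_f, "n_dropped"), 1L)
  expect_error(normalize_height(point_cloud(data.frame(x = 500, y = 500, z = 0)),
                                dtm), "no overlap")
})

test_that("the CHM reproduces a uniform canopy slab", {
  set.seed(25)
  n <- 4000
  slab <- point_cloud(data.frame(x = runif(n, 0, 20), y = runif(n, 0, 20),
                                 z = 3))
  chm <- build_chm(slab, cell_size_m = 0.5)
  expect_lt(max(abs(chm$values - 3), na.rm = TRUE), 0.01)
  expect_error(build_chm(slab[0, ]), "no vegetation")
})

test_that("canopy height is non-negative over terrain-bottomed scenes", {
  sc <- make_demo_scene(seed = 26, n_trees = 3)
  cfg <- tiny_config(tilt_start_deg = -60, tilt_end_deg = 60)
  raw <- simulate_scan(cfg, sc, scanner_position(sc),
                       noise = noise_from_rangefinder(seed = 26))
  res <- process_cloud(reconstruct(raw), dtm_cell_m = 0.5, chm_cell_m = 0.5)
  expect_gt(min(res$chm$values, na.rm = TRUE), -0.2)
})

test_that("tree height extraction reads the CHM maximum near each stem", {
  v <- matrix(0, 20, 20)
  v[10, 10] <- 12.3
  chm <- lidar_raster(v, origin = c(0, 0), cell_size_m = 1)
  pos <- data.frame(x = 9.5, y = 9.5)
  expect_equal(estimate_tree_heights(chm, pos, search_radius_m = 2), 12.3)
  expect_error(estimate_tree_heights(chm, data.frame(x = 50, y = 5), 2),
               "outside the raster")
  v2 <- matrix(NA_real_, 20, 20); v2[1, 1] <- 1
  chm2 <- lidar_raster(v2, c(0, 0), 1)
  expect_error(estimate_tree_heights(chm2, data.frame(x = 15, y = 15), 2),
               "no canopy data")
})

test_that("ESRI ASCII rasters round-trip with orientation preserved", {
  v <- matrix(seq_len(12) / 7, nrow = 3)
  v[2, 2] <- NA
  r <- lidar_raster(v, origin = c(100, 200), cell_size_m = 0.25)
  f <- withr::local_tempfile(fileext = ".asc")
  write_esri_ascii(r, f, digits = 6)
  back <- read_esri_ascii(f)
  expect_equal(back$origin, r$origin)
  expect_equal(back$cell_size_m, r$cell_size_m)
  expect_equal(back$values, r$values, tolerance = 1e-6)
})
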