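test_that("reconstruction preserves count, order and time", {
  raw <- data.table::data.table(time_ms = 0, bearing_deg = 0, tilt_deg = 0,
                                distance_m = 10)
  cloud <- reconstruct(raw)
  expect_equal(nrow(cloud), 1L)
  expect_equal(unlist(cloud[1, c("x", "y", "z")]), c(x = 0, y = 10, z = 0))
  expect_equal(cloud$t_ms, 0)

  cfg <- tiny_config()
  sim <- simulate_scan(cfg, flat_scene(), position = c(0, 0, 1.5), noise = NULL)
  rec <- reconstruct(sim)
  expect_equal(nrow(rec), nrow(sim))
  expect_identical(rec$t_ms, sim$time_ms)
})

test_that("records beyond the rangefinder's reach are rejected", {
  raw <- data.table::data.table(time_ms = c(0, 3.3), bearing_deg = 0,
                                tilt_deg = 0, distance_m = c(10, 55))
  expect_error(reconstruct(raw, max_range_m = 40), "record 2")
})

test_that("reconstruction honors the mount offset it is given", {
  raw <- data.table::data.table(time_ms = 0, bearing_deg = 0, tilt_deg = 0,
                                distance_m = 10)
  off <- offset_spec(lateral_m = 0.05)
  cloud <- reconstruct(raw, offset = off)
  expect_equal(cloud$x, 0.05)
})

test_that("merging with identity transforms is exact concatenation", {
  pts <- point_cloud(data.frame(x = 1:10, y = 0, z = 0))
  m <- merge_clouds(list(pts, pts))
  expect_equal(nrow(m), 20L)
  expect_equal(m$x, rep(1:10, 2))
  expect_equal(m$scan_id, rep(1:2, each = 10))
  expect_equal(nrow(merge_clouds(list())), 0L)
  expect_error(merge_clouds(list(pts), list(rigid_transform(), rigid_transform())),
               "same length")
})

test_that("merged grid scans add their counts", {
  sc <- make_demo_scene(seed = 8, n_trees = 2)
  cfg <- tiny_config()
  offs <- list(c(-2.5, -2.5), c(2.5, -2.5), c(-2.5, 2.5), c(2.5, 2.5))
  clouds <- lapply(seq_along(offs), function(i) {
    p <- offs[[i]]
    reconstruct(simulate_scan(cfg, sc, scanner_position(sc, p[1], p[2]),
                              noise = noise_from_rangefinder(seed = i)))
  })
  merged <- merge_clouds(clouds)
  expect_equal(nrow(merged), sum(vapply(clouds, nrow, numeric(1))))
})

test_that("a rigid transform composed with its inverse is the identity", {
  set.seed(12)
  pts <- point_cloud(data.frame(x = runif(500, -20, 20),
                                y = runif(500, -20, 20),
                                z = runif(500, -5, 25)))
  tf <- rigid_transform(rotation_deg = 37.5, dx = 4.2, dy = -1.1, dz = 0.6)
  back <- apply_transform(apply_transform(pts, tf), invert_transform(tf))
  expect_cloud_equal(back, pts, tol = 1e-9)
})

test_that("ASCII XYZ round trip is exact at the printed precision", {
  set.seed(13)
  pts <- point_cloud(data.frame(x = runif(1000, -40, 40),
                                y = runif(1000, -40, 40),
                                z = runif(1000, -2, 30),
                                t_ms = seq(0, by = 3.3, length.out = 1000)))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(pts, f)
  back <- read_xyz(f)
  expect_equal(nrow(back), 1000L)
  expect_lt(max(abs(back$x - pts$x)), 5.001e-4)
  expect_lt(max(abs(back$z - pts$z)), 5.001e-4)
  expect_lt(max(abs(back$t_ms - pts$t_ms)), 0.051)
  # not silently accepting garbage
  writeLines(c("1 2 3", "4 five 6"), f)
  expect_error(read_xyz(f), "XYZ")
})

test_that("LAS round trip is exact to half the millimeter scale", {
  set.seed(14)
  pts <- point_cloud(data.frame(x = runif(1000, -40, 40),
                                y = runif(1000, -40, 40),
                                z = runif(1000, -2, 30),
                                t_ms = seq(0, by = 3.3, length.out = 1000),
                                label = sample(c("ground", "vegetation"), 1000,
                                               replace = TRUE)))
  f <- withr::local_tempfile(fileext = ".las")
  write_las(pts, f)
  back <- read_las(f)
  expect_equal(nrow(back), 1000L)
  expect_lt(max(abs(back$x - pts$x)), 5e-4 + 1e-12)
  expect_lt(max(abs(back$y - pts$y)), 5e-4 + 1e-12)
  expect_lt(max(abs(back$z - pts$z)), 5e-4 + 1e-12)
  expect_equal(back$t_ms, pts$t_ms, tolerance = 1e-9)
  expect_equal(as.character(back$label), as.character(pts$label))
})

test_that("a truncated LAS file errors instead of partially succeeding", {
  pts <- point_cloud(data.frame(x = 1:100 / 10, y = 0, z = 0))
  f <- withr::local_tempfile(fileext = ".las")
  write_las(pts, f)
  full <- readBin(f, "raw", file.size(f))
  writeBin(full[1:(length(full) - 100)], f)
  expect_error(read_las(f), "truncated")
  writeBin(as.raw(1:100), f)
  expect_error(read_las(f), "signature")
})
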