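test_that("ray casting hits terrain, trunks, and respects the range cap", {
  sc <- flat_scene()
  # straight down from 1.5 m
  r <- ray_cast(c(0, 0, 1.5), c(0, 0, -1), sc)
  expect_equal(r$distance_m, 1.5, tolerance = 1e-9)
  expect_equal(as.character(r$hit), "terrain")
  # horizontal ray into a 0.2 m trunk centered 10 m due north
  r2 <- ray_cast(c(0, 0, 1.5), c(0, 1, 0), one_tree_scene())
  expect_equal(r2$distance_m, 9.8, tolerance = 1e-9)
  expect_equal(as.character(r2$hit), "trunk")
  # nothing within range: a miss is a value, not an error
  r3 <- ray_cast(c(0, 0, 1.5), c(0, 1, 0), sc, max_range_m = 40)
  expect_true(is.na(r3$distance_m))
  expect_true(is.na(r3$hit))
})

test_that("ray marching agrees with the closed-form planar intersection", {
  sc <- scene(terrain_plane(z0 = 0.3, sx = 0.05, sy = -0.02))
  set.seed(3)
  n <- 300
  dirs <- as.matrix(to_cartesian(runif(n, 0, 360), runif(n, -80, -5), 1))
  org <- matrix(rep(c(0, 0, 1.7), each = n), ncol = 3)
  closed <- ray_cast(org, dirs, sc, force_march = FALSE)$distance_m
  marched <- ray_cast(org, dirs, sc, force_march = TRUE)$distance_m
  ok <- !is.na(closed)
  expect_true(any(ok))
  expect_equal(is.na(closed), is.na(marched))
  expect_lt(max(abs(closed[ok] - marched[ok])), 1e-3)
})

test_that("every scheduled pulse is either a hit or a miss", {
  cfg <- tiny_config(tilt_start_deg = -60, tilt_end_deg = 40)
  raw <- simulate_scan(cfg, flat_scene(), position = c(0, 0, 1.5),
                       noise = NULL)
  expect_equal(nrow(raw) + attr(raw, "n_misses"), total_points(cfg))
  expect_equal(attr(raw, "n_pulses"), total_points(cfg))
  # keep_misses retains the full pulse count with the -1 sentinel
  raw2 <- simulate_scan(cfg, flat_scene(), position = c(0, 0, 1.5),
                        noise = NULL, keep_misses = TRUE)
  expect_equal(nrow(raw2), total_points(cfg))
  expect_equal(sum(raw2$distance_m == -1), attr(raw, "n_misses"))
})

test_that("a noiseless scan of a flat plane reconstructs it to within quantization", {
  cfg <- tiny_config()  # tilt entirely below the horizon
  raw <- simulate_scan(cfg, flat_scene(), position = c(0, 0, 1.5), noise = NULL)
  expect_gt(nrow(raw), 1000)
  cloud <- reconstruct(raw)  # absolute frame: the plane lies at z = 0
  expect_lt(max(abs(cloud$z)), 0.005 + 1e-6)
})

test_that("enlarging the range cap never loses hits", {
  cfg <- tiny_config(tilt_start_deg = -20, tilt_end_deg = 20)
  sc <- flat_scene()
  sch <- build_schedule(cfg)
  o <- matrix(rep(c(0, 0, 1.5), each = nrow(sch)), ncol = 3)
  d <- as.matrix(to_cartesian(sch$bearing_deg, sch$tilt_deg, 1))
  hits <- vapply(c(10, 20, 40), function(mr)
    sum(!is.na(ray_cast(o, d, sc, max_range_m = mr)$distance_m)), numeric(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("simulated scans are reproducible from the seed", {
  cfg <- tiny_config()
  sc <- make_demo_scene(seed = 5, n_trees = 3)
  pos <- scanner_position(sc)
  a <- simulate_scan(cfg, sc, pos, noise = noise_from_rangefinder(seed = 9))
  b <- simulate_scan(cfg, sc, pos, noise = noise_from_rangefinder(seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_scan(cfg, sc, pos, noise = noise_from_rangefinder(seed = 10))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("the measurement error model reproduces its configured spread", {
  nm <- noise_model(seed = 11)
  set.seed(11)
  meas_far <- panoscan:::apply_noise(rep(10, 1e4), nm)
  expect_lt(abs(sd(meas_far - 10) / nm$sd_far_m - 1), 0.05)
  meas_near <- panoscan:::apply_noise(rep(1.5, 1e4), nm)
  expect_lt(abs(sd(meas_near - 1.5) / nm$sd_near_m - 1), 0.05)
  # quantization: every measured distance is a whole centimeter
  expect_true(all(abs(meas_far / 0.01 - round(meas_far / 0.01)) < 1e-9))
})

test_that("porous crowns attenuate rather than block rays", {
  mk <- function(k) scene(terrain_plane(),
                          trees = tree_primitive(0, 10, total_height_m = 8,
                                                 trunk_height_m = 3,
                                                 crown_radius_m = 2,
                                                 crown_extinction_per_m = k))
  # aim through the crown center: opaque always returns the surface
  org <- matrix(rep(c(0, 0, 1.5), each = 500), ncol = 3)
  aim <- to_cartesian(0, from_cartesian(0, 10, 5.5 - 1.5)$tilt_deg, 1)
  dir <- matrix(rep(as.numeric(aim), each = 500), ncol = 3)
  opaque <- ray_cast(org, dir, mk(Inf), seed = 1)$distance_m
  expect_equal(length(unique(opaque)), 1L)
  porous <- ray_cast(org, dir, mk(0.05), seed = 1)$distance_m
  # weak extinction: a good share of the 500 identical pulses passes through
  expect_gt(sum(is.na(porous) | porous > max(opaque) + 1), 100)
  # returns never occur before the crown surface
  expect_true(all(porous >= min(opaque) - 1e-9, na.rm = TRUE))
})

test_that("demo scenes are reproducible and carry their truth table", {
  a <- make_demo_scene(seed = 3, n_trees = 7)
  b <- make_demo_scene(seed = 3, n_trees = 7)
  expect_identical(a$trees, b$trees)
  expect_identical(a$terrain, b$terrain)
  expect_equal(nrow(attr(a, "trees")), 7L)
  expect_true(all(attr(a, "trees")$height_m > 0))
  bare <- make_demo_scene(seed = 3, n_trees = 0)
  expect_equal(nrow(bare$trees), 0L)
  # terrain undulation stays within a meter of datum
  g <- expand.grid(x = seq(-12, 12, by = 0.5), y = seq(-12, 12, by = 0.5))
  expect_lt(max(abs(terrain_height(a$terrain, g$x, g$y))), 1)
})

test_that("raw scan files round-trip through the canonical text format", {
  cfg <- tiny_config()
  sc <- make_demo_scene(seed = 2, n_trees = 2)
  raw <- simulate_scan(cfg, sc, scanner_position(sc),
                       noise = noise_from_rangefinder(seed = 4))
  f <- withr::local_tempfile(fileext = ".txt")
  write_raw_scan(raw, f)
  expect_identical(readLines(f, n = 1), "time_ms\tbearing_deg\ttilt_deg\tdistance_m")
  back <- read_raw_scan(f)
  expect_equal(nrow(back), nrow(raw))
  expect_lt(max(abs(back$time_ms - raw$time_ms)), 0.051)
  expect_lt(max(abs(back$bearing_deg - raw$bearing_deg)), 5.1e-5)
  expect_lt(max(abs(back$distance_m - raw$distance_m)), 5.1e-3)
})

test_that("malformed raw scan files are rejected with a line reference", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("time_ms\tbearing_deg\ttilt_deg\tdistance_m",
               "0.0\t0.0000\t0.0000\t5.00",
               "3.3\t0.1500\tbroken\t5.00"), f)
  expect_error(read_raw_scan(f), "line 3")
  writeLines(c("x y z"), f)
  expect_error(read_raw_scan(f), "not a raw scan file")
})

test_that("the scanner must stand above the terrain", {
  expect_error(simulate_scan(tiny_config(), flat_scene(),
                             position = c(0, 0, -0.5), noise = NULL),
               "below the terrain")
})

test_that("laser footprint grows linearly with range", {
  expect_equal(footprint_m(10), 0.08)
  expect_equal(footprint_m(c(0, 40)), c(0, 0.32))
  expect_error(footprint_m(-1), ">= 0")
})
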