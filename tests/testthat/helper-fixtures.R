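# Small configurations and scenes shared across the suite.

# coarse instrument: 200 pts/rev, 1.8 deg tilt steps -- fast to simulate
tiny_config <- function(tilt_start_deg = -60, tilt_end_deg = -20, ...) {
  default_scanner_config(pan_microstep = 1, tilt_microstep = 1,
                         step_duration_s = 1 / 300,
                         tilt_start_deg = tilt_start_deg,
                         tilt_end_deg = tilt_end_deg, ...)
}

flat_scene <- function(z0 = 0) scene(terrain_plane(z0 = z0))

# a single opaque tree on flat ground, for exact-geometry checks
one_tree_scene <- function(x = 0, y = 10, trunk_radius_m = 0.2) {
  scene(terrain_plane(),
        trees = tree_primitive(x, y, total_height_m = 5, trunk_height_m = 3,
                               trunk_radius_m = trunk_radius_m,
                               crown_radius_m = 1.5))
}

expect_cloud_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z)), tol)
}
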