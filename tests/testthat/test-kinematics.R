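test_that("angular resolutions follow the motor/microstep/gear formula", {
  # reference device: 200 steps, 1/4 microstepping, 3:1 pan belt
  cfg <- default_scanner_config()
  expect_equal(pan_resolution_deg(cfg), 0.15)
  expect_equal(tilt_resolution_deg(cfg), 0.45)
  # finest driver settings
  expect_equal(pan_resolution_deg(default_scanner_config(pan_microstep = 16)),
               0.0375)
  expect_equal(tilt_resolution_deg(default_scanner_config(tilt_microstep = 8)),
               0.225)
  # bare motor, no gearing
  bare <- scanner_config(
    pan = axis_config(motor_spec(200), 1, gear_ratio = 1),
    tilt = axis_config(motor_spec(200), 1, gear_ratio = 1,
                       positive_direction = "up"),
    step_duration_s = 1 / 100, tilt_start_deg = 0, tilt_end_deg = 10)
  expect_equal(pan_resolution_deg(bare), 1.8)
  expect_equal(tilt_resolution_deg(bare), 1.8)
})

test_that("revolution period, counts and duration reproduce the reference device", {
  cfg <- default_scanner_config()  # 3.3 ms literal step
  expect_equal(points_per_revolution(cfg), 2400L)
  expect_equal(revolution_period_s(cfg), 7.92)
  expect_equal(num_revolutions(cfg), 289L)
  expect_equal(total_points(cfg), 693600L)
  expect_equal(round(scan_duration_s(cfg) / 60), 38)
  # high-resolution field settings at 240 Hz: 4800 points per revolution
  cfg8 <- default_scanner_config(pan_microstep = 8, step_duration_s = 1 / 240)
  expect_equal(points_per_revolution(cfg8), 4800L)
  expect_equal(revolution_period_s(cfg8), 20)
  expect_equal(total_points(cfg8), 1387200L)
})

test_that("revolution count rounds up to cover the tilt sweep, exact quotients kept", {
  expect_equal(num_revolutions(default_scanner_config()), 289L)  # 288.9 up
  one <- default_scanner_config(tilt_start_deg = 0, tilt_end_deg = 0.45)
  expect_equal(num_revolutions(one), 1L)
  full <- default_scanner_config(tilt_microstep = 8, tilt_start_deg = -90,
                                 tilt_end_deg = 90)
  expect_equal(num_revolutions(full), 800L)  # 180 / 0.225 exact
})

test_that("count and duration identities hold over a grid of configurations", {
  for (m_pan in c(1, 2, 4, 8, 16)) {
    for (m_tilt in c(1, 4)) {
      for (sweep in list(c(-40, 90), c(-10, 10), c(0, 0.9))) {
        cfg <- default_scanner_config(pan_microstep = m_pan,
                                      tilt_microstep = m_tilt,
                                      tilt_start_deg = sweep[1],
                                      tilt_end_deg = sweep[2])
        expect_identical(total_points(cfg),
                         num_revolutions(cfg) * points_per_revolution(cfg))
        expect_equal(scan_duration_s(cfg),
                     total_points(cfg) * cfg$step_duration_s)
      }
    }
  }
})

test_that("halving the microstep denominator halves points and doubles spacing", {
  for (m in c(2, 4, 8, 16)) {
    hi <- default_scanner_config(pan_microstep = m)
    lo <- default_scanner_config(pan_microstep = m / 2)
    expect_equal(points_per_revolution(hi), 2L * points_per_revolution(lo))
    expect_equal(pan_resolution_deg(lo), 2 * pan_resolution_deg(hi))
  }
})

test_that("the sensor cap's minimum step interval displays as 3.3 ms", {
  expect_identical(sprintf("%.1f", 1000 * min_step_duration_s()), "3.3")
  expect_error(default_scanner_config(step_duration_s = 0.002),
               "undercuts the sensor sampling cap")
})

test_that("schedules start at the aligned orientation and advance stepwise", {
  cfg <- default_scanner_config(tilt_end_deg = -39.1)  # 2 revolutions
  sch <- build_schedule(cfg)
  expect_equal(nrow(sch), 4800L)
  # field alignment: north, 40 deg below the horizon
  expect_equal(unlist(sch[1, c("time_ms", "bearing_deg", "tilt_deg")]),
               c(time_ms = 0, bearing_deg = 0, tilt_deg = -40))
  expect_equal(sch$time_ms[2], 3.3)
  expect_equal(sch$bearing_deg[2], 0.15)
  expect_equal(sch$tilt_deg[2], -40)
  # constant step timing; constant tilt within a revolution; one tilt step at wrap
  expect_true(all(abs(diff(sch$time_ms) - 3.3) < 1e-9))
  expect_equal(unique(sch$tilt_deg[sch$revolution == 0]), -40)
  expect_equal(unique(sch$tilt_deg[sch$revolution == 1]), -39.55)
  # consecutive bearings differ by the pan resolution, mod 360
  dd <- diff(sch$bearing_deg) %% 360
  expect_true(all(abs(dd - 0.15) < 1e-9))
})

test_that("schedule size is guarded by the safety cap", {
  cfg <- default_scanner_config()
  expect_error(build_schedule(cfg, max_entries = 1000), "safety cap")
})

test_that("invalid axis configurations are rejected", {
  expect_error(axis_config(motor_spec(200), 3), "microstep_denominator")
  expect_error(axis_config(motor_spec(200), 4, gear_ratio = 1.001),
               "not an integer")
  expect_error(motor_spec(0), "positive")
  expect_error(default_scanner_config(tilt_start_deg = 50, tilt_end_deg = 40),
               "tilt_start_deg")
})
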