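# Reference device: 200-step NEMA 17 motors, 3:1 pan belt drive, direct
# tilt drive, 1/4 microstepping on both axes, 3.3 ms step interval (the
# 300 Hz sensor cap), tilt sweep -40 deg to the zenith, 40 m / 1 cm
# rangefinder. Mount offsets are per-unit calibration values: measure them
# on the physical build and edit here (zeros = ideal on-axis laser).
pan:
  steps_per_rev: 200
  microstep_denominator: 4
  gear_ratio: 3.0
  positive_direction: clockwise
tilt:
  steps_per_rev: 200
  microstep_denominator: 4
  gear_ratio: 1.0
  positive_direction: up
step_duration_s: 0.0033
tilt_start_deg: -40.0
tilt_end_deg: 90.0
start_bearing_deg: 0.0
rangefinder:
  max_range_m: 40.0
  distance_resolution_m: 0.01
  accuracy_near_m: 0.05
  accuracy_far_m: 0.025
  near_far_boundary_m: 2.0
  max_sample_rate_hz: 300.0
mount_offset:
  lateral_m: 0.0
  forward_m: 0.0
  vertical_m: 0.0
  bearing_trim_deg: 0.0
  tilt_trim_deg: 0.0
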