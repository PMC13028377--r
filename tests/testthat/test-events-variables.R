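# Event detection and the 22-variable extraction.

test_that("detected events match the generator exactly on clean data", {
  for (sex in c("male", "female")) {
    gt <- default_truth(sex)
    ev <- detect_events(gt$trial, pole_plant = gt$events$pole_plant)
    expect_identical(ev$toe_offs, gt$events$toe_offs)
    expect_identical(ev$td_third_last, gt$events$td_third_last)
    expect_identical(ev$take_off, gt$events$take_off)
  }
})

test_that("detected events stay within one frame under 2 mm landmark noise", {
  gt <- default_truth("male")
  worst <- 0L
  for (s in 1:100) {
    noisy <- degrade_as_method(gt, noise_sd = 0.002, seed = s)
    ev <- detect_events(noisy, pole_plant = gt$events$pole_plant)
    worst <- max(worst, abs(ev$toe_offs - gt$events$toe_offs),
                 abs(ev$td_third_last - gt$events$td_third_last))
  }
  expect_lte(worst, 1L)
})

test_that("an airborne-only excerpt raises an error", {
  gt <- default_truth("male")
  a <- gt$events$toe_offs[1] + 3
  b <- gt$events$td_third_last - 2
  sub <- trial3d(gt$trial$coords[a:b, , , drop = FALSE], sample_rate = 100)
  expect_error(detect_events(sub), "fewer than 4")
})

test_that("extraction on noise-free ground truth reproduces the generator values", {
  for (sex in c("male", "female")) {
    gt <- default_truth(sex)
    ev <- detect_events(gt$trial, pole_plant = gt$events$pole_plant)
    roles <- leg_roles(ev, gt$trial)
    cm <- whole_body_cm(gt$trial, segmental_table(sex))   # filter disabled
    ang <- joint_angles(gt$trial)
    vars <- extract_variables(cm, ang, gt$trial, ev, roles)
    expect_identical(vars$variable, gt$variables$variable)
    expect_lt(max(abs(vars$value - gt$variables$value)), 1e-6)
  }
})

test_that("extraction through the 20 Hz filter stays within stated tolerances", {
  gt <- default_truth("male")
  a <- analyze_trial(gt$trial, sex = "male",
                     events = detect_events(gt$trial,
                                            pole_plant = gt$events$pole_plant))
  d <- a$variables$value - gt$variables$value
  names(d) <- a$variables$variable
  units <- a$variables$units
  expect_lt(max(abs(d[units == "m"])), 0.02)      # lengths / heights
  expect_lt(max(abs(d[units == "m/s"])), 0.15)    # velocities
  # angles at the take-off frame sit on a contact corner that the 20 Hz
  # dual-pass filter necessarily smooths; a few degrees of edge distortion
  # is inherent to coordinate-level filtering
  expect_lt(max(abs(d[units == "deg"])), 5)
})

test_that("step lengths telescope into the toe displacement across the window", {
  gt <- default_truth("male")
  ev <- gt$events
  v <- gt$variables
  steps <- v$value[grep("^step_length", v$variable)]
  toe_first <- gt$trial$coords[ev$toe_offs[1], "right_mtp", "x"]
  toe_last <- gt$trial$coords[ev$take_off, "left_mtp", "x"]
  expect_equal(sum(steps), unname(toe_last - toe_first), tolerance = 1e-9)
})

test_that("take-off angle and resultant velocity satisfy their identities", {
  expect_equal(takeoff_angle(5, 0), 0)
  expect_equal(takeoff_angle(1, 1), 45)
  expect_equal(resultant_velocity(3, 4), 5)
  gt <- default_truth("female")
  v <- gt$variables
  val <- function(nm) v$value[v$variable == nm]
  expect_equal(val("cm_abs_velocity_to"),
               resultant_velocity(val("cm_hor_velocity_to"),
                                  val("cm_vert_velocity_to")),
               tolerance = 1e-12)
  expect_equal(val("cm_takeoff_angle"),
               takeoff_angle(val("cm_hor_velocity_to"),
                             val("cm_vert_velocity_to")),
               tolerance = 1e-12)
  expect_gte(val("cm_abs_velocity_to"), val("cm_hor_velocity_to"))
})

test_that("waveform windows are shared, sliced, and normalised to 101 points", {
  gt <- default_truth("male")
  ev <- detect_events(gt$trial, pole_plant = gt$events$pole_plant)
  cm <- whole_body_cm(gt$trial, segmental_table("male"))
  ang <- joint_angles(gt$trial)
  w <- extract_waveforms(cm, ang, ev)
  n_expected <- ev$take_off - ev$td_third_last + 1
  expect_length(w$channels$cm_z, n_expected)
  expect_length(w$normalised$cm_z, 101)

  noisy <- degrade_as_method(gt, noise_sd = 0.002, seed = 3)
  w2 <- extract_waveforms(whole_body_cm(noisy, segmental_table("male")),
                          joint_angles(noisy), ev)
  expect_identical(w$frames, w2$frames)          # shared-window contract

  bad_ev <- ev; bad_ev$td_third_last <- ev$take_off
  expect_error(extract_waveforms(cm, ang, bad_ev), "degenerate")
})

test_that("events outside the trajectory window are rejected", {
  gt <- default_truth("male")
  ev <- gt$events
  roles <- leg_roles(ev, gt$trial)
  cm <- whole_body_cm(gt$trial, segmental_table("male"))
  ang <- joint_angles(gt$trial)
  bad <- ev; bad$pole_plant <- 1L
  expect_error(extract_variables(cm, ang, gt$trial, bad, roles), "window")
})
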