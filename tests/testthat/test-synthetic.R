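# Synthetic vaulter generator.

test_that("ground-truth variables equal the generator parameters exactly", {
  p <- synth_params(step_lengths = c(2.2, 2.2, 2.0),
                    step_velocities = c(9.3, 9.4, 9.5))
  gt <- generate_trial(p)
  v <- gt$variables
  val <- function(nm) v$value[v$variable == nm]
  expect_equal(val("step_length_last"), 2.0, tolerance = 1e-9)
  expect_equal(val("step_length_3rd_last"), 2.2, tolerance = 1e-9)
  expect_equal(val("step_velocity_2nd_last"), 9.4, tolerance = 1e-9)
  # event velocities are frame-rate central differences of the closed-form
  # profile; they sit within one frame's acceleration of the continuous value
  expect_equal(val("cm_vert_velocity_to"), p$launch_velocity, tolerance = 0.1)
})

test_that("the generator is deterministic and degradation is seed-driven", {
  p <- synth_params()
  a <- generate_trial(p); b <- generate_trial(p)
  expect_identical(a$trial$coords, b$trial$coords)
  d1 <- degrade_as_method(a, noise_sd = 0.002, seed = 7)
  d2 <- degrade_as_method(a, noise_sd = 0.002, seed = 7)
  d3 <- degrade_as_method(a, noise_sd = 0.002, seed = 8)
  expect_identical(d1$coords, d2$coords)
  expect_false(identical(d1$coords, d3$coords))
})

test_that("men's defaults produce runway velocities in the elite envelope", {
  gt <- default_truth("male")
  v <- gt$variables
  avg <- v$value[v$variable == "avg_runway_velocity"]
  expect_gt(avg, 9.63 - 3 * 0.28)
  expect_lt(avg, 9.63 + 3 * 0.28)
})

test_that("stance toes are anchored at runway height and events are consistent", {
  gt <- default_truth("male")
  tl_TO <- gt$events$toe_offs
  expect_true(all(diff(tl_TO) > 0))
  expect_identical(gt$events$take_off, tl_TO[4])
  expect_true(gt$events$td_third_last > tl_TO[1] &&
                gt$events$td_third_last < tl_TO[2])
  # the toe of the final stance is exactly on the runway and stationary
  td <- gt$events$take_off - 3
  toe <- gt$trial$coords[, "left_mtp", ]
  expect_lt(max(abs(toe[td:gt$events$take_off, 3])), 1e-12)
  expect_lt(max(abs(diff(toe[td:gt$events$take_off, 1]))), 1e-12)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(synth_params(step_lengths = c(2, -1, 2)), "step lengths")
  expect_error(synth_params(noise_sd_3d = -0.1), "noise SDs")
  expect_error(synth_params(duty_factor = 1.2), "duty_factor")
  expect_error(generate_trial(synth_params(duty_factor = 0.98)), "overlap")
  expect_error(generate_trial(synth_params(pole_plant_offset = 10000)),
               "pole_plant_offset")
})

test_that("degradation: identity, systematic offsets, and noise convergence", {
  gt <- default_truth("male")
  same <- degrade_as_method(gt, offsets = NULL, noise_sd = 0, method = "COPY")
  expect_identical(same$coords, gt$trial$coords)
  expect_equal(same$method, "COPY")

  # +15 mm anterior shift of one ankle: ankle angle biased, CM shift equals
  # the mass-fraction-weighted landmark shift
  off <- list(left_ankle = c(0.015, 0, 0))
  shifted <- degrade_as_method(gt, offsets = off, noise_sd = 0)
  tab <- segmental_table("male")
  ja0 <- joint_angles(gt$trial); ja1 <- joint_angles(shifted)
  to <- gt$events$take_off
  expect_gt(abs(ja1[to, "left_ankle"] - ja0[to, "left_ankle"]), 0.5)
  cm_shift <- whole_body_cm(shifted, tab) - whole_body_cm(gt$trial, tab)
  mf <- function(seg) tab$mass_fraction[tab$segment == seg]
  cr <- function(seg) tab$cm_ratio[tab$segment == seg]
  expected_dx <- 0.015 * (mf("left_shank") * cr("left_shank") +
                            mf("left_foot") * (1 - cr("left_foot")))
  expect_equal(mean(cm_shift[, 1]), expected_dx, tolerance = 1e-12)
  expect_lt(max(abs(cm_shift[, 2:3])), 1e-12)

  # Monte-Carlo mean of injected differences converges to the offsets
  off2 <- c(0.004, -0.002, 0.003)
  acc <- 0
  for (s in 1:200) {
    d <- degrade_as_method(gt, offsets = off2, noise_sd = 0.002, seed = s)
    acc <- acc + (d$coords - gt$trial$coords)
  }
  mdiff <- apply(acc / 200, 3, mean)
  se <- 0.002 / sqrt(200 * prod(dim(gt$trial$coords)[1:2]))
  expect_lt(max(abs(mdiff - off2)), 6 * se + 1e-6)
})

test_that("camera projection flags occlusions instead of clipping", {
  gt <- default_truth("male")
  rig <- default_camera_rig()
  obs <- project_to_cameras(gt$trial, rig, pixel_noise_sd = 0)
  vis <- vapply(obs, function(o) mean(o$visible), numeric(1))
  expect_true(all(vis > 0.5))                  # cameras cover the volume
  inframe <- vapply(seq_along(obs), function(k) {
    o <- obs[[k]]
    all(o$u[o$visible] >= 0 & o$u[o$visible] <= rig[[k]]$image_size[1])
  }, logical(1))
  expect_true(all(inframe))
  # flagged-not-clipped: invisible observations keep their out-of-frame pixels
  out <- which(!obs[[1]]$visible, arr.ind = TRUE)
  if (nrow(out) > 0) {
    i <- out[1, 1]; j <- out[1, 2]
    expect_true(obs[[1]]$u[i, j] < 0 | obs[[1]]$u[i, j] > rig[[1]]$image_size[1] |
                  obs[[1]]$v[i, j] < 0 | obs[[1]]$v[i, j] > rig[[1]]$image_size[2])
  }
})

test_that("parameters and trials survive YAML/CSV round trips", {
  p <- synth_params(step_lengths = c(2.1, 2.0, 1.9), seed = 42)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synth_params(p, f)
  back <- read_synth_params(f)
  expect_equal(back$step_lengths, p$step_lengths)
  expect_equal(back$athlete_sex, p$athlete_sex)

  gt <- default_truth("female")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(gt$trial, fc)
  tr <- read_trial_csv(fc)
  expect_lt(max(abs(tr$coords - gt$trial$coords)), 1e-12)
  expect_equal(tr$method, gt$trial$method)

  ft <- withr::local_tempfile(fileext = ".trc")
  write_trc(gt$trial, ft)
  expect_gt(length(readLines(ft)), n_frames(gt$trial))

  cps <- make_control_points(n = 8)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_control_points_csv(cps, fp)
  expect_equal(nrow(read.csv(fp)), 8)
})
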