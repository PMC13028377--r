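# de Leva segmental model: whole-body CM and sagittal joint angles.

test_that("segmental tables are normalised and well-formed", {
  for (sex in c("male", "female")) {
    tab <- segmental_table(sex)
    expect_equal(sum(tab$mass_fraction), 1, tolerance = 1e-12)
    expect_true(all(tab$cm_ratio >= 0 & tab$cm_ratio <= 1))
    expect_equal(nrow(tab), 14)   # head, trunk, 6 paired segments x 2 sides
  }
  # sexes differ (different source anthropometry)
  expect_false(isTRUE(all.equal(segmental_table("male")$mass_fraction,
                                segmental_table("female")$mass_fraction)))
})

test_that("CM of a bilaterally symmetric posture lies on the midsagittal plane", {
  tr <- posture_trial()
  cm <- whole_body_cm(tr, segmental_table("male"))
  expect_lt(max(abs(cm[, 2])), 1e-12)
})

test_that("degenerate all-trunk weighting collapses CM onto the trunk segment", {
  tr <- random_posture_trial(seed = 8)
  tab <- segmental_table("male")
  tab$mass_fraction <- ifelse(tab$segment == "trunk", 1, 0)
  cm <- whole_body_cm(tr, tab)
  co <- tr$coords
  mid_sh <- (co[, "left_shoulder", ] + co[, "right_shoulder", ]) / 2
  mid_hip <- (co[, "left_hip", ] + co[, "right_hip", ]) / 2
  r <- tab$cm_ratio[tab$segment == "trunk"]
  expect_equal(cm, unname(mid_sh + r * (mid_hip - mid_sh)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("CM equals an independent brute-force weighted sum on random postures", {
  for (seed in c(3, 14, 25)) {
    tr <- random_posture_trial(seed = seed)
    tab <- segmental_table(if (seed %% 2) "male" else "female")
    expect_equal(whole_body_cm(tr, tab), bruteforce_cm(tr, tab),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("CM stays inside the convex hull of segment CMs (convexity)", {
  gt <- default_truth("male")
  tab <- segmental_table("male")
  cm <- whole_body_cm(gt$trial, tab)
  co <- gt$trial$coords
  # bounding box of all landmarks contains every convex combination
  for (ax in 1:3) {
    expect_true(all(cm[, ax] <= apply(co[, , ax], 1, max) + 1e-12))
    expect_true(all(cm[, ax] >= apply(co[, , ax], 1, min) - 1e-12))
  }
})

test_that("missing landmarks in the window are reported by name", {
  tr <- posture_trial()
  tr$missing[2, "left_knee"] <- TRUE
  expect_error(whole_body_cm(tr, segmental_table("male")), "left_knee")
})

test_that("joint angles follow the 180-degree standing convention", {
  ja <- joint_angles(posture_trial())
  expect_equal(unname(ja[1, "left_hip"]), 180, tolerance = 1e-9)
  expect_equal(unname(ja[1, "right_knee"]), 180, tolerance = 1e-9)
  expect_equal(unname(ja[1, "left_ankle"]), 90, tolerance = 1e-9)

  # thigh rotated 30 degrees forward of the trunk line with a straight knee
  ja30 <- joint_angles(posture_trial(thigh_fwd_deg = 30))
  expect_equal(unname(ja30[1, "left_hip"]), 150, tolerance = 1e-9)
  expect_equal(unname(ja30[1, "left_knee"]), 180, tolerance = 1e-9)
  expect_equal(unname(ja30[1, "left_ankle"]), 90, tolerance = 1e-9)

  # hyperextension: thigh behind the trunk line reads above 180, no wrap
  jam <- joint_angles(posture_trial(thigh_fwd_deg = -12))
  expect_equal(unname(jam[1, "right_hip"]), 192, tolerance = 1e-9)
})

test_that("angles are invariant to uniform scaling and runway translation", {
  tr <- random_posture_trial(seed = 6)
  ja <- joint_angles(tr)
  tr2 <- tr
  tr2$coords <- tr$coords * 2.5
  tr2$coords[, , "x"] <- tr2$coords[, , "x"] + 7
  expect_equal(joint_angles(tr2), ja, tolerance = 1e-10)
})

test_that("take-off leg hyperextends past 180 on the synthetic trial", {
  gt <- default_truth("male")
  v <- gt$variables
  expect_gt(v$value[v$variable == "tol_hip_angle_to"], 180)
  expect_lt(v$value[v$variable == "tol_hip_angle_to"], 360)
})

test_that("leg roles identify the take-off and drive legs", {
  gt <- default_truth("male")                  # left take-off by default
  roles <- leg_roles(gt$events, gt$trial)
  expect_equal(roles$take_off_leg, "left")
  expect_equal(roles$drive_leg, "right")

  gtr <- generate_trial(synth_params(takeoff_side = "right"))
  expect_equal(leg_roles(gtr$events, gtr$trial)$take_off_leg, "right")

  # robust to landmark noise at the 2 mm scale
  noisy <- degrade_as_method(gt, noise_sd = 0.002, seed = 5)
  expect_equal(leg_roles(gt$events, noisy)$take_off_leg, "left")
})
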