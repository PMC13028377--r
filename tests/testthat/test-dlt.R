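# DLT calibration and multi-camera reconstruction.

test_that("calibration from exact control points recovers the camera", {
  rig <- default_camera_rig()
  cps <- make_control_points(n = 8, cameras = rig, seed = 2)
  cam <- dlt_calibrate(cps$points, cps$observations[[1]])
  expect_lt(cam$residual_px, 1e-6)
  expect_lt(max(abs(cam$coefficients - rig[[1]]$coefficients)), 1e-6)

  # minimum point count is solvable; fewer is an error
  cps6 <- make_control_points(n = 6, cameras = rig, seed = 2)
  cam6 <- dlt_calibrate(cps6$points, cps6$observations[[1]])
  expect_lt(cam6$residual_px, 1e-6)
  expect_error(dlt_calibrate(cps$points[1:5, ], cps$observations[[1]][1:5, ]),
               "at least 6")
})

test_that("pixel noise shows up in the calibration residual at its own scale", {
  rig <- default_camera_rig()
  cps <- make_control_points(n = 20, cameras = rig, seed = 5)
  set.seed(11)
  obs <- cps$observations[[1]]
  obs$u <- obs$u + rnorm(20, sd = 0.5)
  obs$v <- obs$v + rnorm(20, sd = 0.5)
  cam <- dlt_calibrate(cps$points, obs)
  expect_gt(cam$residual_px, 0.1)
  expect_lt(cam$residual_px, 1.5)
})

test_that("coplanar control points raise a rank error", {
  pts <- cbind(runif(8, -5, 5), runif(8, -1, 1), 1.3)  # all on z = 1.3
  obs <- data.frame(u = runif(8, 0, 2048), v = runif(8, 0, 1536))
  expect_error(dlt_calibrate(pts, obs), "coplanar")
  expect_error(make_control_points(volume = list(x = c(-5, 5), y = c(0, 0),
                                                 z = c(0, 2)), n = 8),
               "degenerate")
})

test_that("triangulation round trip is exact and degrades monotonically", {
  rig <- default_camera_rig()
  cps <- make_control_points(n = 10, cameras = rig, seed = 3)
  cams <- dlt_calibrate_rig(cps)
  expect_lt(cams[[1]]$residual_m, 1e-9)

  set.seed(21)
  pts <- cbind(runif(100, -12, 0), runif(100, -1, 1), runif(100, 0, 2))
  recon_rms <- function(noise_sd, seed) {
    set.seed(seed)
    errs <- vapply(seq_len(nrow(pts)), function(i) {
      px <- lapply(cams, function(cm) {
        p <- dlt_project(cm, pts[i, , drop = FALSE])
        c(p$u + rnorm(1, sd = noise_sd), p$v + rnorm(1, sd = noise_sd))
      })
      sqrt(sum((dlt_reconstruct(cams, px)$xyz - pts[i, ])^2))
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  expect_lt(recon_rms(0, 1), 1e-9)
  e <- vapply(c(0.25, 0.5, 1.0), recon_rms, numeric(1), seed = 31)
  expect_true(all(e > 0))
  expect_true(all(diff(e) > 0))
})

test_that("two views reconstruct exactly; fewer than two is an error", {
  rig <- default_camera_rig()
  cps <- make_control_points(n = 10, cameras = rig, seed = 3)
  cams <- dlt_calibrate_rig(cps)
  pt <- c(-4, 0.3, 1.1)
  px <- lapply(cams, function(cm) {
    p <- dlt_project(cm, rbind(pt)); c(p$u, p$v)
  })
  two <- px; two[[3]] <- c(NA, NA); two[[4]] <- c(NA, NA)
  expect_lt(max(abs(dlt_reconstruct(cams, two)$xyz - pt)), 1e-9)
  one <- two; one[[2]] <- c(NA, NA)
  expect_error(dlt_reconstruct(cams, one), "fewer than 2")
})

test_that("near-parallel camera pairs inflate the condition diagnostic", {
  wide <- list(make_pinhole_camera(c(-10, 8, 5), c(-4, 0, 1)),
               make_pinhole_camera(c(2, -8, 5), c(-4, 0, 1)))
  near <- list(make_pinhole_camera(c(-10, 8, 5), c(-4, 0, 1)),
               make_pinhole_camera(c(-9.9, 8.05, 5), c(-4, 0, 1)))
  pt <- c(-4, 0.2, 1.2)
  px_for <- function(cams) lapply(cams, function(cm) {
    p <- dlt_project(cm, rbind(pt)); c(p$u, p$v)
  })
  cond_wide <- dlt_reconstruct(wide, px_for(wide))$condition
  cond_near <- dlt_reconstruct(near, px_for(near))$condition
  expect_gt(cond_near, 5 * cond_wide)
})

test_that("trial reconstruction propagates missing views and logs gaps", {
  rig <- default_camera_rig()
  cps <- make_control_points(n = 10, cameras = rig, seed = 3)
  cams <- dlt_calibrate_rig(cps)
  gt <- default_truth("male")
  obs <- project_to_cameras(gt$trial, rig, pixel_noise_sd = 0)
  rec <- dlt_reconstruct_trial(cams, obs)
  seen <- !rec$missing
  expect_lt(max(abs(rec$coords[seen] -
                      gt$trial$coords[as.vector(seen)])), 1e-9)
  expect_equal(sum(rec$missing), 0)

  # one camera fully dropped: still reconstructs from 3 views
  obs3 <- obs; obs3[[2]]$visible[] <- FALSE
  rec3 <- dlt_reconstruct_trial(cams, obs3)
  expect_equal(sum(rec3$missing), 0)
  expect_lt(max(abs(rec3$coords - gt$trial$coords)), 1e-9)

  # occlusion of one landmark in 3 of 4 cameras over a window: flagged missing
  occ <- obs
  for (k in 1:3) occ[[k]]$visible[20:30, "left_ankle"] <- FALSE
  rec_occ <- dlt_reconstruct_trial(cams, occ)
  expect_true(all(rec_occ$missing[20:30, "left_ankle"]))
  gaps <- attr(rec_occ, "gap_log")
  expect_setequal(gaps$frame[gaps$landmark == "left_ankle"], 20:30)
})

test_that("projection flags out-of-frame points and rejects points behind", {
  cam <- make_pinhole_camera(c(0, 10, 5), c(0, 0, 1))
  far <- rbind(c(30, 0, 1))                    # outside the frustum, in front
  p <- dlt_project(cam, far)
  expect_false(p$visible)
  behind <- rbind(c(0, 20, 5))                 # behind the camera
  expect_error(dlt_project(cam, behind), "behind camera")
  expect_identical(dlt_project(cam, behind, behind = "flag")$visible, FALSE)
})

test_that("camera YAML round trip preserves coefficients", {
  rig <- default_camera_rig()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cameras_yaml(rig, f)
  back <- read_cameras_yaml(f)
  expect_lt(max(abs(back[[2]]$coefficients - rig[[2]]$coefficients)), 1e-9)
})
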