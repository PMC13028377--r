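# Extraction of the 22 discrete run-up / take-off variables and the analysis
# window waveforms.

#' Resultant velocity and take-off angle identities
#'
#' `resultant_velocity` is the Euclidean norm of the CM velocity components;
#' `takeoff_angle` is the angle of the CM path above the horizontal at
#' take-off, `atan2(vz, vx)` in degrees.
#'
#' @param vx,vy,vz CM velocity components, m/s (mediolateral `vy` defaults
#'   to 0).
#' @return numeric value (m/s or degrees).
#' @export
resultant_velocity <- function(vx, vz, vy = 0) sqrt(vx^2 + vy^2 + vz^2)

#' @rdname resultant_velocity
#' @export
takeoff_angle <- function(vx, vz) atan2(vz, vx) * 180 / pi

# which side's toe leaves the ground at a toe-off frame: the side with the
# stronger (cleaned) contact evidence in the frames leading up to the event
departing_side <- function(trial, frame, height_threshold = 0.02,
                           speed_threshold = 0.8) {
  win <- max(1, frame - 4):frame
  score <- vapply(c("left", "right"), function(side) {
    mask <- clean_mask(toe_contact_mask(trial, side, height_threshold,
                                        speed_threshold))
    sum(mask[win])
  }, numeric(1))
  if (score["left"] == score["right"])
    stop(sprintf("ambiguous stance at frame %d: expected exactly one toe in contact", frame))
  names(score)[which.max(score)]
}

#' Extract the 22 run-up / take-off variables
#'
#' Definitions:
#' \itemize{
#'   \item step length: horizontal (X) distance between the toe positions of
#'     the feet leaving the ground at consecutive toe-offs.
#'   \item step velocity: mean CM horizontal velocity over the step, computed
#'     exactly as CM X displacement divided by the step duration.
#'   \item average runway velocity: mean CM horizontal velocity over the last
#'     three steps (same displacement/duration form); maximum runway velocity:
#'     maximum instantaneous CM X velocity over that window.
#'   \item event heights / velocities: CM height and instantaneous
#'     (differentiated) CM velocity components at the pole-plant and take-off
#'     frames (no sub-frame interpolation); "standing height" is the CM height
#'     at take-off (alias `take_off_cm_height`).
#'   \item take-off angle `atan2(vz, vx)` (degrees); absolute velocity
#'     includes the mediolateral component.
#'   \item joint angles: hip/knee/ankle of the drive (DL) and take-off (TOL)
#'     legs sampled at the take-off frame.
#' }
#'
#' @param cm `n x 3` CM trajectory (from filtered coordinates), metres.
#' @param angles `n x 6` joint angle matrix from [joint_angles()].
#' @param trial the (unfiltered) [trial3d()] used for toe positions and
#'   stance-side identification.
#' @param events an [event_set()].
#' @param roles leg roles from [leg_roles()].
#' @return data.frame with columns `variable`, `value`, `units` (one row per
#'   variable of [variable_catalogue()]).
#' @export
extract_variables <- function(cm, angles, trial, events, roles) {
  fs <- trial$sample_rate
  cm <- matrix(as.numeric(cm), nrow = nrow(cm))   # strip names off scalars
  n <- nrow(cm)
  TO <- events$toe_offs
  if (events$pole_plant < 2 || events$take_off > n - 1)
    stop("event outside trajectory window")
  vx <- differentiate(cm[, 1], fs)
  vy <- differentiate(cm[, 2], fs)
  vz <- differentiate(cm[, 3], fs)
  t <- trial$time

  # toe-off toe positions (departing foot)
  toe_x <- vapply(TO, function(fr) {
    side <- departing_side(trial, fr)
    landmark_xyz(trial, paste0(side, "_mtp"))[fr, 1]
  }, numeric(1))
  step_len <- diff(toe_x)

  step_vel <- (cm[TO[2:4], 1] - cm[TO[1:3], 1]) / (t[TO[2:4]] - t[TO[1:3]])
  avg_rv <- (cm[TO[4], 1] - cm[TO[1], 1]) / (t[TO[4]] - t[TO[1]])
  max_rv <- max(vx[TO[1]:TO[4]])

  pp <- events$pole_plant; to <- events$take_off
  tol <- roles$take_off_leg; dl <- roles$drive_leg
  vals <- c(
    avg_runway_velocity = avg_rv,
    max_runway_velocity = max_rv,
    step_length_3rd_last = step_len[1], step_velocity_3rd_last = step_vel[1],
    step_length_2nd_last = step_len[2], step_velocity_2nd_last = step_vel[2],
    step_length_last = step_len[3], step_velocity_last = step_vel[3],
    cm_height_pp = cm[pp, 3],
    cm_hor_velocity_pp = vx[pp], cm_vert_velocity_pp = vz[pp],
    standing_height = cm[to, 3],
    dl_hip_angle_to = as.numeric(angles[to, paste0(dl, "_hip")]),
    dl_knee_angle_to = as.numeric(angles[to, paste0(dl, "_knee")]),
    dl_ankle_angle_to = as.numeric(angles[to, paste0(dl, "_ankle")]),
    tol_hip_angle_to = as.numeric(angles[to, paste0(tol, "_hip")]),
    tol_knee_angle_to = as.numeric(angles[to, paste0(tol, "_knee")]),
    tol_ankle_angle_to = as.numeric(angles[to, paste0(tol, "_ankle")]),
    cm_hor_velocity_to = vx[to], cm_vert_velocity_to = vz[to],
    cm_abs_velocity_to = resultant_velocity(vx[to], vz[to], vy[to]),
    cm_takeoff_angle = takeoff_angle(vx[to], vz[to])
  )
  cat_df <- variable_catalogue()
  data.frame(variable = cat_df$variable, value = unname(vals[cat_df$variable]),
             units = cat_df$units, stringsAsFactors = FALSE)
}

#' Extract analysis-window waveforms
#'
#' Slices CM displacement (X, Y, Z), CM velocity (X, Z) and the six joint
#' angles to the window from the touchdown of the third-last step to the
#' take-off instant, and also emits a 101-point time-normalised copy intended
#' only for group-mean plotting.
#'
#' @param cm `n x 3` CM trajectory, metres.
#' @param angles `n x 6` matrix from [joint_angles()].
#' @param events an [event_set()].
#' @param sample_rate Hz.
#' @return list of class `waveform_set` with `frames` (window indices),
#'   `channels` (named list of numeric vectors over the window) and
#'   `normalised` (named list of length-101 vectors).
#' @export
extract_waveforms <- function(cm, angles, events, sample_rate = 100) {
  a <- events$td_third_last; b <- events$take_off
  if (b - a < 1) stop("degenerate waveform window (need at least 2 frames)")
  idx <- a:b
  vx <- differentiate(cm[, 1], sample_rate)
  vz <- differentiate(cm[, 3], sample_rate)
  ch <- list(
    cm_x = cm[idx, 1], cm_y = cm[idx, 2], cm_z = cm[idx, 3],
    cm_velocity_x = vx[idx], cm_velocity_z = vz[idx]
  )
  for (col in colnames(angles)) ch[[paste0("angle_", col)]] <- angles[idx, col]
  s <- seq(0, 1, length.out = length(idx))
  norm <- lapply(ch, function(y) approx(s, y, xout = seq(0, 1, length.out = 101))$y)
  structure(list(frames = idx, channels = ch, normalised = norm),
            class = "waveform_set")
}
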