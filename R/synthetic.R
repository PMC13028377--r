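# Synthetic vaulter generator: ground-truth trials, method-degraded copies,
# camera observations and control points, so every downstream stage is
# testable with no external data.
#
# The generator is kinematic, not dynamic: the whole-body CM follows a
# prescribed piecewise path (per-step constant mean horizontal velocity,
# sinusoidal vertical oscillation, a vertical launch ramp through the final
# stance) and the articulated limbs are solved around it. The pelvis is
# placed each frame by a fixed-point iteration so that the de Leva whole-body
# CM of the assembled posture equals the prescribed CM path to machine
# precision, while the stance-foot toe stays anchored to the runway.

#' Parameters of the synthetic vaulter
#'
#' Defaults emulate the men's or women's elite run-up envelopes (runway
#' velocities near 9.6 m/s for men and 8.3 m/s for women, step lengths around
#' 1.8-2.2 m), captured at 100 Hz over the final three steps and take-off.
#'
#' @param athlete_sex `"male"` or `"female"`; selects the segmental table and
#'   the sex-specific defaults for any parameter left `NULL`.
#' @param step_lengths metres, length 3 (3rd-last, 2nd-last, last).
#' @param step_velocities mean CM horizontal velocity per step, m/s, length 3.
#' @param cm_height baseline CM height, metres.
#' @param cm_oscillation amplitude of the sinusoidal CM vertical oscillation,
#'   metres.
#' @param cadence step frequency, steps/s.
#' @param duty_factor fraction of each step spent in ground contact.
#' @param launch_velocity CM vertical velocity at take-off, m/s.
#' @param takeoff_hor_velocity CM horizontal velocity at take-off, m/s; the
#'   CM decelerates linearly to this value through the final stance (pole
#'   plant and take-off absorb horizontal velocity), while the mean velocity
#'   of the last step stays exactly `step_velocities[3]`.
#' @param pole_plant_offset frames before take-off at which the pole contacts
#'   the plant box (the pole tip itself is untracked).
#' @param stature metres.
#' @param takeoff_side `"left"` or `"right"`: the take-off leg.
#' @param noise_sd_3d per-landmark isotropic noise SD used when degrading,
#'   metres.
#' @param method_offsets default per-landmark systematic shifts used when
#'   degrading (see [degrade_as_method()]).
#' @param pixel_noise_sd default pixel noise SD for camera projection.
#' @param lead_frames extra frames before the first analysed toe-off.
#' @param trail_frames frames kept after take-off (before padding).
#' @param pad_frames padding frames at each end for filter initialisation.
#' @param sample_rate Hz.
#' @param seed integer seed for downstream stochastic operations.
#' @return list of class `synth_params`.
#' @export
synth_params <- function(athlete_sex = c("male", "female"),
                         step_lengths = NULL,
                         step_velocities = NULL,
                         cm_height = NULL,
                         cm_oscillation = 0.04,
                         cadence = 4.4,
                         duty_factor = 0.32,
                         launch_velocity = NULL,
                         takeoff_hor_velocity = NULL,
                         pole_plant_offset = 14,
                         stature = NULL,
                         takeoff_side = "left",
                         noise_sd_3d = 0,
                         method_offsets = NULL,
                         pixel_noise_sd = 0,
                         lead_frames = 10,
                         trail_frames = 8,
                         pad_frames = 10,
                         sample_rate = 100,
                         seed = 1L) {
  athlete_sex <- match.arg(athlete_sex)
  if (athlete_sex == "male") {
    if (is.null(step_lengths)) step_lengths <- c(2.20, 2.20, 1.96)
    if (is.null(step_velocities)) step_velocities <- c(9.60, 9.63, 9.66)
    if (is.null(cm_height)) cm_height <- 1.10
    if (is.null(launch_velocity)) launch_velocity <- 2.70
    if (is.null(takeoff_hor_velocity)) takeoff_hor_velocity <- 8.0
    if (is.null(stature)) stature <- 1.85
  } else {
    if (is.null(step_lengths)) step_lengths <- c(1.98, 1.92, 1.81)
    if (is.null(step_velocities)) step_velocities <- c(8.25, 8.29, 8.36)
    if (is.null(cm_height)) cm_height <- 1.03
    if (is.null(launch_velocity)) launch_velocity <- 2.26
    if (is.null(takeoff_hor_velocity)) takeoff_hor_velocity <- 6.9
    if (is.null(stature)) stature <- 1.72
  }
  p <- list(athlete_sex = athlete_sex, step_lengths = step_lengths,
            step_velocities = step_velocities, cm_height = cm_height,
            cm_oscillation = cm_oscillation, cadence = cadence,
            duty_factor = duty_factor, launch_velocity = launch_velocity,
            takeoff_hor_velocity = takeoff_hor_velocity,
            pole_plant_offset = as.integer(pole_plant_offset),
            stature = stature, takeoff_side = takeoff_side,
            noise_sd_3d = noise_sd_3d, method_offsets = method_offsets,
            pixel_noise_sd = pixel_noise_sd,
            lead_frames = as.integer(lead_frames),
            trail_frames = as.integer(trail_frames),
            pad_frames = as.integer(pad_frames),
            sample_rate = sample_rate, seed = as.integer(seed))
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  stopifnot(length(p$step_lengths) == 3, length(p$step_velocities) == 3)
  if (any(p$step_lengths <= 0)) stop("step lengths must be > 0")
  if (any(p$step_velocities <= 0)) stop("step velocities must be > 0")
  if (p$noise_sd_3d < 0 || p$pixel_noise_sd < 0) stop("noise SDs must be >= 0")
  if (p$cadence <= 0 || p$stature <= 0 || p$cm_height <= 0)
    stop("cadence, stature and cm_height must be > 0")
  if (p$takeoff_hor_velocity <= 0)
    stop("takeoff_hor_velocity must be > 0")
  if (p$duty_factor <= 0 || p$duty_factor >= 1)
    stop("configuration error: duty_factor must be in (0, 1)")
  if (!p$takeoff_side %in% c("left", "right"))
    stop("takeoff_side must be 'left' or 'right'")
  if (p$pole_plant_offset < 0) stop("pole_plant_offset must be >= 0")
  invisible(p)
}

# smooth interpolants on [0, 1]
smooth3 <- function(s) { s <- pmin(1, pmax(0, s)); s^2 * (3 - 2 * s) }
smooth5 <- function(s) { s <- pmin(1, pmax(0, s)); s^3 * (6 * s^2 - 15 * s + 10) }

# body proportions (metres) from stature
body_dims <- function(stature) {
  list(thigh = 0.252 * stature, shank = 0.254 * stature,
       foot = 0.095 * stature,              # ankle -> MTP
       trunk = 0.288 * stature,             # mid-hip -> mid-shoulder
       neck = 0.110 * stature,              # mid-shoulder -> head centre
       upper_arm = 0.172 * stature, forearm = 0.150 * stature,
       hand = 0.045 * stature,
       hip_halfwidth = 0.052 * stature, shoulder_halfwidth = 0.098 * stature)
}

#' Event set for one trial
#'
#' @param toe_offs four frame indices: the toe-off starting the 3rd-last step
#'   through the take-off toe-off.
#' @param td_third_last touchdown frame of the third-last step.
#' @param pole_plant pole-plant frame.
#' @return list of class `event_set` (with `take_off = toe_offs[4]`).
#' @export
event_set <- function(toe_offs, td_third_last, pole_plant) {
  toe_offs <- as.integer(toe_offs)
  stopifnot(length(toe_offs) == 4)
  ev <- list(toe_offs = toe_offs, td_third_last = as.integer(td_third_last),
             pole_plant = as.integer(pole_plant), take_off = toe_offs[4])
  if (any(diff(toe_offs) <= 0)) stop("toe-off frames must be strictly increasing")
  if (!(ev$td_third_last > toe_offs[1] && ev$td_third_last < toe_offs[2]))
    stop("td_third_last must lie between the first two toe-offs")
  if (ev$pole_plant > ev$take_off) stop("pole plant cannot follow take-off")
  structure(ev, class = "event_set")
}

#' Names and units of the run-up / take-off variable set
#'
#' The 22 discrete variables describing the final three steps and take-off.
#'
#' @return data.frame with columns `variable`, `units`.
#' @export
variable_catalogue <- function() {
  data.frame(
    variable = c("avg_runway_velocity", "max_runway_velocity",
                 "step_length_3rd_last", "step_velocity_3rd_last",
                 "step_length_2nd_last", "step_velocity_2nd_last",
                 "step_length_last", "step_velocity_last",
                 "cm_height_pp", "cm_hor_velocity_pp", "cm_vert_velocity_pp",
                 "standing_height",
                 "dl_hip_angle_to", "dl_knee_angle_to", "dl_ankle_angle_to",
                 "tol_hip_angle_to", "tol_knee_angle_to", "tol_ankle_angle_to",
                 "cm_hor_velocity_to", "cm_vert_velocity_to",
                 "cm_abs_velocity_to", "cm_takeoff_angle"),
    units = c("m/s", "m/s", "m", "m/s", "m", "m/s", "m", "m/s",
              "m", "m/s", "m/s", "m",
              "deg", "deg", "deg", "deg", "deg", "deg",
              "m/s", "m/s", "m/s", "deg"),
    stringsAsFactors = FALSE
  )
}

# frame timeline implied by the parameters. Step durations follow from the
# step lengths and mean velocities (T_k = s_k / v_k, rounded to frames) so
# that the CM passes over each anchored contact; cadence only shapes the arm
# swing. Contact durations are duty_factor of the step ending at each stance.
synth_timeline <- function(p) {
  fs <- p$sample_rate
  Tf <- pmax(4L, as.integer(round(fs * p$step_lengths / p$step_velocities)))
  Cf1_3 <- pmax(3L, as.integer(round(p$duty_factor * Tf)))
  Cf <- c(Cf1_3[1], Cf1_3)                 # stances 0..3; stance 0 mirrors step 1
  if (any(Cf1_3 >= Tf))
    stop("configuration error: ground contacts overlap in time (duty_factor too high for these steps)")
  TO0 <- p$pad_frames + p$lead_frames + Cf[1]
  TO <- TO0 + c(0L, cumsum(Tf))
  if (p$pole_plant_offset >= TO[4])
    stop("pole_plant_offset must be smaller than the frames to take-off")
  n <- TO[4] + p$trail_frames + p$pad_frames
  list(Tf = Tf, Cf = Cf, TO = TO, n = n, fs = fs, dt = 1 / fs,
       t = (seq_len(n) - 1) / fs,
       td = TO - Cf + 1L,                  # touchdown frame of each stance
       pp = TO[4] - p$pole_plant_offset)
}

# closed-form CM path; returns functions x(t), z(t) (vectorised).
# xc gives the four anchored contact positions; the free horizontal offset of
# the CM path is chosen to balance the residual contact/mid-stance
# misalignment (caused by rounding step durations to whole frames) across the
# four stances.
synth_cm_path <- function(p, tl, xc) {
  v <- p$step_velocities
  tTO <- tl$t[tl$TO]
  t_td3 <- tl$t[tl$td[4]]
  t_to <- tTO[4]
  A <- p$cm_oscillation
  h0 <- p$cm_height
  # oscillation phase locked to the mid-stances: u = j at the mid-time of
  # stance j (piecewise-linear phase keeps minima exactly at mid-stance and
  # the vertical velocity continuous)
  ms <- (tl$t[tl$td] + tTO) / 2
  t_ms3 <- ms[4]
  ufun <- function(t) {
    u <- numeric(length(t))
    lo <- t < ms[1]
    u[lo] <- (t[lo] - ms[1]) / (ms[2] - ms[1])
    hi <- t >= ms[4]
    u[hi] <- 3 + (t[hi] - ms[4]) / (ms[4] - ms[3])
    for (j in 1:3) {
      sel <- t >= ms[j] & t < ms[j + 1]
      u[sel] <- (j - 1) + (t[sel] - ms[j]) / (ms[j + 1] - ms[j])
    }
    u
  }
  zsin <- function(t) h0 - A * cos(2 * pi * ufun(t))
  # launch ramp: constant vertical acceleration from the pole plant (or the
  # final touchdown, whichever is earlier than take-off by at least 2 frames)
  # so that CM vertical velocity at take-off equals launch_velocity. The rise
  # through the plant emulates pole support; the generator is kinematic.
  t_rise <- min(tl$t[tl$pp], t_td3)
  t_rise <- min(t_rise, t_to - 2 * tl$dt)
  dzsin_to <- A * 2 * pi * sin(2 * pi * ufun(t_to)) / (ms[4] - ms[3])
  v_ramp <- p$launch_velocity - dzsin_to
  acc <- v_ramp / (t_to - t_rise)
  z_to <- zsin(t_to) + 0.5 * acc * (t_to - t_rise)^2
  vz_to <- dzsin_to + v_ramp
  g <- 9.81
  zfun <- function(t) {
    ramp <- ifelse(t < t_rise, 0,
                   ifelse(t <= t_to, 0.5 * acc * (t - t_rise)^2, NA_real_))
    out <- zsin(t) + ramp
    air <- t > t_to
    out[air] <- z_to + vz_to * (t[air] - t_to) - 0.5 * g * (t[air] - t_to)^2
    out
  }
  # horizontal: per-step constant mean velocity, with a linear deceleration
  # through the final stance down to the take-off horizontal velocity; the
  # pre-stance velocity v_pre is chosen so the mean velocity of the last step
  # stays exactly v[3]
  v_to <- p$takeoff_hor_velocity
  T3 <- tTO[4] - tTO[3]
  C3 <- t_to - t_td3
  v_pre <- (v[3] * T3 - v_to * C3 / 2) / (T3 - C3 / 2)
  xfun_rel <- function(t) {
    base <- v[1] * (pmin(t, tTO[2]) - tTO[1]) +
      v[2] * pmax(0, pmin(t, tTO[3]) - tTO[2]) +
      v_pre * pmax(0, pmin(t, t_td3) - tTO[3])
    tau <- pmax(0, pmin(t, t_to) - t_td3)
    decel <- v_pre * tau - (v_pre - v_to) * tau^2 / (2 * C3)
    base + decel + v_to * pmax(0, t - t_to)
  }
  mis <- (xc - 0.05) - xfun_rel(ms)
  off <- (max(mis) + min(mis)) / 2
  xfun <- function(t) xfun_rel(t) + off
  list(xfun = xfun, zfun = zfun, t_ms3 = t_ms3, v_pre = v_pre)
}

# per-foot MTP / foot-angle schedules.
# Each foot is anchored at its contact positions, swings between consecutive
# contacts on a smooth profile, and rises away after its final contact (the
# drive knee after the penultimate stance, the jump after take-off).
synth_foot_tracks <- function(p, tl, xc) {
  n <- tl$n
  # foot pitch: forefoot strike (~28 deg) with the heel rising over the
  # anchored toe through stance (~62 deg at toe-off, ankle behind the toe)
  a_td <- 28 * pi / 180; a_to <- 62 * pi / 180
  swing_h <- 0.15
  build <- function(contacts) {     # contacts: data.frame(start, end, x)
    mtp_x <- numeric(n); mtp_z <- numeric(n); alpha <- numeric(n)
    stance <- logical(n)
    for (i in seq_len(nrow(contacts))) {
      s0 <- max(1L, contacts$start[i]); e0 <- contacts$end[i]
      idx <- s0:e0
      mtp_x[idx] <- contacts$x[i]
      mtp_z[idx] <- 0
      ph <- (idx - contacts$start[i]) / max(1L, contacts$end[i] - contacts$start[i])
      alpha[idx] <- a_td + (a_to - a_td) * smooth3(ph)
      stance[idx] <- TRUE
      if (i < nrow(contacts)) {       # swing to the next contact
        sw <- (e0 + 1L):(contacts$start[i + 1] - 1L)
        s <- (sw - e0) / (contacts$start[i + 1] - e0)
        mtp_x[sw] <- contacts$x[i] + (contacts$x[i + 1] - contacts$x[i]) * smooth5(s)
        mtp_z[sw] <- swing_h * sin(pi * s)^0.7
        alpha[sw] <- a_to + (a_td - a_to) * smooth3(s)
      }
    }
    # swing in from a virtual pre-window contact; clamped strictly airborne
    if (contacts$start[1] > 1L) {
      pre <- 1L:(contacts$start[1] - 1L)
      e_v <- contacts$start[1] - (2L * as.integer(round(mean(tl$Tf))) - tl$Cf[1]) - 1L   # virtual prior toe-off
      x_v <- contacts$x[1] - 2 * mean(p$step_lengths)
      s <- pmin(1, pmax(0.06, (pre - e_v) / (contacts$start[1] - e_v)))
      mtp_x[pre] <- x_v + (contacts$x[1] - x_v) * smooth5(s)
      mtp_z[pre] <- swing_h * sin(pi * s)^0.7
      alpha[pre] <- a_to + (a_td - a_to) * smooth3(s)
    }
    # rise away after the final contact (knee drive / jump): the toe sweeps
    # forward and up under the hip and never returns to the runway
    e_last <- contacts$end[nrow(contacts)]
    if (e_last < n) {
      post <- (e_last + 1L):n
      dur <- as.integer(round(1.1 * mean(tl$Tf)))
      s <- pmin(1, (post - e_last) / dur)
      mtp_x[post] <- contacts$x[nrow(contacts)] + 2.4 * smooth5(s)
      mtp_z[post] <- 0.45 * sin(pi * s / 2)^0.8
      alpha[post] <- a_to + (55 * pi / 180 - a_to) * smooth3(s)
    }
    list(mtp_x = mtp_x, mtp_z = mtp_z, alpha = alpha, stance = stance)
  }
  # stances 0..3 alternate; the final stance belongs to the take-off side
  tol_contacts <- data.frame(start = tl$td[c(2, 4)], end = tl$TO[c(2, 4)],
                             x = xc[c(2, 4)])
  oth_contacts <- data.frame(start = tl$td[c(1, 3)], end = tl$TO[c(1, 3)],
                             x = xc[c(1, 3)])
  tol <- build(tol_contacts)
  oth <- build(oth_contacts)
  if (p$takeoff_side == "left") list(left = tol, right = oth)
  else list(left = oth, right = tol)
}

# Two-link inverse kinematics for one leg over all frames.
# hip: n x 2 (x, z) at that side's hip joint; foot track gives the toe and
# foot angle; during stance the foot pitch is raised as needed to keep the
# hip-ankle distance reachable (forefoot rises, toe anchored); during swing
# an unreachable ankle is pulled toward the hip and the toe follows.
leg_ik <- function(hip_x, hip_z, track, dims) {
  r <- dims$foot
  L1 <- dims$thigh; L2 <- dims$shank
  Lmax <- (L1 + L2) * (1 - 1e-9)
  alpha <- track$alpha
  mtp_x <- track$mtp_x; mtp_z <- track$mtp_z
  ank_x <- mtp_x - r * cos(alpha)
  ank_z <- mtp_z + r * sin(alpha)
  dx <- hip_x - ank_x; dz <- hip_z - ank_z
  d <- sqrt(dx^2 + dz^2)
  # stance feasibility: raise foot pitch until the leg can reach the ankle
  bad <- which(track$stance & d > Lmax)
  if (length(bad)) {
    a <- hip_x[bad] - mtp_x[bad]
    b <- hip_z[bad] - mtp_z[bad]
    K <- a^2 + b^2 + r^2
    R <- sqrt(a^2 + b^2)
    cstar <- (Lmax^2 - K) / (2 * r * R)
    phi <- atan2(b, a)
    psi <- acos(pmin(1, pmax(-1, cstar)))
    cand <- cbind(psi - phi, -psi - phi)
    amin <- 10 * pi / 180; amax <- 88 * pi / 180
    pick <- function(i) {
      cc <- cand[i, ]
      cc <- cc[cc > amin - 1e-9 & cc < amax + 1e-9]
      if (length(cc)) cc[which.min(abs(cc - alpha[bad[i]]))]
      else pi - phi[i]                     # fall back to the d-minimising pitch
    }
    anew <- vapply(seq_along(bad), pick, numeric(1))
    anew <- pmin(pmax(anew, amin), amax)
    alpha[bad] <- anew
    ank_x[bad] <- mtp_x[bad] - r * cos(anew)
    ank_z[bad] <- mtp_z[bad] + r * sin(anew)
    dx[bad] <- hip_x[bad] - ank_x[bad]
    dz[bad] <- hip_z[bad] - ank_z[bad]
    d[bad] <- sqrt(dx[bad]^2 + dz[bad]^2)
    still <- bad[d[bad] > Lmax + 1e-6]
    if (length(still))
      stop(sprintf(paste0("configuration error: stance leg cannot reach the ",
                          "anchored toe at frame %d (required %.3f m, leg %.3f m); ",
                          "check cm_height / step parameters"),
                   still[1], d[still[1]], L1 + L2))
  }
  # swing clamp: pull the airborne ankle toward the hip, toe follows
  over <- which(!track$stance & d > Lmax)
  if (length(over)) {
    sc <- Lmax / d[over]
    ank_x[over] <- hip_x[over] - dx[over] * sc
    ank_z[over] <- hip_z[over] - dz[over] * sc
    mtp_x[over] <- ank_x[over] + r * cos(alpha[over])
    mtp_z[over] <- ank_z[over] - r * sin(alpha[over])
    dx[over] <- hip_x[over] - ank_x[over]
    dz[over] <- hip_z[over] - ank_z[over]
    d[over] <- sqrt(dx[over]^2 + dz[over]^2)
  }
  d <- pmin(d, Lmax)
  # knee on the anterior side of the hip-ankle line
  ux <- -dx / d; uz <- -dz / d            # unit hip -> ankle
  px <- -uz; pz <- ux
  q <- (d^2 + L1^2 - L2^2) / (2 * d)
  h <- sqrt(pmax(L1^2 - q^2, 0))
  knee_x <- hip_x + ux * q + px * h
  knee_z <- hip_z + uz * q + pz * h
  list(knee_x = knee_x, knee_z = knee_z,
       ank_x = ank_x, ank_z = ank_z,
       mtp_x = mtp_x, mtp_z = mtp_z)
}

# assemble the full landmark array for given pelvis positions (vectorised
# over frames); returns n x 17 x 3 array
synth_assemble <- function(pel_x, pel_z, tracks, arms, trunk_lean_deg, dims) {
  n <- length(pel_x)
  lm <- landmark_names()
  co <- array(0, c(n, 17, 3), dimnames = list(NULL, lm, c("x", "y", "z")))
  hw <- dims$hip_halfwidth; sw <- dims$shoulder_halfwidth
  th <- trunk_lean_deg * pi / 180          # forward lean, + toward +X
  msh_x <- pel_x + dims$trunk * sin(th)
  msh_z <- pel_z + dims$trunk * cos(th)
  co[, "left_hip", ] <- cbind(pel_x, rep(hw, n), pel_z)
  co[, "right_hip", ] <- cbind(pel_x, rep(-hw, n), pel_z)
  co[, "left_shoulder", ] <- cbind(msh_x, rep(sw, n), msh_z)
  co[, "right_shoulder", ] <- cbind(msh_x, rep(-sw, n), msh_z)
  co[, "head_centre", ] <- cbind(msh_x + dims$neck * sin(th), rep(0, n),
                                 msh_z + dims$neck * cos(th))
  for (side in c("left", "right")) {
    y <- if (side == "left") hw else -hw
    ik <- leg_ik(pel_x, pel_z, tracks[[side]], dims)
    co[, paste0(side, "_knee"), ] <- cbind(ik$knee_x, rep(y, n), ik$knee_z)
    co[, paste0(side, "_ankle"), ] <- cbind(ik$ank_x, rep(y, n), ik$ank_z)
    co[, paste0(side, "_mtp"), ] <- cbind(ik$mtp_x, rep(y, n), ik$mtp_z)
    ya <- if (side == "left") sw else -sw
    ua <- arms[[side]]$upper * pi / 180    # angle of upper arm from downward vertical
    fa <- arms[[side]]$fore * pi / 180
    shx <- msh_x; shz <- msh_z
    el_x <- shx + dims$upper_arm * sin(ua)
    el_z <- shz - dims$upper_arm * cos(ua)
    wr_x <- el_x + dims$forearm * sin(fa)
    wr_z <- el_z - dims$forearm * cos(fa)
    mc_x <- wr_x + dims$hand * sin(fa)
    mc_z <- wr_z - dims$hand * cos(fa)
    co[, paste0(side, "_elbow"), ] <- cbind(el_x, rep(ya, n), el_z)
    co[, paste0(side, "_wrist"), ] <- cbind(wr_x, rep(ya, n), wr_z)
    co[, paste0(side, "_mcp"), ] <- cbind(mc_x, rep(ya, n), mc_z)
  }
  co
}

# whole-body CM of a raw coordinate array (internal fast path)
array_cm <- function(co, table) {
  defs <- segment_defs()
  n <- dim(co)[1]
  mid_sh <- (co[, "left_shoulder", ] + co[, "right_shoulder", ]) / 2
  mid_hip <- (co[, "left_hip", ] + co[, "right_hip", ]) / 2
  if (is.null(dim(mid_sh))) { mid_sh <- rbind(mid_sh); mid_hip <- rbind(mid_hip) }
  getp <- function(nm) {
    if (nm == "mid_shoulder") return(mid_sh)
    if (nm == "mid_hip") return(mid_hip)
    p <- co[, nm, , drop = FALSE][, 1, ]
    if (is.null(dim(p))) rbind(p) else p
  }
  cm <- matrix(0, n, 3)
  for (i in seq_along(defs)) {
    pr <- getp(defs[[i]]$prox); di <- getp(defs[[i]]$dist)
    cm <- cm + table$mass_fraction[i] * (pr + table$cm_ratio[i] * (di - pr))
  }
  cm
}

#' Generate a ground-truth synthetic vaulter trial
#'
#' Builds a kinematically consistent 17-landmark trajectory from a prescribed
#' CM path (per-step constant mean horizontal velocity, sinusoidal vertical
#' oscillation, vertical launch ramp through the final stance) plus
#' articulated limb profiles. The stance-foot toe is stationary at runway
#' height (z = 0) during every contact, and the whole-body de Leva CM of the
#' assembled body equals the prescribed path to machine precision.
#'
#' Ground-truth toe-off/touchdown frames and all 22 run-up/take-off variable
#' values are returned alongside the trajectory. Step lengths and mean step
#' velocities equal the input parameters exactly; instantaneous event
#' velocities are the central differences of the closed-form CM profile at
#' the event frames (the estimator the pipeline itself uses); joint angles
#' are evaluated on the noise-free trajectory.
#'
#' @param params a [synth_params()] object.
#' @return list of class `vault_ground_truth` with elements `trial`
#'   ([trial3d()], method `"TRUTH"`), `events` ([event_set()]), `variables`
#'   (data.frame variable/value/units) and `params`.
#' @export
generate_trial <- function(params) {
  p <- validate_synth_params(params)
  tl <- synth_timeline(p)
  dims <- body_dims(p$stature)
  t <- tl$t; dt <- tl$dt

  # contact positions: anchored at the take-off contact (a fixed distance
  # from the plant box at x = 0), spaced backward by the exact step lengths
  # so that step lengths hold by construction
  s <- p$step_lengths
  xc <- -3.0 - c(s[1] + s[2] + s[3], s[2] + s[3], s[3], 0)
  cmp <- synth_cm_path(p, tl, xc)

  tracks <- synth_foot_tracks(p, tl, xc)

  # arm carriage: both arms forward (pole carry), raised overhead through the
  # plant; mild cadence-locked swing
  t_pp <- t[tl$pp]; t_to <- t[tl$TO[4]]
  raise <- smooth3((t - t_pp) / max(t_to - t_pp, dt))
  wsw <- 2 * pi * p$cadence / 2
  arms <- list(
    left = list(upper = (38 + 7 * sin(wsw * t)) * (1 - raise) + 150 * raise),
    right = list(upper = (30 - 7 * sin(wsw * t)) * (1 - raise) + 145 * raise)
  )
  arms$left$fore <- arms$left$upper + 45 * (1 - raise) + 12 * raise
  arms$right$fore <- arms$right$upper + 50 * (1 - raise) + 12 * raise

  # trunk: slight forward lean easing to slight extension at take-off
  t_td3 <- t[tl$td[4]]
  lean <- 8 - 13 * smooth3((t - t_td3) / max(t_to - t_td3, dt))

  table <- segmental_table(p$athlete_sex)
  cm_x <- cmp$xfun(t); cm_z <- cmp$zfun(t)

  # fixed point: place the pelvis so the assembled body's CM matches the
  # prescribed path exactly
  pel_x <- cm_x; pel_z <- cm_z - 0.12
  co <- NULL
  for (it in 1:300) {
    co <- synth_assemble(pel_x, pel_z, tracks, arms, lean, dims)
    est <- array_cm(co, table)
    ex <- cm_x - est[, 1]; ez <- cm_z - est[, 3]
    pel_x <- pel_x + 0.9 * ex; pel_z <- pel_z + 0.9 * ez
    if (max(abs(ex), abs(ez)) < 1e-12) break
  }
  if (max(abs(ex), abs(ez)) > 1e-8)
    stop("configuration error: CM placement did not converge; parameters are kinematically inconsistent")

  trial <- trial3d(co, sample_rate = tl$fs, method = "TRUTH",
                   trial_id = sprintf("synth_seed%d", p$seed))
  events <- event_set(tl$TO, td_third_last = tl$td[2], pole_plant = tl$pp)

  # ground-truth variables
  v <- p$step_velocities
  cd <- function(f, tt) (f(tt + dt) - f(tt - dt)) / (2 * dt)  # central difference
  vx_pp <- cd(cmp$xfun, t_pp); vz_pp <- cd(cmp$zfun, t_pp)
  vx_to <- cd(cmp$xfun, t_to); vz_to <- cd(cmp$zfun, t_to)
  ja <- joint_angles(trial)[tl$TO[4], ]
  tol <- p$takeoff_side; dl <- setdiff(c("left", "right"), tol)
  vals <- c(
    avg_runway_velocity = sum(v * tl$Tf) / sum(tl$Tf),
    max_runway_velocity = max(v[1], v[2], cmp$v_pre),
    step_length_3rd_last = s[1], step_velocity_3rd_last = v[1],
    step_length_2nd_last = s[2], step_velocity_2nd_last = v[2],
    step_length_last = s[3], step_velocity_last = v[3],
    cm_height_pp = cmp$zfun(t_pp),
    cm_hor_velocity_pp = vx_pp, cm_vert_velocity_pp = vz_pp,
    standing_height = cmp$zfun(t_to),
    dl_hip_angle_to = unname(ja[paste0(dl, "_hip")]),
    dl_knee_angle_to = unname(ja[paste0(dl, "_knee")]),
    dl_ankle_angle_to = unname(ja[paste0(dl, "_ankle")]),
    tol_hip_angle_to = unname(ja[paste0(tol, "_hip")]),
    tol_knee_angle_to = unname(ja[paste0(tol, "_knee")]),
    tol_ankle_angle_to = unname(ja[paste0(tol, "_ankle")]),
    cm_hor_velocity_to = vx_to, cm_vert_velocity_to = vz_to,
    cm_abs_velocity_to = sqrt(vx_to^2 + vz_to^2),
    cm_takeoff_angle = atan2(vz_to, vx_to) * 180 / pi
  )
  cat_df <- variable_catalogue()
  variables <- data.frame(variable = cat_df$variable,
                          value = unname(vals[cat_df$variable]),
                          units = cat_df$units, stringsAsFactors = FALSE)
  structure(list(trial = trial, events = events, variables = variables,
                 params = p),
            class = "vault_ground_truth")
}

#' @export
print.vault_ground_truth <- function(x, ...) {
  cat(sprintf("<vault_ground_truth> %s (%s), take-off side %s\n",
              x$trial$trial_id, x$params$athlete_sex, x$params$takeoff_side))
  print(x$trial)
  invisible(x)
}

# normalise a method-offset spec to a 17 x 3 matrix
offsets_matrix <- function(offsets) {
  lm <- landmark_names()
  M <- matrix(0, 17, 3, dimnames = list(lm, c("x", "y", "z")))
  if (is.null(offsets)) return(M)
  if (is.matrix(offsets)) {
    stopifnot(nrow(offsets) == 17, ncol(offsets) == 3)
    M[, ] <- offsets
    return(M)
  }
  if (is.numeric(offsets) && length(offsets) == 3) {
    M[, ] <- matrix(offsets, 17, 3, byrow = TRUE)
    return(M)
  }
  if (is.list(offsets)) {
    for (nm in names(offsets)) {
      if (!nm %in% lm) stop("unknown landmark in offsets: ", nm)
      M[nm, ] <- offsets[[nm]]
    }
    return(M)
  }
  stop("offsets must be NULL, a length-3 vector, a 17x3 matrix, or a named list")
}

#' Degrade a trial to emulate an alternative tracking method
#'
#' Applies per-landmark systematic 3D shifts, then adds zero-mean Gaussian
#' noise per frame/landmark/axis, emulating the landmark-identification
#' discrepancies of a markerless tracker relative to the reference.
#'
#' @param truth a `vault_ground_truth` or a [trial3d()].
#' @param offsets systematic shifts, metres: `NULL` (none), a length-3 vector
#'   applied to all landmarks, a named list of length-3 vectors, or a `17 x 3`
#'   matrix.
#' @param noise_sd isotropic noise SD, metres (>= 0).
#' @param seed integer seed.
#' @param method method tag for the degraded copy.
#' @return A [trial3d()].
#' @export
degrade_as_method <- function(truth, offsets = NULL, noise_sd = 0,
                              seed = 1L, method = "ML") {
  trial <- if (inherits(truth, "vault_ground_truth")) truth$trial else truth
  stopifnot(inherits(trial, "trial3d"), noise_sd >= 0)
  M <- offsets_matrix(offsets)
  co <- trial$coords
  n <- dim(co)[1]
  co <- co + aperm(array(M, c(17, 3, n)), c(3, 1, 2))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    co <- co + array(rnorm(length(co), sd = noise_sd), dim = dim(co))
  }
  out <- trial
  out$coords <- co
  out$method <- method
  out
}

#' Project a trial into a camera rig
#'
#' Applies the DLT projection equations camera by camera. Landmarks outside a
#' camera's 2048x1536 frame are flagged not visible (never silently clipped);
#' a point behind a camera raises a geometry error. Gaussian pixel noise is
#' added to visible observations.
#'
#' @param trial a [trial3d()].
#' @param cameras list of [camera_dlt()] (default: [default_camera_rig()]).
#' @param pixel_noise_sd pixel noise SD.
#' @param seed integer seed.
#' @return list (one element per camera) of lists with `n x 17` matrices `u`,
#'   `v` and logical `visible`.
#' @export
project_to_cameras <- function(trial, cameras = default_camera_rig(),
                               pixel_noise_sd = 0, seed = 1L) {
  n <- n_frames(trial)
  pts <- matrix(aperm(trial$coords, c(1, 2, 3)), n * 17, 3)
  set.seed(as.integer(seed))
  lapply(cameras, function(cam) {
    prj <- dlt_project(cam, pts, behind = "error")
    u <- matrix(prj$u, n, 17); v <- matrix(prj$v, n, 17)
    vis <- matrix(prj$visible, n, 17)
    if (pixel_noise_sd > 0) {
      u <- u + matrix(rnorm(n * 17, sd = pixel_noise_sd), n, 17)
      v <- v + matrix(rnorm(n * 17, sd = pixel_noise_sd), n, 17)
    }
    colnames(u) <- colnames(v) <- colnames(vis) <- landmark_names()
    list(u = u, v = v, visible = vis)
  })
}

#' Synthetic control points with exact per-camera projections
#'
#' Non-coplanar points spanning the capture volume (by default the last
#' 12-15 m of the runway): the 8 slightly inset corners of the volume first,
#' then seeded uniform interior points.
#'
#' @param volume list with numeric ranges `x`, `y`, `z` (metres).
#' @param n number of points (>= 6).
#' @param cameras camera rig used to generate the exact projections.
#' @param seed integer seed for interior points.
#' @return A [control_points()] object.
#' @export
make_control_points <- function(volume = list(x = c(-13, 0), y = c(-1.2, 1.2),
                                              z = c(0, 2.4)),
                                n = 12, cameras = default_camera_rig(),
                                seed = 1L) {
  if (n < 6) stop("need at least 6 control points")
  ext <- vapply(volume[c("x", "y", "z")], function(r) diff(range(r)), numeric(1))
  if (any(ext <= 1e-9))
    stop("degenerate control-point volume: zero extent makes points coplanar")
  inset <- function(r) r + c(1, -1) * 0.02 * diff(r)
  rx <- inset(volume$x); ry <- inset(volume$y); rz <- inset(volume$z)
  corners <- as.matrix(expand.grid(x = rx, y = ry, z = rz))
  set.seed(as.integer(seed))
  if (n <= 8) {
    pts <- corners[seq_len(n), , drop = FALSE]
  } else {
    extra <- cbind(stats::runif(n - 8, rx[1], rx[2]),
                   stats::runif(n - 8, ry[1], ry[2]),
                   stats::runif(n - 8, rz[1], rz[2]))
    pts <- rbind(corners, extra)
  }
  colnames(pts) <- c("x", "y", "z")
  obs <- lapply(cameras, function(cam) {
    prj <- dlt_project(cam, pts, behind = "error")
    data.frame(u = prj$u, v = prj$v)
  })
  control_points(pts, obs)
}

#' Write / read synthetic parameters as YAML
#'
#' @param params a [synth_params()] object.
#' @param path file path.
#' @return `write_synth_params` returns `path` invisibly; `read_synth_params`
#'   returns a [synth_params()] object.
#' @export
write_synth_params <- function(params, path) {
  obj <- unclass(params)
  obj$method_offsets <- if (is.null(obj$method_offsets)) NULL else
    as.list(as.data.frame(t(offsets_matrix(obj$method_offsets))))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synth_params
#' @export
read_synth_params <- function(path) {
  o <- yaml::read_yaml(path)
  off <- o$method_offsets
  if (!is.null(off)) off <- lapply(off, as.numeric)
  synth_params(athlete_sex = o$athlete_sex,
               step_lengths = as.numeric(o$step_lengths),
               step_velocities = as.numeric(o$step_velocities),
               cm_height = o$cm_height, cm_oscillation = o$cm_oscillation,
               cadence = o$cadence, duty_factor = o$duty_factor,
               launch_velocity = o$launch_velocity,
               pole_plant_offset = o$pole_plant_offset,
               stature = o$stature, takeoff_side = o$takeoff_side,
               noise_sd_3d = o$noise_sd_3d, method_offsets = off,
               pixel_noise_sd = o$pixel_noise_sd,
               lead_frames = o$lead_frames, trail_frames = o$trail_frames,
               pad_frames = o$pad_frames, sample_rate = o$sample_rate,
               seed = o$seed)
}

#' Write control points and observations as CSV
#'
#' @param cps a [control_points()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_control_points_csv <- function(cps, path) {
  d <- as.data.frame(cps$points)
  for (i in seq_along(cps$observations)) {
    d[[sprintf("cam%d_u", i)]] <- cps$observations[[i]]$u
    d[[sprintf("cam%d_v", i)]] <- cps$observations[[i]]$v
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
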