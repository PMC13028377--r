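# de Leva segmental model: whole-body centre of mass and sagittal joint
# angles from the 17 tracked landmarks.

# Segment definitions on the 17-landmark set. The trunk runs mid-shoulder to
# mid-hip; the head is a point mass at the tracked head centre; the foot axis
# is ankle -> MTP (no heel is tracked), with its CM ratio re-based to that
# axis.
segment_defs <- function() {
  list(
    head          = list(prox = "head_centre", dist = "head_centre"),
    trunk         = list(prox = "mid_shoulder", dist = "mid_hip"),
    left_upper_arm  = list(prox = "left_shoulder",  dist = "left_elbow"),
    right_upper_arm = list(prox = "right_shoulder", dist = "right_elbow"),
    left_forearm    = list(prox = "left_elbow",  dist = "left_wrist"),
    right_forearm   = list(prox = "right_elbow", dist = "right_wrist"),
    left_hand       = list(prox = "left_wrist",  dist = "left_mcp"),
    right_hand      = list(prox = "right_wrist", dist = "right_mcp"),
    left_thigh      = list(prox = "left_hip",  dist = "left_knee"),
    right_thigh     = list(prox = "right_hip", dist = "right_knee"),
    left_shank      = list(prox = "left_knee",  dist = "left_ankle"),
    right_shank     = list(prox = "right_knee", dist = "right_ankle"),
    left_foot       = list(prox = "left_ankle",  dist = "left_mtp"),
    right_foot      = list(prox = "right_ankle", dist = "right_mtp")
  )
}

#' Body-segment inertial parameter table (de Leva)
#'
#' Mass fractions and longitudinal centre-of-mass ratios (fraction of segment
#' length from the proximal endpoint) for the adjusted de Leva (1996)
#' body-segment inertial parameters, by sex. Paired segments carry half of the
#' per-side fraction on each side. Printed mass fractions do not sum exactly
#' to one (rounding in the original tables), so the fractions are renormalised
#' so that they sum to 1 within 1e-12.
#'
#' The foot CM ratio is re-based to the ankle-to-MTP axis used here (no heel
#' landmark is tracked) and set to 0.5 of that axis; the head is a point mass
#' at the tracked head centre.
#'
#' @param sex `"male"` or `"female"`.
#' @return data.frame with columns `segment`, `mass_fraction`, `cm_ratio`,
#'   `sex`; one row per segment (head, trunk, and paired upper arms,
#'   forearms, hands, thighs, shanks, feet), mass fractions summing to 1.
#' @export
segmental_table <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  # per-segment values: head, trunk, upper arm, forearm, hand, thigh, shank,
  # foot (mass %, CM ratio from proximal)
  if (sex == "male") {
    mass <- c(head = 6.94, trunk = 43.46, upper_arm = 2.71, forearm = 1.62,
              hand = 0.61, thigh = 14.16, shank = 4.33, foot = 1.37)
    cmr <- c(head = 0, trunk = 0.4486, upper_arm = 0.5772, forearm = 0.4574,
             hand = 0.7900, thigh = 0.4095, shank = 0.4459, foot = 0.5)
  } else {
    mass <- c(head = 6.68, trunk = 42.57, upper_arm = 2.55, forearm = 1.38,
              hand = 0.56, thigh = 14.78, shank = 4.81, foot = 1.29)
    cmr <- c(head = 0, trunk = 0.4151, upper_arm = 0.5754, forearm = 0.4559,
             hand = 0.7474, thigh = 0.3612, shank = 0.4416, foot = 0.5)
  }
  segs <- names(segment_defs())
  base <- sub("^(left|right)_", "", segs)
  mf <- mass[base] / 100
  mf <- mf / sum(mf)   # renormalise printed rounding to sum exactly to 1
  data.frame(segment = segs, mass_fraction = unname(mf),
             cm_ratio = unname(cmr[base]), sex = sex,
             stringsAsFactors = FALSE)
}

# virtual landmark positions (n x 3): mid_shoulder / mid_hip plus the raw 17
virtual_points <- function(trial) {
  co <- trial$coords
  list(
    mid_shoulder = (co[, "left_shoulder", ] + co[, "right_shoulder", ]) / 2,
    mid_hip      = (co[, "left_hip", ] + co[, "right_hip", ]) / 2
  )
}

point_of <- function(trial, vp, name) {
  if (name %in% names(vp)) {
    p <- vp[[name]]
  } else {
    p <- trial$coords[, name, ]
  }
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p
}

#' Whole-body centre of mass
#'
#' Per frame, each segment CM is `proximal + cm_ratio * (distal - proximal)`
#' and the whole-body CM is the mass-fraction-weighted sum of segment CMs.
#'
#' @param trial a [trial3d()] object with all 17 landmarks present.
#' @param table a [segmental_table()]; defaults to the male table.
#' @return `n x 3` matrix (columns x, y, z), metres.
#' @export
whole_body_cm <- function(trial, table = segmental_table("male")) {
  miss <- which(trial$missing, arr.ind = TRUE)
  if (nrow(miss) > 0) {
    bad <- unique(colnames(trial$missing)[miss[, 2]])
    stop(sprintf("missing landmarks in analysis window: %s (e.g. frame %d)",
                 paste(bad, collapse = ", "), miss[1, 1]))
  }
  defs <- segment_defs()
  stopifnot(identical(table$segment, names(defs)))
  vp <- virtual_points(trial)
  n <- n_frames(trial)
  cm <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (i in seq_along(defs)) {
    prox <- point_of(trial, vp, defs[[i]]$prox)
    dist <- point_of(trial, vp, defs[[i]]$dist)
    seg_cm <- prox + table$cm_ratio[i] * (dist - prox)
    cm <- cm + table$mass_fraction[i] * seg_cm
  }
  cm
}

# signed angle (degrees) from vector a to vector b in the sagittal X-Z plane,
# positive when b lies on the forward (+X) side of a for a downward a
sagittal_signed_angle <- function(ax, az, bx, bz) {
  atan2(az * bx - ax * bz, ax * bx + az * bz) * 180 / pi
}

# unsigned included angle (degrees) between projected vectors
sagittal_included_angle <- function(ax, az, bx, bz) {
  na <- sqrt(ax^2 + az^2)
  nb <- sqrt(bx^2 + bz^2)
  cosv <- (ax * bx + az * bz) / (na * nb)
  out <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  out[na < 1e-12 | nb < 1e-12] <- NA_real_
  out
}

#' Sagittal-plane joint angles
#'
#' Hip, knee and ankle angles per side, computed from segment longitudinal
#' axes projected onto the global X-Z (sagittal) plane:
#' \itemize{
#'   \item hip: 180 degrees plus the signed angle between the downward trunk
#'     extension (mid-shoulder to mid-hip direction) and the thigh axis
#'     (hip to knee); thigh flexed forward of the trunk line gives < 180,
#'     hyperextension gives > 180 (no wrap-around).
#'   \item knee: 180 degrees minus the included angle between thigh and shank
#'     axes (180 = full extension, as in anatomical standing).
#'   \item ankle: included angle at the joint between the shank and foot
#'     axes (the vectors from the ankle to the knee and from the ankle to the
#'     MTP), no offset: about 90 degrees in standing, increasing with plantar
#'     flexion (typically 120-135 at toe-off).
#' }
#' Assumes progression toward +X (runway frame). Frames where a projected
#' segment has zero length are flagged `NA`.
#'
#' @param trial a [trial3d()] object.
#' @return `n x 6` matrix, degrees; columns
#'   `left_hip, right_hip, left_knee, right_knee, left_ankle, right_ankle`.
#' @export
joint_angles <- function(trial) {
  co <- trial$coords
  vp <- virtual_points(trial)
  # downward trunk extension: mid-shoulder -> mid-hip
  tdx <- vp$mid_hip[, "x"] - vp$mid_shoulder[, "x"]
  tdz <- vp$mid_hip[, "z"] - vp$mid_shoulder[, "z"]
  n <- n_frames(trial)
  out <- matrix(NA_real_, n, 6,
                dimnames = list(NULL, c("left_hip", "right_hip", "left_knee",
                                        "right_knee", "left_ankle", "right_ankle")))
  for (side in c("left", "right")) {
    hip <- co[, paste0(side, "_hip"), , drop = FALSE][, 1, ]
    knee <- co[, paste0(side, "_knee"), , drop = FALSE][, 1, ]
    ank <- co[, paste0(side, "_ankle"), , drop = FALSE][, 1, ]
    mtp <- co[, paste0(side, "_mtp"), , drop = FALSE][, 1, ]
    if (is.null(dim(hip))) { # n == 1
      hip <- rbind(hip); knee <- rbind(knee); ank <- rbind(ank); mtp <- rbind(mtp)
    }
    thx <- knee[, 1] - hip[, 1];  thz <- knee[, 3] - hip[, 3]
    shx <- ank[, 1] - knee[, 1];  shz <- ank[, 3] - knee[, 3]
    # at-joint axes for the ankle: ankle -> knee and ankle -> MTP
    skx <- knee[, 1] - ank[, 1];  skz <- knee[, 3] - ank[, 3]
    fox <- mtp[, 1] - ank[, 1];   foz <- mtp[, 3] - ank[, 3]
    tn <- sqrt(tdx^2 + tdz^2); thn <- sqrt(thx^2 + thz^2)
    hip_ang <- 180 + sagittal_signed_angle(tdx, tdz, thx, thz)
    hip_ang[tn < 1e-12 | thn < 1e-12] <- NA_real_
    knee_ang <- 180 - sagittal_included_angle(thx, thz, shx, shz)
    ank_ang <- sagittal_included_angle(skx, skz, fox, foz)
    out[, paste0(side, "_hip")] <- hip_ang
    out[, paste0(side, "_knee")] <- knee_ang
    out[, paste0(side, "_ankle")] <- ank_ang
  }
  out
}

#' Identify take-off and drive legs
#'
#' The take-off leg (TOL) is the side whose toe is the stance toe of the final
#' ground contact before the body leaves the ground; the drive leg (DL) is the
#' other side.
#'
#' @param events an [event_set()] with a valid `take_off` frame.
#' @param trial the [trial3d()] the events belong to.
#' @param height_threshold stance toe height threshold, metres.
#' @param speed_threshold stance toe horizontal speed threshold, m/s.
#' @return list with elements `take_off_leg` and `drive_leg` (`"left"`/`"right"`).
#' @export
leg_roles <- function(events, trial, height_threshold = 0.02,
                      speed_threshold = 0.8) {
  fr <- events$take_off
  win <- max(1, fr - 5):fr
  score <- vapply(c("left", "right"), function(side) {
    mask <- clean_mask(toe_contact_mask(trial, side, height_threshold,
                                        speed_threshold))
    sum(mask[win])
  }, numeric(1))
  if (score["left"] == score["right"])
    stop("ambiguous stance at take-off: expected exactly one foot in contact")
  tol <- names(score)[which.max(score)]
  list(take_off_leg = tol, drive_leg = setdiff(c("left", "right"), tol))
}
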