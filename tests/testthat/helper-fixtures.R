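# Shared fixtures, built in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

# default ground-truth trial for one sex (expensive; cached)
default_truth <- function(sex = "male") {
  key <- paste0("gt_", sex)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_trial(synth_params(athlete_sex = sex))
  .fixture_cache[[key]]
}

# static posture trial: n identical frames of a configurable sagittal pose.
# Defaults give anatomical standing with horizontal feet (ankle angle 90).
posture_trial <- function(n = 5, thigh_fwd_deg = 0, hip_w = 0.09, sh_w = 0.17,
                          foot_perp = TRUE) {
  lm <- landmark_names()
  co <- array(0, c(n, 17, 3), dimnames = list(NULL, lm, c("x", "y", "z")))
  Lth <- 0.46; Lsh <- 0.46; Lft <- 0.17
  hip_z <- 1.00
  a <- thigh_fwd_deg * pi / 180
  d_th <- c(sin(a), -cos(a))                # thigh direction (x, z), downward
  knee <- c(Lth * d_th[1], hip_z + Lth * d_th[2])
  ank <- c(knee[1] + Lsh * d_th[1], knee[2] + Lsh * d_th[2])  # straight knee
  ft <- if (foot_perp) c(-d_th[2], d_th[1]) else c(1, 0)      # perp to shank
  mtp <- c(ank[1] + Lft * ft[1], ank[2] + Lft * ft[2])
  set_pt <- function(name, x, y, z) for (i in seq_len(n)) co[i, name, ] <<- c(x, y, z)
  for (s in c(1, -1)) {
    side <- if (s == 1) "left" else "right"
    set_pt(paste0(side, "_hip"), 0, s * hip_w, hip_z)
    set_pt(paste0(side, "_knee"), knee[1], s * hip_w, knee[2])
    set_pt(paste0(side, "_ankle"), ank[1], s * hip_w, ank[2])
    set_pt(paste0(side, "_mtp"), mtp[1], s * hip_w, mtp[2])
    set_pt(paste0(side, "_shoulder"), 0, s * sh_w, 1.50)
    set_pt(paste0(side, "_elbow"), 0, s * sh_w, 1.20)
    set_pt(paste0(side, "_wrist"), 0, s * sh_w, 0.95)
    set_pt(paste0(side, "_mcp"), 0, s * sh_w, 0.87)
  }
  set_pt("head_centre", 0, 0, 1.72)
  trial3d(co, sample_rate = 100, method = "POSE", trial_id = "posture")
}

# random (asymmetric) posture for oracle comparisons
random_posture_trial <- function(n = 4, seed = 1) {
  set.seed(seed)
  tr <- posture_trial(n)
  tr$coords <- tr$coords + array(stats::runif(length(tr$coords), -0.2, 0.2),
                                 dim = dim(tr$coords))
  tr
}

# independent brute-force whole-body CM: recompute landmark-by-landmark with
# explicit loops, no shared code with whole_body_cm()
bruteforce_cm <- function(trial, table) {
  co <- trial$coords
  n <- dim(co)[1]
  ends <- list(
    head = c("head_centre", "head_centre"),
    trunk = c("mid_shoulder", "mid_hip"),
    left_upper_arm = c("left_shoulder", "left_elbow"),
    right_upper_arm = c("right_shoulder", "right_elbow"),
    left_forearm = c("left_elbow", "left_wrist"),
    right_forearm = c("right_elbow", "right_wrist"),
    left_hand = c("left_wrist", "left_mcp"),
    right_hand = c("right_wrist", "right_mcp"),
    left_thigh = c("left_hip", "left_knee"),
    right_thigh = c("right_hip", "right_knee"),
    left_shank = c("left_knee", "left_ankle"),
    right_shank = c("right_knee", "right_ankle"),
    left_foot = c("left_ankle", "left_mtp"),
    right_foot = c("right_ankle", "right_mtp")
  )
  getpt <- function(i, nm) {
    if (nm == "mid_shoulder")
      return((co[i, "left_shoulder", ] + co[i, "right_shoulder", ]) / 2)
    if (nm == "mid_hip") return((co[i, "left_hip", ] + co[i, "right_hip", ]) / 2)
    co[i, nm, ]
  }
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    acc <- c(0, 0, 0)
    for (k in seq_along(ends)) {
      seg <- names(ends)[k]
      row <- which(table$segment == seg)
      p <- getpt(i, ends[[k]][1]); q <- getpt(i, ends[[k]][2])
      acc <- acc + table$mass_fraction[row] * (p + table$cm_ratio[row] * (q - p))
    }
    out[i, ] <- acc
  }
  out
}

# ICC(3,1) oracle via stats::aov mean squares
icc_oracle_aov <- function(ref, alt) {
  n <- length(ref)
  d <- data.frame(value = c(ref, alt),
                  trial = factor(rep(seq_len(n), 2)),
                  method = factor(rep(c("r", "a"), each = n)))
  sm <- summary(stats::aov(value ~ trial + method, data = d))[[1]]
  msr <- sm["trial", "Mean Sq"]
  mse <- sm["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (2 - 1) * mse)
}
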