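# Trial container: time-stamped 3D trajectories of the 17 canonical landmarks
# tracked in run-up/take-off analyses.

#' The 17 canonical landmark names
#'
#' Centre of the head plus left and right shoulder, elbow, wrist,
#' metacarpo-phalangeal (MCP), hip, knee, ankle and metatarso-phalangeal (MTP)
#' joint centres.
#'
#' @return Character vector of length 17.
#' @export
landmark_names <- function() {
  c("head_centre",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_mcp", "right_mcp",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_mtp", "right_mtp")
}

#' Construct a trial of 3D landmark trajectories
#'
#' Global frame convention: X points along the runway toward the plant box,
#' Z is vertical (up), Y is mediolateral completing a right-handed frame;
#' the runway plane is Z = 0.
#'
#' @param coords numeric array `n_frames x 17 x 3`; second dimension named by
#'   [landmark_names()], third dimension named `c("x","y","z")`, metres.
#' @param sample_rate sampling rate, Hz.
#' @param method method tag, e.g. `"REF"` or `"ML"`.
#' @param trial_id trial identifier.
#' @param time optional time stamps (seconds); defaults to `(0:(n-1))/sample_rate`.
#' @param missing optional `n_frames x 17` logical matrix flagging landmarks
#'   that could not be reconstructed.
#' @return An object of class `trial3d`.
#' @export
trial3d <- function(coords, sample_rate = 100, method = "REF",
                    trial_id = "trial1", time = NULL, missing = NULL) {
  lm <- landmark_names()
  stopifnot(is.array(coords), length(dim(coords)) == 3L,
            dim(coords)[2] == 17L, dim(coords)[3] == 3L)
  if (is.null(dimnames(coords)[[2]])) dimnames(coords)[[2]] <- lm
  if (!identical(dimnames(coords)[[2]], lm))
    stop("landmark dimension must be named exactly by landmark_names()")
  dimnames(coords)[[3]] <- c("x", "y", "z")
  n <- dim(coords)[1]
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  stopifnot(length(time) == n)
  if (is.null(missing)) {
    missing <- matrix(FALSE, n, 17, dimnames = list(NULL, lm))
  }
  structure(list(coords = coords, time = time, sample_rate = sample_rate,
                 method = method, trial_id = trial_id, missing = missing),
            class = "trial3d")
}

#' @export
print.trial3d <- function(x, ...) {
  cat(sprintf("<trial3d> %s [%s]: %d frames @ %g Hz, %d landmarks",
              x$trial_id, x$method, dim(x$coords)[1], x$sample_rate, 17L))
  nmiss <- sum(x$missing)
  if (nmiss > 0) cat(sprintf(", %d missing observations", nmiss))
  cat("\n")
  invisible(x)
}

#' Number of frames in a trial
#' @param trial a [trial3d()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(trial) dim(trial$coords)[1]

# extract one landmark as an n x 3 matrix
landmark_xyz <- function(trial, name) {
  trial$coords[, name, , drop = FALSE][, 1, ]
}

#' Convert a trial to long format
#'
#' @param trial a [trial3d()] object.
#' @return data.frame with columns frame, time_s, landmark, x_m, y_m, z_m,
#'   method, trial_id.
#' @export
trial_to_long <- function(trial) {
  n <- n_frames(trial)
  lm <- landmark_names()
  data.frame(
    frame = rep(seq_len(n), times = 17),
    time_s = rep(trial$time, times = 17),
    landmark = rep(lm, each = n),
    x_m = as.vector(trial$coords[, , "x"]),
    y_m = as.vector(trial$coords[, , "y"]),
    z_m = as.vector(trial$coords[, , "z"]),
    method = trial$method,
    trial_id = trial$trial_id,
    stringsAsFactors = FALSE
  )
}

#' Write / read a trial as long-format CSV
#'
#' @param trial a [trial3d()] object.
#' @param path file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a [trial3d()] object.
#' @export
write_trial_csv <- function(trial, path) {
  write.csv(trial_to_long(trial), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param sample_rate sampling rate used to rebuild the trial (Hz).
#' @export
read_trial_csv <- function(path, sample_rate = 100) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lm <- landmark_names()
  frames <- sort(unique(d$frame))
  n <- length(frames)
  coords <- array(NA_real_, c(n, 17, 3), dimnames = list(NULL, lm, c("x", "y", "z")))
  for (l in lm) {
    dl <- d[d$landmark == l, ]
    dl <- dl[order(dl$frame), ]
    coords[, l, "x"] <- dl$x_m
    coords[, l, "y"] <- dl$y_m
    coords[, l, "z"] <- dl$z_m
  }
  tm <- tapply(d$time_s, d$frame, function(v) v[1])
  trial3d(coords, sample_rate = sample_rate, method = d$method[1],
          trial_id = d$trial_id[1], time = as.numeric(tm))
}

#' Write a trial in TRC-style text format
#'
#' Minimal TRC writer (header block plus tab-separated frames) so trajectories
#' can be inspected in standard motion-capture tools.
#'
#' @param trial a [trial3d()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trial, path) {
  n <- n_frames(trial)
  fs <- trial$sample_rate
  lm <- landmark_names()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines("DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames", con)
  writeLines(sprintf("%g\t%g\t%d\t%d\tm\t%g\t1\t%d", fs, fs, n, 17L, fs, n), con)
  hdr <- c("Frame#", "Time", as.vector(rbind(lm, "", "")))
  writeLines(paste(hdr, collapse = "\t"), con)
  sub <- c("", "", as.vector(t(outer(seq_along(lm), c("X", "Y", "Z"),
                                     function(i, a) paste0(a, i)))))
  writeLines(paste(sub, collapse = "\t"), con)
  writeLines("", con)
  for (i in seq_len(n)) {
    row <- c(i, format(trial$time[i], digits = 10),
             format(as.vector(t(trial$coords[i, , ])), digits = 10))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
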