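# Rule-based gait event detection from toe (MTP) trajectories.

# Contact mask for one side's toe: low height AND low horizontal speed.
# Speed is the smaller of the forward and backward one-sided differences, so
# that the touchdown frame (still preceded by swing motion) and the toe-off
# frame (already followed by swing motion) both count as contact.
toe_contact_mask <- function(trial, side, height_threshold = 0.02,
                             speed_threshold = 0.8) {
  toe <- landmark_xyz(trial, paste0(side, "_mtp"))
  n <- nrow(toe)
  dt <- 1 / trial$sample_rate
  dx <- abs(diff(toe[, 1])) / dt
  fwd <- c(dx, Inf)
  bwd <- c(Inf, dx)
  toe[, 3] < height_threshold & pmin(fwd, bwd) < speed_threshold
}

# morphological cleaning of a logical contact mask: bridge short FALSE gaps
# between contacts, then drop short TRUE runs (isolated noise hits)
clean_mask <- function(mask, min_run = 3L, max_gap = 2L) {
  r <- rle(mask)
  if (max_gap > 0 && length(r$lengths) > 2) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    fill <- interior[!r$values[interior] & r$lengths[interior] <= max_gap]
    r$values[fill] <- TRUE
    mask <- inverse.rle(r)
    r <- rle(mask)
  }
  drop <- r$values & r$lengths < min_run
  r$values[drop] <- FALSE
  inverse.rle(r)
}

#' Detect toe-off and touchdown events
#'
#' A toe is in ground contact when its height is below `height_threshold` AND
#' its horizontal speed is below `speed_threshold`. Toe-off is the last
#' contact frame of a stance, touchdown the first. The last four toe-offs
#' across both feet define the analysed window (start of the 3rd-last step
#' through take-off). The pole is untracked, so the pole-plant frame is taken
#' from `pole_plant` (ground truth or config); by default it is placed
#' `pole_plant_offset` frames before take-off.
#'
#' Detection is intended to run on unfiltered toe trajectories: low-pass
#' filtering rounds the contact corner and can shift contact edges by a frame.
#'
#' @param trial a [trial3d()].
#' @param height_threshold toe height threshold, metres.
#' @param speed_threshold toe horizontal speed threshold, m/s.
#' @param pole_plant pole-plant frame index, if known.
#' @param pole_plant_offset frames before take-off used when `pole_plant` is
#'   `NULL`.
#' @param min_contact_frames contacts shorter than this are treated as noise.
#' @param max_gap_frames gaps in a contact up to this length are bridged.
#' @return An [event_set()].
#' @export
detect_events <- function(trial, height_threshold = 0.02,
                          speed_threshold = 0.8,
                          pole_plant = NULL, pole_plant_offset = 14L,
                          min_contact_frames = 3L, max_gap_frames = 2L) {
  runs_for <- function(side) {
    contact <- toe_contact_mask(trial, side, height_threshold, speed_threshold)
    contact <- clean_mask(contact, min_contact_frames, max_gap_frames)
    r <- rle(contact)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(start = starts[keep], end = ends[keep],
               side = rep(side, length(keep)), stringsAsFactors = FALSE)
  }
  runs <- rbind(runs_for("left"), runs_for("right"))
  runs <- runs[order(runs$end), ]
  if (nrow(runs) < 4)
    stop(sprintf("fewer than 4 toe-offs found in window (%d contacts detected)",
                 nrow(runs)))
  last4 <- runs[(nrow(runs) - 3):nrow(runs), ]
  toe_offs <- last4$end
  td3 <- last4$start[2]
  take_off <- toe_offs[4]
  pp <- if (is.null(pole_plant)) take_off - as.integer(pole_plant_offset)
        else as.integer(pole_plant)
  ev <- event_set(toe_offs, td_third_last = td3, pole_plant = pp)
  attr(ev, "stance_sides") <- last4$side
  ev
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> toe-offs: %s | td 3rd-last: %d | pole plant: %d | take-off: %d\n",
              paste(x$toe_offs, collapse = ", "),
              x$td_third_last, x$pole_plant, x$take_off))
  invisible(x)
}
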