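# Filtering and differentiation of kinematic time series.

#' Filter specification for kinematic series
#'
#' @param sample_rate sampling rate, Hz.
#' @param cutoff low-pass cutoff frequency, Hz; must satisfy
#'   `0 < cutoff < sample_rate / 2`.
#' @param pad_frames number of padding frames digitised before and after the
#'   sequence of interest; used to absorb filter initialisation and optionally
#'   trimmed from the analysis window.
#' @return list of class `series_spec`.
#' @export
series_spec <- function(sample_rate = 100, cutoff = 20, pad_frames = 10) {
  stopifnot(sample_rate > 0, cutoff > 0, cutoff < sample_rate / 2,
            pad_frames >= 0)
  structure(list(sample_rate = sample_rate, cutoff = cutoff,
                 pad_frames = as.integer(pad_frames)),
            class = "series_spec")
}

# zero-phase second-order Butterworth on one numeric vector.
# Odd-reflection padding at both ends absorbs the zero-state transient of the
# recursive filter; pad length is sized from the pole radius so the residual
# transient is below machine precision, then trimmed.
zero_phase_butter <- function(x, bf) {
  n <- length(x)
  pr <- max(Mod(polyroot(rev(bf$a))))
  np <- ceiling(log(1e-16) / log(max(pr, 1e-6)))
  np <- min(max(np, 12L), n - 1L)
  left <- 2 * x[1] - x[seq(np + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(left, x, right)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1):(np + n)]
}

#' Zero-lag low-pass Butterworth filter
#'
#' A second-order low-pass Butterworth filter applied forward and backward
#' (dual pass, zero phase lag). No cutoff-frequency correction is applied for
#' the dual pass: the stated cutoff is the design cutoff of the single-pass
#' filter, following common biomechanics practice. The `pad_frames` at each
#' end of the series absorb filter initialisation; with `trim = TRUE` they are
#' removed from the returned series.
#'
#' @param x numeric vector, or matrix/3D array filtered column-wise along the
#'   first (time) dimension.
#' @param spec a [series_spec()].
#' @param trim if `TRUE`, drop `spec$pad_frames` frames from each end of the
#'   output.
#' @return Filtered series with the same shape as `x` (minus trimmed frames).
#' @export
butterworth_lowpass <- function(x, spec = series_spec(), trim = FALSE) {
  dims <- dim(x)
  n <- if (is.null(dims)) length(x) else dims[1]
  if (n <= 3 * 2 + 2 * spec$pad_frames)
    stop(sprintf("series too short to filter: %d frames (need > %d)",
                 n, 3 * 2 + 2 * spec$pad_frames))
  bf <- signal::butter(2, spec$cutoff / (spec$sample_rate / 2), type = "low")
  if (is.null(dims)) {
    y <- zero_phase_butter(x, bf)
  } else {
    xm <- matrix(x, nrow = n)
    ym <- apply(xm, 2, zero_phase_butter, bf = bf)
    y <- array(ym, dim = dims, dimnames = dimnames(x))
  }
  if (trim && spec$pad_frames > 0) {
    keep <- seq(spec$pad_frames + 1, n - spec$pad_frames)
    y <- if (is.null(dims)) y[keep] else {
      if (length(dims) == 2) y[keep, , drop = FALSE] else y[keep, , , drop = FALSE]
    }
  }
  y
}

#' Filter all landmark coordinates of a trial
#'
#' Filtering is applied at the coordinate level, before any derived quantity
#' (CM, joint angles, velocities) is computed.
#'
#' @param trial a [trial3d()] object.
#' @param spec a [series_spec()].
#' @return A [trial3d()] with filtered coordinates.
#' @export
filter_trial <- function(trial, spec = series_spec(sample_rate = trial$sample_rate)) {
  trial$coords <- butterworth_lowpass(trial$coords, spec, trim = FALSE)
  trial
}

#' First derivative of a sampled series
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param x numeric vector or matrix (columns differentiated independently).
#' @param sample_rate sampling rate, Hz.
#' @return Series of first derivatives, units of `x` per second.
#' @export
differentiate <- function(x, sample_rate) {
  if (is.matrix(x)) return(apply(x, 2, differentiate, sample_rate = sample_rate))
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  dt <- 1 / sample_rate
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}
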