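# Two-method agreement battery: Bland-Altman bias / random error / limits of
# agreement, RMSE, ICC(3,1), waveform CMD, interpretation bands and heatmap
# values.

#' Paired two-method sample for one variable
#'
#' @param ref_values per-trial values from the reference method.
#' @param alt_values same trials, alternative method (trial-aligned).
#' @param variable variable name.
#' @param units units label.
#' @return list of class `paired_sample`.
#' @export
paired_sample <- function(ref_values, alt_values, variable = "variable",
                          units = "") {
  stopifnot(length(ref_values) == length(alt_values), length(ref_values) >= 2)
  structure(list(ref = as.numeric(ref_values), alt = as.numeric(alt_values),
                 variable = variable, units = units),
            class = "paired_sample")
}

#' Limits of agreement from bias and random error
#'
#' `LOA = bias +/- random_error`, where the random error is the LOA half-width
#' (1.96 x SD of the paired differences).
#'
#' @param bias mean paired difference.
#' @param random_error LOA half-width.
#' @return list with `low`, `high`.
#' @export
loa_from_bias_re <- function(bias, random_error) {
  list(low = bias - random_error, high = bias + random_error)
}

#' Bias, random error and limits of agreement
#'
#' Paired differences are `d_i = ref_i - alt_i` (reference minus alternative).
#' Bias is `mean(d)`; random error is `1.96 x` the sample SD of `d`
#' (`n - 1` denominator); the limits of agreement are `bias +/- random error`.
#' Inputs are rounded to `round_dp` decimals before computing (3 by default,
#' matching the convention of reporting LOA from data to 3 decimal places);
#' set `round_dp = NULL` for full precision.
#'
#' @param sample a [paired_sample()].
#' @param round_dp decimals to round the inputs to, or `NULL`.
#' @return list of class `agreement_row` with `bias`, `random_error`,
#'   `loa_low`, `loa_high`, `n` (plus `rmse`, `icc_3_1` slots filled by
#'   [agreement_row()]).
#' @export
bias_loa <- function(sample, round_dp = 3) {
  if (length(sample$ref) < 2) stop("need at least 2 paired trials")
  ref <- sample$ref; alt <- sample$alt
  if (!is.null(round_dp)) {
    ref <- round(ref, round_dp); alt <- round(alt, round_dp)
  }
  d <- ref - alt
  bias <- mean(d)
  re <- 1.96 * sd(d)
  loa <- loa_from_bias_re(bias, re)
  structure(list(variable = sample$variable, units = sample$units,
                 bias = bias, random_error = re,
                 loa_low = loa$low, loa_high = loa$high,
                 rmse = NA_real_, icc_3_1 = NA_real_, n = length(d)),
            class = "agreement_row")
}

#' Root mean square error between paired methods
#'
#' `sqrt(mean(d_i^2))` with `d_i = ref_i - alt_i`, full precision; combines
#' systematic and random error (`rmse^2 = bias^2 + population variance of d`).
#'
#' @param sample a [paired_sample()].
#' @return numeric RMSE.
#' @export
rmse_paired <- function(sample) {
  d <- sample$ref - sample$alt
  sqrt(mean(d^2))
}

#' ICC(3,1): two-way mixed, single measure, consistency
#'
#' From the two-way ANOVA decomposition of the `n x 2` trials-by-methods
#' table (no interaction): `(MS_rows - MS_error) / (MS_rows + (k-1) MS_error)`
#' with `k = 2` methods. Insensitive to a fixed offset between methods.
#'
#' @param sample a [paired_sample()] with at least 3 trials.
#' @return numeric ICC; `NA` (with a warning) when the between-trial variance
#'   is zero and the coefficient is undefined.
#' @export
icc_3_1 <- function(sample) {
  x <- cbind(sample$ref, sample$alt)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 trials for ICC(3,1)")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  # residual SS computed directly from the two-way residuals (numerically
  # stable when the residuals are tiny relative to the totals)
  resid <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ss_rows < 1e-300 * max(ss_tot, 1)) {
    warning("ICC(3,1) undefined: zero between-trial variance")
    return(NA_real_)
  }
  if (ms_err <= 0) return(1)
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Coefficient of multiple determination (CMD) between two waveforms
#'
#' The R-squared of an ordinary least-squares simple linear regression of the
#' alternative waveform on the reference over the trial's frames. CMD measures
#' shape similarity on a 0-1 scale and is blind to amplitude: any affine map
#' `alt = a * ref + b` (`a != 0`) scores 1. (The simple-regression R-squared is
#' symmetric in the two inputs, so the regression direction is cosmetic.)
#'
#' @param waveform_ref,waveform_alt equal-length numeric vectors (length >= 3).
#' @return numeric in `[0, 1]`; `NA` (flagged by a warning) if either waveform
#'   has zero variance.
#' @export
cmd <- function(waveform_ref, waveform_alt) {
  stopifnot(length(waveform_ref) == length(waveform_alt),
            length(waveform_ref) >= 3)
  x <- waveform_ref - mean(waveform_ref)
  y <- waveform_alt - mean(waveform_alt)
  sxx <- sum(x^2); syy <- sum(y^2)
  if (sxx <= 0 || syy <= 0) {
    warning("CMD undefined: zero-variance waveform")
    return(NA_real_)
  }
  r2 <- sum(x * y)^2 / (sxx * syy)
  min(max(r2, 0), 1)
}

#' Interpretation band for ICC / CMD values
#'
#' Koo-Li style bands: below 0.50 poor, 0.50-0.75 moderate, 0.75-0.90 good,
#' 0.90-1.00 excellent; boundary values belong to the upper band; negative
#' values (possible for ICC) map to "poor".
#'
#' @param value numeric vector of ICC or CMD values.
#' @return character vector of band labels.
#' @export
interpret_agreement <- function(value) {
  out <- character(length(value))
  out[value < 0.50] <- "poor"
  out[value >= 0.50 & value < 0.75] <- "moderate"
  out[value >= 0.75 & value < 0.90] <- "good"
  out[value >= 0.90] <- "excellent"
  out[is.na(value)] <- NA_character_
  out
}

#' Full agreement row for one variable
#'
#' @param sample a [paired_sample()].
#' @param round_dp rounding applied to bias/LOA inputs (see [bias_loa()]).
#' @return An `agreement_row` with bias, random error, LOA, RMSE and ICC(3,1).
#' @export
agreement_row <- function(sample, round_dp = 3) {
  row <- bias_loa(sample, round_dp = round_dp)
  row$rmse <- rmse_paired(sample)
  row$icc_3_1 <- if (length(sample$ref) >= 3) {
    tryCatch(icc_3_1(sample), warning = function(w) NA_real_)
  } else NA_real_
  row
}

#' @export
print.agreement_row <- function(x, ...) {
  cat(sprintf("%s [%s] n=%d: bias %.3f, random error %.3f, LOA [%.3f, %.3f], RMSE %.3f, ICC(3,1) %s\n",
              x$variable, x$units, x$n, x$bias, x$random_error,
              x$loa_low, x$loa_high, x$rmse,
              ifelse(is.na(x$icc_3_1), "NA", sprintf("%.3f", x$icc_3_1))))
  invisible(x)
}

#' Agreement table over matched variable tables
#'
#' @param ref_table,alt_table per-trial variable tables: data.frames with
#'   columns `trial_id`, `variable`, `value`, `units`.
#' @param round_dp rounding for bias/LOA (see [bias_loa()]).
#' @return data.frame with one row per variable: bias, random error, LOA,
#'   RMSE, ICC(3,1), interpretation band and n.
#' @export
agreement_table <- function(ref_table, alt_table, round_dp = 3) {
  vars <- unique(ref_table$variable)
  if (!setequal(vars, unique(alt_table$variable)))
    stop("unmatched variable sets between methods")
  rows <- lapply(vars, function(v) {
    r <- ref_table[ref_table$variable == v, ]
    a <- alt_table[alt_table$variable == v, ]
    a <- a[match(r$trial_id, a$trial_id), ]
    if (any(is.na(a$value)) && !any(is.na(r$value)))
      stop("unmatched trials for variable ", v)
    s <- paired_sample(r$value, a$value, variable = v, units = r$units[1])
    row <- agreement_row(s, round_dp = round_dp)
    data.frame(variable = v, units = row$units, n = row$n, bias = row$bias,
               random_error = row$random_error, loa_low = row$loa_low,
               loa_high = row$loa_high, rmse = row$rmse,
               icc_3_1 = row$icc_3_1,
               icc_band = interpret_agreement(row$icc_3_1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Signed heatmap values: alternative minus reference
#'
#' Per-variable mean difference `alt - ref` (the negative of the bias), the
#' convention used when visualising whether the alternative method over- or
#' under-estimates each variable.
#'
#' @param ref_table,alt_table per-trial variable tables (see
#'   [agreement_table()]).
#' @return data.frame with columns `variable`, `mean_difference`.
#' @export
heatmap_values <- function(ref_table, alt_table) {
  vars <- unique(ref_table$variable)
  if (!setequal(vars, unique(alt_table$variable)))
    stop("unmatched variable sets between methods")
  md <- vapply(vars, function(v) {
    r <- ref_table[ref_table$variable == v, ]
    a <- alt_table[alt_table$variable == v, ]
    a <- a[match(r$trial_id, a$trial_id), ]
    mean(a$value - r$value)
  }, numeric(1))
  data.frame(variable = vars, mean_difference = unname(md),
             stringsAsFactors = FALSE)
}

#' Waveform agreement (CMD) across trials
#'
#' @param ref_waves,alt_waves lists (one element per trial) of
#'   `waveform_set` objects from [extract_waveforms()], sharing identical
#'   windows per trial.
#' @param channel channel name, e.g. `"cm_z"` or `"angle_left_knee"`.
#' @return list of class `waveform_agreement` with `cmd_per_trial`,
#'   `cmd_mean`, `cmd_sd`, `band`, `channel`.
#' @export
waveform_agreement <- function(ref_waves, alt_waves, channel) {
  stopifnot(length(ref_waves) == length(alt_waves))
  cmds <- vapply(seq_along(ref_waves), function(i) {
    r <- ref_waves[[i]]$channels[[channel]]
    a <- alt_waves[[i]]$channels[[channel]]
    if (!identical(ref_waves[[i]]$frames, alt_waves[[i]]$frames))
      stop("methods do not share the same frame window for trial ", i)
    cmd(r, a)
  }, numeric(1))
  m <- mean(cmds, na.rm = TRUE)
  structure(list(cmd_per_trial = cmds, cmd_mean = m,
                 cmd_sd = sd(cmds[!is.na(cmds)]),
                 band = interpret_agreement(m), channel = channel),
            class = "waveform_agreement")
}
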