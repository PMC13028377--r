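# Configuration, orchestration and report generation for the full
# reference-vs-alternative comparison and the test-retest reliability
# use-case.

#' Pipeline configuration
#'
#' @param mode input mode: `"synthetic"` (trials generated internally),
#'   `"trajectories"` (trials supplied as [trial3d()] pairs) — camera
#'   observations can be reconstructed first with
#'   [dlt_reconstruct_trial()] and supplied as trajectories.
#' @param method_labels length-2 character: reference then alternative label.
#' @param n_trials number of trials (synthetic mode).
#' @param sexes per-trial sex vector, recycled to `n_trials`.
#' @param ml_offsets systematic per-landmark shifts applied to the
#'   alternative method (see [degrade_as_method()]).
#' @param ml_noise_sd,ref_noise_sd isotropic landmark noise SD per method,
#'   metres.
#' @param jitter_velocity,jitter_step,jitter_cm_height between-trial SDs used
#'   to vary the synthetic athletes (m/s, m, m).
#' @param cutoff,pad_frames,sample_rate filter settings (see [series_spec()]).
#' @param variables optional subset of variable names to report.
#' @param seed integer master seed.
#' @param out_dir optional output directory for the report bundle.
#' @param trials `trajectories` mode: list of lists with elements `ref`,
#'   `alt` ([trial3d()]), `sex`, optional `pole_plant`.
#' @return list of class `pipeline_config`.
#' @export
comparison_config <- function(mode = c("synthetic", "trajectories"),
                              method_labels = c("REF", "ML"),
                              n_trials = 8,
                              sexes = rep(c("male", "female"), each = 4),
                              ml_offsets = default_ml_offsets(),
                              ml_noise_sd = 0.003,
                              ref_noise_sd = 0.001,
                              jitter_velocity = 0.25,
                              jitter_step = 0.06,
                              jitter_cm_height = 0.015,
                              cutoff = 20, pad_frames = 10, sample_rate = 100,
                              variables = NULL,
                              seed = 1L, out_dir = NULL, trials = NULL) {
  mode <- match.arg(mode)
  if (mode == "trajectories" && is.null(trials))
    stop("config error: mode 'trajectories' requires a 'trials' list")
  stopifnot(length(method_labels) == 2)
  structure(list(mode = mode, method_labels = method_labels,
                 n_trials = as.integer(n_trials),
                 sexes = rep(sexes, length.out = n_trials),
                 ml_offsets = ml_offsets, ml_noise_sd = ml_noise_sd,
                 ref_noise_sd = ref_noise_sd,
                 jitter_velocity = jitter_velocity, jitter_step = jitter_step,
                 jitter_cm_height = jitter_cm_height,
                 cutoff = cutoff, pad_frames = pad_frames,
                 sample_rate = sample_rate, variables = variables,
                 seed = as.integer(seed), out_dir = out_dir, trials = trials),
            class = "pipeline_config")
}

#' Default systematic degradation of the alternative method
#'
#' A small anterior-superior shift of the distal landmarks plus a global
#' vertical offset, emulating the landmark-identification discrepancies of a
#' markerless tracker (largest at distal joints).
#'
#' @return `17 x 3` offset matrix, metres.
#' @export
default_ml_offsets <- function() {
  off <- list()
  for (s in c("left", "right")) {
    off[[paste0(s, "_ankle")]] <- c(0.012, 0, 0.006)
    off[[paste0(s, "_mtp")]] <- c(0.008, 0, 0.004)
    off[[paste0(s, "_knee")]] <- c(0.008, 0, 0.004)
    off[[paste0(s, "_hip")]] <- c(-0.006, 0, -0.008)
  }
  M <- offsets_matrix(off)
  M[, 3] <- M[, 3] - 0.005       # global vertical under-estimate
  M
}

# draw per-trial synthetic parameters around the sex defaults
draw_trial_params <- function(config, i) {
  sex <- config$sexes[i]
  base <- synth_params(athlete_sex = sex)
  dv <- rnorm(1, 0, config$jitter_velocity) + rnorm(3, 0, 0.04)
  ds <- rnorm(3, 0, config$jitter_step)
  synth_params(athlete_sex = sex,
               step_lengths = pmax(base$step_lengths + ds, 1.2),
               step_velocities = pmax(base$step_velocities + dv, 5),
               cm_height = base$cm_height + rnorm(1, 0, config$jitter_cm_height),
               launch_velocity = max(base$launch_velocity + rnorm(1, 0, 0.12), 1),
               seed = config$seed + i)
}

# draw a feasible synthetic athlete, resampling draws whose jittered
# parameters are kinematically inconsistent
draw_feasible_trial <- function(config, i, max_tries = 25L) {
  for (k in seq_len(max_tries)) {
    pars <- draw_trial_params(config, i)
    gt <- tryCatch(generate_trial(pars), error = function(e) NULL)
    if (!is.null(gt)) return(gt)
  }
  stop("could not draw a feasible synthetic trial after ", max_tries, " tries")
}

#' Analyse one trial: filter, CM, angles, events, variables, waveforms
#'
#' Event detection and toe-position reads use the unfiltered trial (contact
#' corners survive); CM, joint angles and all velocities come from the
#' filtered coordinates.
#'
#' @param trial a [trial3d()].
#' @param sex `"male"` or `"female"` (selects the segmental table).
#' @param events optional shared [event_set()]; detected from this trial when
#'   `NULL`.
#' @param pole_plant pole-plant frame passed to [detect_events()].
#' @param spec a [series_spec()].
#' @return list with `events`, `cm`, `angles`, `roles`, `variables`,
#'   `waveforms`.
#' @export
analyze_trial <- function(trial, sex = "male", events = NULL,
                          pole_plant = NULL,
                          spec = series_spec(sample_rate = trial$sample_rate)) {
  if (is.null(events)) {
    events <- detect_events(trial, pole_plant = pole_plant)
  }
  filt <- filter_trial(trial, spec)
  cm <- whole_body_cm(filt, segmental_table(sex))
  angles <- joint_angles(filt)
  roles <- leg_roles(events, trial)
  vars <- extract_variables(cm, angles, trial, events, roles)
  waves <- extract_waveforms(cm, angles, events, sample_rate = trial$sample_rate)
  list(events = events, cm = cm, angles = angles, roles = roles,
       variables = vars, waveforms = waves)
}

#' Run the full two-method comparison
#'
#' Executes the pipeline end to end: (synthetic mode) generate ground-truth
#' trials and degrade them into a reference and an alternative copy, or
#' (trajectories mode) take supplied trial pairs; then filter, compute CM and
#' joint angles, detect events on the reference (both methods share the
#' identical frame window per trial), extract the 22 variables and the
#' analysis-window waveforms, and compute descriptives, the per-variable
#' agreement table, waveform CMD summaries and heatmap values.
#'
#' @param config a [comparison_config()].
#' @return list of class `vault_comparison` with `descriptives`, `agreement`,
#'   `cmd`, `heatmap`, `variables` (long per-trial table), `events`,
#'   `waveforms_ref`, `waveforms_alt`, `truth_variables` (synthetic mode),
#'   `config`. When `config$out_dir` is set the report bundle (CSV + JSON +
#'   log) is written there.
#' @export
run_comparison <- function(config = comparison_config()) {
  labels <- config$method_labels
  spec <- series_spec(sample_rate = config$sample_rate,
                      cutoff = config$cutoff, pad_frames = config$pad_frames)
  set.seed(config$seed)
  n <- config$n_trials
  ref_tabs <- list(); alt_tabs <- list(); truth_tabs <- list()
  waves_ref <- list(); waves_alt <- list(); ev_rows <- list()
  for (i in seq_len(n)) {
    if (config$mode == "synthetic") {
      truth <- draw_feasible_trial(config, i)
      pars <- truth$params
      sex <- pars$athlete_sex
      tid <- sprintf("trial%02d", i)
      ref <- degrade_as_method(truth, offsets = NULL,
                               noise_sd = config$ref_noise_sd,
                               seed = config$seed + 1000L + i, method = labels[1])
      alt <- degrade_as_method(truth, offsets = config$ml_offsets,
                               noise_sd = config$ml_noise_sd,
                               seed = config$seed + 2000L + i, method = labels[2])
      ref$trial_id <- alt$trial_id <- tid
      pp <- truth$events$pole_plant
      tv <- truth$variables; tv$trial_id <- tid; tv$sex <- sex
      truth_tabs[[i]] <- tv
    } else {
      tr <- config$trials[[i]]
      ref <- tr$ref; alt <- tr$alt; sex <- tr$sex %||% "male"
      pp <- tr$pole_plant
      # trial ids must be unique across the batch for trial-aligned pairing
      tid <- sprintf("%s_%02d", ref$trial_id, i)
      ref$trial_id <- alt$trial_id <- tid
      if (n_frames(ref) != n_frames(alt))
        stop("unmatched trials across methods for ", tid)
    }
    events <- detect_events(ref, pole_plant = pp)
    ar <- analyze_trial(ref, sex = sex, events = events, spec = spec)
    aa <- analyze_trial(alt, sex = sex, events = events, spec = spec)
    vr <- ar$variables; vr$trial_id <- tid; vr$sex <- sex; vr$method <- labels[1]
    va <- aa$variables; va$trial_id <- tid; va$sex <- sex; va$method <- labels[2]
    ref_tabs[[i]] <- vr; alt_tabs[[i]] <- va
    waves_ref[[i]] <- ar$waveforms; waves_alt[[i]] <- aa$waveforms
    ev_rows[[i]] <- data.frame(trial_id = tid,
                               toe_off_1 = events$toe_offs[1],
                               toe_off_2 = events$toe_offs[2],
                               toe_off_3 = events$toe_offs[3],
                               toe_off_4 = events$toe_offs[4],
                               td_third_last = events$td_third_last,
                               pole_plant = events$pole_plant,
                               take_off = events$take_off,
                               stringsAsFactors = FALSE)
  }
  ref_tab <- do.call(rbind, ref_tabs)
  alt_tab <- do.call(rbind, alt_tabs)
  if (!is.null(config$variables)) {
    ref_tab <- ref_tab[ref_tab$variable %in% config$variables, ]
    alt_tab <- alt_tab[alt_tab$variable %in% config$variables, ]
  }
  vars_long <- rbind(ref_tab, alt_tab)

  desc <- descriptives_table(vars_long)
  agr <- agreement_table(ref_tab, alt_tab)
  heat <- heatmap_values(ref_tab, alt_tab)
  channels <- names(waves_ref[[1]]$channels)
  cmd_tab <- do.call(rbind, lapply(channels, function(ch) {
    wa <- waveform_agreement(waves_ref, waves_alt, ch)
    data.frame(channel = ch, cmd_mean = wa$cmd_mean, cmd_sd = wa$cmd_sd,
               band = wa$band, stringsAsFactors = FALSE)
  }))
  out <- structure(list(descriptives = desc, agreement = agr, cmd = cmd_tab,
                        heatmap = heat, variables = vars_long,
                        events = do.call(rbind, ev_rows),
                        waveforms_ref = waves_ref, waveforms_alt = waves_alt,
                        truth_variables = if (length(truth_tabs))
                          do.call(rbind, truth_tabs) else NULL,
                        config = config),
                   class = "vault_comparison")
  if (!is.null(config$out_dir)) write_report_bundle(out, config$out_dir)
  out
}

#' @export
print.vault_comparison <- function(x, ...) {
  cat(sprintf("<vault_comparison> %d trials, methods %s vs %s\n",
              length(unique(x$variables$trial_id)),
              x$config$method_labels[1], x$config$method_labels[2]))
  cat("Agreement (per variable):\n")
  print(format(x$agreement, digits = 3), row.names = FALSE)
  invisible(x)
}

# Table-4-style descriptives: mean +/- SD overall and by sex, per method
descriptives_table <- function(vars_long) {
  groups <- list(ALL = c("male", "female"), MEN = "male", WOMEN = "female")
  rows <- list()
  for (g in names(groups)) {
    sub <- vars_long[vars_long$sex %in% groups[[g]], ]
    if (nrow(sub) == 0) next
    agg_m <- aggregate(value ~ variable + units + method, data = sub, FUN = mean)
    agg_s <- aggregate(value ~ variable + units + method, data = sub, FUN = sd)
    agg_m$sd <- agg_s$value[match(paste(agg_m$variable, agg_m$method),
                                  paste(agg_s$variable, agg_s$method))]
    agg_m$group <- g
    names(agg_m)[names(agg_m) == "value"] <- "mean"
    rows[[g]] <- agg_m[, c("variable", "units", "group", "method", "mean", "sd")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test-retest reliability report
#'
#' Compares two same-method tracking passes over one trial: RMSE and ICC(3,1)
#' per variable. Step lengths pair the three steps; CM height, CM velocities
#' and the take-off-leg joint angles pair frame-by-frame over the analysis
#' window (touchdown of the 3rd-last step to take-off).
#'
#' @param pass1,pass2 [trial3d()] objects: two digitising passes of the same
#'   trial. Supplying only one pass is an error.
#' @param sex segmental table selector.
#' @param pole_plant optional pole-plant frame.
#' @param spec a [series_spec()].
#' @return data.frame with columns `variable`, `units`, `rmse`, `icc_3_1`, `n`.
#' @export
run_retest <- function(pass1, pass2 = NULL, sex = "male", pole_plant = NULL,
                       spec = series_spec(sample_rate = pass1$sample_rate)) {
  if (is.null(pass2))
    stop("test-retest requires two tracking passes over the same trial")
  if (n_frames(pass1) != n_frames(pass2))
    stop("passes must cover the same frames")
  events <- detect_events(pass1, pole_plant = pole_plant)
  a1 <- analyze_trial(pass1, sex = sex, events = events, spec = spec)
  a2 <- analyze_trial(pass2, sex = sex, events = events, spec = spec)
  tol <- a1$roles$take_off_leg
  win_pairs <- list(
    cm_vert_height = c("cm_z", "m"),
    cm_hor_velocity = c("cm_velocity_x", "m/s"),
    cm_vert_velocity = c("cm_velocity_z", "m/s"),
    hip_angle = c(paste0("angle_", tol, "_hip"), "deg"),
    knee_angle = c(paste0("angle_", tol, "_knee"), "deg"),
    ankle_angle = c(paste0("angle_", tol, "_ankle"), "deg")
  )
  sl1 <- a1$variables$value[grep("^step_length", a1$variables$variable)]
  sl2 <- a2$variables$value[grep("^step_length", a2$variables$variable)]
  rows <- list(data.frame(
    variable = "step_length", units = "m",
    rmse = rmse_paired(paired_sample(sl1, sl2)),
    icc_3_1 = icc_3_1(paired_sample(sl1, sl2)),
    n = length(sl1), stringsAsFactors = FALSE))
  for (v in names(win_pairs)) {
    ch <- win_pairs[[v]][1]; un <- win_pairs[[v]][2]
    s <- paired_sample(a1$waveforms$channels[[ch]],
                       a2$waveforms$channels[[ch]], variable = v, units = un)
    rows[[v]] <- data.frame(variable = v, units = un,
                            rmse = rmse_paired(s), icc_3_1 = icc_3_1(s),
                            n = length(s$ref), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the comparison report bundle
#'
#' CSV tables (descriptives, agreement, CMD, heatmap, per-trial variables,
#' events), a JSON summary and a run log with ISO timestamps, seed and package
#' version. Re-running with the same config and seed reproduces byte-identical
#' CSV output.
#'
#' @param comparison a `vault_comparison` from [run_comparison()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(comparison, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(comparison$descriptives, "descriptives.csv")
  wr(comparison$agreement, "agreement.csv")
  wr(comparison$cmd, "cmd.csv")
  wr(comparison$heatmap, "heatmap.csv")
  wr(comparison$variables, "variables.csv")
  wr(comparison$events, "events.csv")
  summary <- list(
    n_trials = length(unique(comparison$variables$trial_id)),
    methods = comparison$config$method_labels,
    seed = comparison$config$seed,
    agreement = comparison$agreement,
    cmd = comparison$cmd
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log <- c(
    sprintf("%s | vaultkin %s | run_comparison", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            as.character(utils::packageVersion("vaultkin"))),
    sprintf("mode=%s n_trials=%d seed=%d cutoff=%g Hz",
            comparison$config$mode,
            length(unique(comparison$variables$trial_id)),
            comparison$config$seed, comparison$config$cutoff)
  )
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Overlay waveforms of the two methods
#'
#' Reference trials in black, alternative in red (solid mean, dashed
#' individual trials), over the shared analysis window.
#'
#' @param waves_ref,waves_alt lists of `waveform_set` objects (time-normalised
#'   copies are used so trials of different durations overlay).
#' @param channel channel name.
#' @param main plot title.
#' @return `NULL`, invisibly (draws on the active device).
#' @export
plot_waveform_overlay <- function(waves_ref, waves_alt, channel,
                                  main = channel) {
  s <- seq(0, 100, length.out = 101)
  mr <- sapply(waves_ref, function(w) w$normalised[[channel]])
  ma <- sapply(waves_alt, function(w) w$normalised[[channel]])
  ylim <- range(mr, ma, na.rm = TRUE)
  graphics::plot(s, rowMeans(mr), type = "l", col = "black", lwd = 2,
                 ylim = ylim, xlab = "window (%)", ylab = channel, main = main)
  for (j in seq_len(ncol(mr))) graphics::lines(s, mr[, j], col = "black", lty = 2)
  for (j in seq_len(ncol(ma))) graphics::lines(s, ma[, j], col = "red", lty = 2)
  graphics::lines(s, rowMeans(ma), col = "red", lwd = 2)
  invisible(NULL)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields matching [comparison_config()] arguments.
#' @return A [comparison_config()].
#' @export
read_comparison_config <- function(path) {
  o <- yaml::read_yaml(path)
  args <- o[intersect(names(o), names(formals(comparison_config)))]
  if (!is.null(args$ml_offsets)) args$ml_offsets <-
      offsets_matrix(lapply(args$ml_offsets, as.numeric))
  do.call(comparison_config, args)
}
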