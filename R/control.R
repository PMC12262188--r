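# Closed-loop feedback control: per-acquisition cumulative-map update,
# control-ROI statistic, threshold decision, and UC/SC/USC classification.

#' Feedback control configuration
#'
#' @param threshold_log10 Control threshold on the log10-scaled ROI-average
#'   cumulative decorrelation (default -2.8, the 90%-specificity cutoff of
#'   the emulated study).
#' @param roi_center_mm Center of the spherical control ROI (default the
#'   grid center, i.e. the needle tip).
#' @param roi_diameter_mm Control ROI diameter (default 20 mm, the targeted
#'   ablation zone).
#' @param statistic_mode `"mean-then-log"` (default: log10 of the ROI mean of
#'   linear decorrelation) or `"log-then-mean"` (ROI mean of log10 values).
#' @return An object of class `control_config`.
#' @export
control_config <- function(threshold_log10 = -2.8,
                           roi_center_mm = c(0, 0, 0),
                           roi_diameter_mm = 20,
                           statistic_mode = c("mean-then-log",
                                              "log-then-mean")) {
  statistic_mode <- match.arg(statistic_mode)
  if (roi_diameter_mm <= 0)
    stop("roi_diameter_mm must be positive", call. = FALSE)
  if (!is.finite(threshold_log10))
    stop("threshold must be finite", call. = FALSE)
  structure(list(threshold_log10 = threshold_log10,
                 roi_center_mm = roi_center_mm,
                 roi_diameter_mm = roi_diameter_mm,
                 statistic_mode = statistic_mode),
            class = "control_config")
}

#' Control-ROI statistic of a cumulative decorrelation map
#'
#' The spatial average of cumulative decorrelation over the control ROI, on
#' the log10 scale. With `mode = "mean-then-log"` (default) the linear values
#' are averaged first and the mean is log-scaled; `"log-then-mean"` averages
#' the per-voxel log10 values. An all-zero map yields `-Inf` (no trigger).
#'
#' @param cum A `cumulative_map`.
#' @param roi_mask Logical array (or `ablation_mask`) selecting ROI voxels.
#' @param mode Statistic mode, see above.
#' @return Scalar log10-scaled statistic (possibly `-Inf`).
#' @export
roi_statistic <- function(cum, roi_mask,
                          mode = c("mean-then-log", "log-then-mean")) {
  mode <- match.arg(mode)
  if (inherits(roi_mask, "ablation_mask")) roi_mask <- roi_mask$mask
  vals <- cum$delta[roi_mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("control ROI is empty or entirely invalid", call. = FALSE)
  if (mode == "mean-then-log") {
    m <- mean(vals)
    if (m <= 0) -Inf else log10(m)
  } else {
    lv <- ifelse(vals <= 0, -Inf, log10(vals))
    mean(lv)
  }
}

#' One step of the feedback control loop
#'
#' Updates the cumulative map with the new instantaneous map, recomputes the
#' control-ROI statistic, and decides whether to cease treatment: in
#' controlled mode the loop stops as soon as the statistic reaches or exceeds
#' the threshold; in uncontrolled mode it never stops.
#'
#' @param state List with elements `cum` (a `cumulative_map`) and `roi_mask`.
#' @param inst A `decorr_map` for the current acquisition.
#' @param config A [control_config()].
#' @param mode `"controlled"` or `"uncontrolled"`.
#' @return List with updated `state`, the `statistic`, and `stop` flag.
#' @export
control_step <- function(state, inst, config,
                         mode = c("controlled", "uncontrolled")) {
  mode <- match.arg(mode)
  state$cum <- update_cumulative(state$cum, inst)
  statistic <- roi_statistic(state$cum, state$roi_mask,
                             config$statistic_mode)
  stop_flag <- (mode == "controlled") &&
    (statistic >= config$threshold_log10)
  list(state = state, statistic = statistic, stop = stop_flag)
}

#' Run the feedback control loop over a simulated trial
#'
#' Processes a trial's echo pairs in acquisition order: each pair is
#' scan-converted, its instantaneous decorrelation map computed and folded
#' into the cumulative map, and the control-ROI statistic compared to the
#' threshold. A controlled run that reaches the threshold before the cycle
#' end stops there and is labeled SC; a controlled run that never reaches it
#' is USC; an uncontrolled run always completes the cycle and is labeled UC.
#'
#' @param dataset A `trial_dataset` from [simulate_trial()].
#' @param config A [control_config()].
#' @param mode `"controlled"` or `"uncontrolled"`.
#' @param window A [window_spec()].
#' @param beta_bar_mode Passed to [instantaneous_decorrelation()].
#' @param verbose Emit one log line per acquisition.
#' @return An object of class `trial_record` with fields `mode`, `label`
#'   (`"UC"`, `"SC"` or `"USC"`), `stop_time_s` (`NA` unless SC),
#'   `duration_min`, `series` (per-acquisition data frame of time, statistic
#'   and decision), `final_cum` (the final `cumulative_map`) and
#'   `final_roi_log10`.
#' @export
run_trial <- function(dataset, config = control_config(),
                      mode = c("controlled", "uncontrolled"),
                      window = window_spec(), beta_bar_mode = "valid",
                      verbose = FALSE) {
  mode <- match.arg(mode)
  grid <- dataset$grid
  roi <- sphere_mask(grid, config$roi_center_mm, config$roi_diameter_mm,
                     provenance = "target")
  state <- list(cum = empty_cumulative(grid), roi_mask = roi$mask)
  times <- numeric(0); stats <- numeric(0); stops <- logical(0)
  stop_time <- NA_real_
  for (pair in dataset$pairs) {
    inst <- pair_decorrelation(pair, dataset$geometry, grid,
                               dataset$apex_mm, window, beta_bar_mode)
    st <- control_step(state, inst, config, mode)
    state <- st$state
    times <- c(times, pair$acquisition_time_s)
    stats <- c(stats, st$statistic)
    stops <- c(stops, st$stop)
    if (verbose)
      message(sprintf("[control] t=%6.1f s  statistic=%8.3f  %s",
                      pair$acquisition_time_s, st$statistic,
                      if (st$stop) "STOP" else "continue"))
    if (st$stop) { stop_time <- pair$acquisition_time_s; break }
  }
  cycle_s <- dataset$config$cycle_duration_s
  label <- if (mode == "uncontrolled") "UC"
           else if (!is.na(stop_time) && stop_time < cycle_s) "SC"
           else "USC"
  duration_min <- if (label == "SC") stop_time / 60 else cycle_s / 60
  structure(list(mode = mode, label = label,
                 stop_time_s = if (label == "SC") stop_time else NA_real_,
                 duration_min = duration_min,
                 series = data.frame(time_s = times, statistic = stats,
                                     stopped = stops),
                 final_cum = state$cum,
                 final_roi_log10 = stats[length(stats)],
                 threshold_log10 = config$threshold_log10),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s (%s), duration %.2f min, final ROI log10 = %.3f\n",
              x$label, x$mode, x$duration_min, x$final_roi_log10))
  invisible(x)
}

#' Re-label a trial's control outcome under a different threshold
#'
#' Uses the recorded per-acquisition statistic series of a controlled run to
#' determine whether (and when) a different threshold would have stopped the
#' trial, without re-processing echo data. Because the cumulative map is
#' temporally monotone, lowering the threshold can only turn USC trials into
#' SC trials, never the reverse.
#'
#' @param record A `trial_record` from a controlled (or uncontrolled) run.
#' @param threshold_log10 Alternative control threshold.
#' @param cycle_duration_s Generator cycle length in seconds.
#' @return List with `label` and `stop_time_s`.
#' @export
relabel_trial <- function(record, threshold_log10, cycle_duration_s) {
  hit <- which(record$series$statistic >= threshold_log10)
  if (length(hit) > 0 && record$series$time_s[hit[1]] < cycle_duration_s)
    list(label = "SC", stop_time_s = record$series$time_s[hit[1]])
  else list(label = "USC", stop_time_s = NA_real_)
}
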