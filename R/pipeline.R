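# End-to-end pipeline: simulate a seeded batch of trials, run the feedback
# controller over each, measure ablation outcomes, evaluate voxelwise
# prediction per group, and compute the outcome statistics.

draw_trial_profile <- function(profile, base, seed) {
  with_seed(seed, {
    diam <- stats::runif(1, profile$diameter_range_mm[1],
                         profile$diameter_range_mm[2])
    gfrac <- stats::runif(1, profile$growth_frac_range[1],
                          profile$growth_frac_range[2])
    floor_ <- stats::runif(1, profile$rho_floor_range[1],
                           profile$rho_floor_range[2])
    trans <- stats::runif(1, profile$transience_range[1],
                          profile$transience_range[2])
    gender <- sample(c("M", "F"), 1)
  })
  list(target_diameter_mm = diam,
       growth_duration_s = gfrac * base$cycle_duration_s,
       rho_floor = floor_, transience_frac = trans, gender = gender)
}

#' Run the full simulate / decorrelate / control / evaluate / stats pipeline
#'
#' Simulates a seeded batch of trials per tissue profile and control mode,
#' runs the feedback loop over each, measures the ablation outcome (the
#' ablated region at treatment stop), pools voxelwise predictions per group,
#' and computes success rates, group statistics and regressions. All
#' artifacts are written under `out_dir`; reruns with the same configuration
#' and seed are byte-identical.
#'
#' @param config A resolved configuration from [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log per-trial progress lines.
#' @return The results list, invisibly (also written as
#'   `results.json`).
#' @export
pipeline_run <- function(config, out_dir, verbose = FALSE) {
  if (is.null(config$seed)) stop("config must state an explicit seed",
                                 call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geometry <- do.call(beam_geometry, config$geometry)
  grid <- do.call(cartesian_grid, config$grid)
  window <- do.call(window_spec, config$window)
  ctrl <- control_config(config$control$threshold_log10,
                         roi_diameter_mm = config$control$roi_diameter_mm,
                         statistic_mode = config$control$statistic_mode)
  target <- sphere_mask(grid, ctrl$roi_center_mm, ctrl$roi_diameter_mm)
  eval_roi <- sphere_mask(grid, ctrl$roi_center_mm,
                          2 * config$evaluation$roi_radius_mm)
  base <- config$trial
  rows <- list(); preds <- list(); trial_counter <- 0L
  for (tissue in names(config$trials)) {
    profile <- config$trials[[tissue]]
    modes <- c(rep("uncontrolled", profile$n_uncontrolled),
               rep("controlled", profile$n_controlled))
    for (mode in modes) {
      trial_counter <- trial_counter + 1L
      tseed <- derive_seed(config$seed, trial_counter)
      dp <- draw_trial_profile(profile, base, derive_seed(tseed, 99L))
      cfg <- trial_config(
        target_diameter_mm = dp$target_diameter_mm,
        growth_duration_s = dp$growth_duration_s,
        cycle_duration_s = base$cycle_duration_s,
        acquisition_interval_s = base$acquisition_interval_s,
        tau_ms = base$tau_ms, rho_floor = dp$rho_floor,
        noise_snr_db = base$noise_snr_db,
        psf_widths_mm = base$psf_widths_mm,
        transience_exponent = dp$transience_frac *
          base$acquisition_interval_s / (base$tau_ms / 1000),
        mask_threshold = base$mask_threshold,
        tissue_label = tissue)
      dataset <- simulate_trial(cfg, geometry, grid, tseed,
                                keep_coherence = FALSE)
      record <- run_trial(dataset, ctrl, mode, window)
      t_eff <- if (record$label == "SC") record$stop_time_s
               else cfg$cycle_duration_s
      measured <- coherence_field(cfg, t_eff, grid)
      measured_mask <- ablation_mask(measured$rho <= cfg$mask_threshold,
                                     grid, provenance = "truth")
      vol <- mask_volume_ml(measured_mask)
      rows[[trial_counter]] <- data.frame(
        trial_id = sprintf("T%03d", trial_counter),
        tissue = tissue, label = record$label, gender = dp$gender,
        volume_ml = vol,
        rate_ml_min = ablation_rate(vol, record$duration_min),
        dice_vs_target = dice(measured_mask, target),
        final_roi_log10 = record$final_roi_log10,
        duration_min = record$duration_min)
      pd <- collect_predictions(record$final_cum, measured_mask, eval_roi)
      pd$tissue <- tissue; pd$control <- record$label
      preds[[trial_counter]] <- pd
      if (verbose)
        log_line("pipeline", "trial %d (%s, %s): %s, %.2f ml",
                 trial_counter, tissue, mode, record$label, vol)
      if (isTRUE(config$output$save_maps)) {
        dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
        write_volume_nifti(record$final_cum,
                           file.path(out_dir, "maps",
                                     sprintf("T%03d_cum.nii.gz",
                                             trial_counter)))
        write_volume_nifti(measured_mask,
                           file.path(out_dir, "maps",
                                     sprintf("T%03d_mask.nii.gz",
                                             trial_counter)))
      }
    }
  }
  outcomes <- outcome_table(do.call(rbind, rows))
  write_outcome_table(outcomes, file.path(out_dir, "outcomes.csv"))
  pred_df <- do.call(rbind, preds)
  frac <- effective_fraction(grid$step_mm, window$sigma_mm)

  eval_groups <- list()
  for (tissue in unique(pred_df$tissue)) {
    sub <- pred_df[pred_df$tissue == tissue, ]
    if (any(sub$label == 1) && any(sub$label == 0)) {
      pr <- prediction_result(sub, grid$step_mm, window$sigma_mm)
      eval_groups[[tissue]] <- list(
        auroc = pr$auroc, aupr = pr$aupr, aupr_min = pr$aupr_min,
        skew = pr$skew, n_total = pr$n_total,
        n_effective = pr$n_effective,
        threshold_jmax = pr$roc$threshold_jmax, jmax = pr$roc$jmax,
        threshold_f1max = pr$pr$threshold_f1max, f1max = pr$pr$f1max,
        threshold_spec90 = pr$roc$threshold_spec,
        sensitivity_at_spec90 = pr$roc$sensitivity_at_spec,
        auroc_vs_null = compare_auroc(pr, NULL, frac)[c("z", "p")])
    }
  }

  att <- table(factor(outcomes$tissue[outcomes$label != "UC"],
                      names(config$trials)))
  suc <- table(factor(outcomes$tissue[outcomes$label == "SC"],
                      names(config$trials)))
  sr <- if (all(att > 0))
    success_rates(stats::setNames(as.integer(suc), names(suc)),
                  stats::setNames(as.integer(att), names(att)))
  else NULL

  safe <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  outcomes_stats <- list()
  for (v in c("volume_ml", "rate_ml_min", "dice_vs_target",
              "final_roi_log10")) {
    outcomes_stats[[v]] <- list(
      group_compare = safe({
        gc <- group_compare(outcomes, v)
        list(branch = gc$branch, bartlett_p = gc$screen$bartlett_p,
             omnibus = as.list(gc$omnibus))
      }),
      regression_on_decorrelation = safe({
        if (v == "final_roi_log10") NULL else {
          r <- simple_regression(outcomes[[v]], outcomes$final_roi_log10)
          list(r = r$r, rmse = r$rmse, slope_p = r$coefficients$p[2])
        }
      }),
      tissue_regression = safe({
        if (v == "final_roi_log10") NULL else {
          r <- tissue_regression(outcomes[[v]], outcomes$final_roi_log10,
                                 outcomes$tissue == "steatotic",
                                 outcomes$tissue == "cirrhotic")
          list(r = r$r, rmse = r$rmse, overall_p = r$overall_p,
               coefficients = r$coefficients)
        }
      }))
  }

  results <- list(
    seed = config$seed,
    n_trials = nrow(outcomes),
    labels = as.list(table(outcomes$label)),
    success_rates = if (is.null(sr)) NULL else
      list(percent = as.list(sr$percent), pairwise = sr$pairwise),
    evaluation = eval_groups,
    neff_fraction = frac,
    outcome_statistics = outcomes_stats)
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  invisible(results)
}
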