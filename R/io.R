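# Readers and writers: the trial-dataset directory container, NIfTI volumes
# for Cartesian maps and masks, delimited outcome tables, and the
# hierarchical run configuration.

log_line <- function(stage, ...) {
  message(sprintf("%s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  sprintf(...)))
}

write_array_bin <- function(a, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(a), con, size = 8, endian = "little")
}

read_array_bin <- function(path, dim) {
  con <- file(path, "rb")
  on.exit(close(con))
  array(readBin(con, "double", n = prod(dim), size = 8, endian = "little"),
        dim)
}

#' Write a trial dataset to a directory container
#'
#' Serializes a `trial_dataset` to a structured directory mirroring an
#' HDF5-style layout: `pairs/<n>/` holds the real and imaginary parts of
#' both IQ volumes as raw little-endian float64 arrays, `coherence/<n>.bin`
#' the per-acquisition Cartesian coherence fields, `truth_mask.bin` the
#' ground-truth mask, and `manifest.json` the geometry, grid, configuration
#' and seed. The round trip is bit-exact.
#'
#' @param dataset A `trial_dataset`.
#' @param path Directory to create (must not exist or be empty).
#' @return `path`, invisibly.
#' @export
write_trial_dataset <- function(dataset, path) {
  if (dir.exists(path) && length(list.files(path)) > 0)
    stop("refusing to write into a non-empty directory", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nb <- beam_dim(dataset$geometry)
  for (pair in dataset$pairs) {
    pd <- file.path(path, "pairs", sprintf("%03d", pair$acquisition_index))
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    write_array_bin(Re(pair$iq0), file.path(pd, "iq0_real.bin"))
    write_array_bin(Im(pair$iq0), file.path(pd, "iq0_imag.bin"))
    write_array_bin(Re(pair$iq1), file.path(pd, "iq1_real.bin"))
    write_array_bin(Im(pair$iq1), file.path(pd, "iq1_imag.bin"))
  }
  if (!is.null(dataset$coherence_history)) {
    dir.create(file.path(path, "coherence"), showWarnings = FALSE)
    for (i in seq_along(dataset$coherence_history))
      write_array_bin(dataset$coherence_history[[i]]$rho,
                      file.path(path, "coherence",
                                sprintf("%03d.bin", i - 1L)))
  }
  write_array_bin(dataset$truth_mask$mask + 0,
                  file.path(path, "truth_mask.bin"))
  manifest <- list(
    geometry = unclass(dataset$geometry),
    grid = list(extent_mm = dataset$grid$extent_mm,
                step_mm = dataset$grid$step_mm,
                origin_mm = dataset$grid$origin_mm),
    config = unclass(dataset$config),
    apex_mm = dataset$apex_mm,
    times_s = dataset$times_s,
    seed = dataset$seed,
    pair_tau_ms = dataset$pairs[[1]]$tau_ms,
    n_pairs = length(dataset$pairs),
    has_coherence = !is.null(dataset$coherence_history))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trial dataset written by [write_trial_dataset()]
#'
#' @param path Container directory.
#' @return A `trial_dataset` (derived per-acquisition fields such as the
#'   within-pair coherence are not stored and come back `NULL`).
#' @export
read_trial_dataset <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  g <- manifest$geometry
  geometry <- beam_geometry(g$n_range, g$n_azimuth, g$n_elevation,
                            g$azimuth_span_deg, g$elevation_span_deg,
                            g$depth_mm, g$range_step_mm)
  gr <- manifest$grid
  grid <- cartesian_grid(gr$extent_mm, gr$step_mm, gr$origin_mm)
  cfgl <- manifest$config
  config <- do.call(trial_config, cfgl[names(cfgl) %in%
                                         names(formals(trial_config))])
  nb <- beam_dim(geometry)
  pairs <- lapply(seq_len(manifest$n_pairs), function(i) {
    pd <- file.path(path, "pairs", sprintf("%03d", i - 1L))
    iq0 <- complex(real = read_array_bin(file.path(pd, "iq0_real.bin"), nb),
                   imaginary = read_array_bin(file.path(pd, "iq0_imag.bin"),
                                              nb))
    iq1 <- complex(real = read_array_bin(file.path(pd, "iq1_real.bin"), nb),
                   imaginary = read_array_bin(file.path(pd, "iq1_imag.bin"),
                                              nb))
    structure(list(iq0 = array(iq0, nb), iq1 = array(iq1, nb),
                   tau_ms = manifest$pair_tau_ms,
                   acquisition_index = i - 1L,
                   acquisition_time_s = manifest$times_s[i]),
              class = "echo_pair")
  })
  coh <- NULL
  if (isTRUE(manifest$has_coherence)) {
    coh <- lapply(seq_len(manifest$n_pairs), function(i) {
      structure(list(rho = read_array_bin(
        file.path(path, "coherence", sprintf("%03d.bin", i - 1L)),
        grid_dim(grid)),
        time_s = manifest$times_s[i], grid = grid),
        class = "coherence_field")
    })
  }
  truth <- ablation_mask(read_array_bin(file.path(path, "truth_mask.bin"),
                                        grid_dim(grid)) > 0.5,
                         grid, provenance = "truth")
  structure(list(pairs = pairs, truth_mask = truth,
                 coherence_history = coh, pair_coherence = NULL,
                 compounded_coherence_beam = NULL,
                 times_s = manifest$times_s, config = config,
                 geometry = geometry, grid = grid,
                 apex_mm = manifest$apex_mm,
                 seed = as.integer(manifest$seed)),
            class = "trial_dataset")
}

#' Write a Cartesian map or mask as NIfTI
#'
#' Stores the array with the grid's mm spacing in the header. Masks are
#' written as integers, maps as float64; `NA` (invalid sector) voxels are
#' stored as `NaN`.
#'
#' @param x A `cumulative_map`, `decorr_map`, `ablation_mask`, or plain
#'   array (then `grid` is required).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param grid Grid for plain arrays.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, grid = NULL) {
  if (inherits(x, "ablation_mask")) {
    grid <- x$grid; arr <- array(as.integer(x$mask), dim(x$mask))
  } else if (inherits(x, c("cumulative_map", "decorr_map"))) {
    if (is.null(grid)) grid <- x$grid
    arr <- x$delta
  } else arr <- x
  if (is.null(grid)) stop("grid required", call. = FALSE)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid$step_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_volume_nifti()]
#'
#' @param path NIfTI file path.
#' @return List with `array` and `spacing_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(array = array(as.vector(img), dim(img)),
       spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write / read an outcome table as CSV
#'
#' @param table An [outcome_table()].
#' @param path CSV file path.
#' @return `path` invisibly (writer); an `outcome_table` (reader).
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
read_outcome_table <- function(path) {
  outcome_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# ---- Run configuration ------------------------------------------------------

#' Default hierarchical run configuration
#'
#' All module defaults in one document: beam geometry, Cartesian grid,
#' window width, control parameters, acquisition cadence, per-tissue trial
#' profiles and counts, evaluation settings, and the master seed (which has
#' no default: every run must state its seed explicitly).
#'
#' The per-tissue profiles draw each trial's target diameter, growth
#' duration, coherence floor and transience fraction from seeded uniform
#' ranges, emulating biological variability: normal liver decoheres strongly
#' and reliably, steatotic and cirrhotic liver more weakly and more
#' variably, with mean target volumes mirroring the smaller measured
#' ablation zones of diseased tissue.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = NULL,
    geometry = list(n_range = 485L, n_azimuth = 85L, n_elevation = 67L,
                    azimuth_span_deg = 90, elevation_span_deg = 90,
                    depth_mm = 70),
    grid = list(extent_mm = 60, step_mm = 0.5),
    window = list(sigma_mm = 3, truncation_radius_sigmas = 4),
    control = list(threshold_log10 = -2.8, roi_diameter_mm = 20,
                   statistic_mode = "mean-then-log"),
    trial = list(acquisition_interval_s = 22, cycle_duration_s = 330,
                 tau_ms = 50, noise_snr_db = 30,
                 psf_widths_mm = c(0.3, 1.7), mask_threshold = 0.5),
    trials = list(
      normal = list(n_uncontrolled = 14L, n_controlled = 16L,
                    diameter_range_mm = c(17, 23),
                    growth_frac_range = c(0.5, 0.8),
                    rho_floor_range = c(0, 0.2),
                    transience_range = c(0.3, 1)),
      steatotic = list(n_uncontrolled = 14L, n_controlled = 24L,
                       diameter_range_mm = c(15, 21),
                       growth_frac_range = c(0.5, 0.85),
                       rho_floor_range = c(0.1, 0.45),
                       transience_range = c(0.02, 0.6)),
      cirrhotic = list(n_uncontrolled = 14L, n_controlled = 15L,
                       diameter_range_mm = c(16, 22),
                       growth_frac_range = c(0.5, 0.85),
                       rho_floor_range = c(0.1, 0.45),
                       transience_range = c(0.02, 0.55))),
    evaluation = list(roi_radius_mm = 25, n_boot = 5000),
    output = list(save_maps = FALSE)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Merges the user document over [default_run_config()]; unknown keys are
#' rejected, and a missing seed is an error (every run must be explicitly
#' seeded).
#'
#' @param path YAML file, or `NULL` to take the defaults (still requires
#'   `seed` via the `overrides` argument).
#' @param overrides Optional named list merged last (e.g.
#'   `list(seed = 17)`).
#' @return The fully resolved configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  if (is.null(cfg$seed))
    stop("config must state an explicit seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
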