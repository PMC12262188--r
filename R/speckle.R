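# Synthetic paired-IQ trial generator: fully developed speckle on the sector
# beam geometry, a growing heat-induced decoherence region defined on the
# Cartesian grid, additive electronic noise, and the ground-truth mask.

# Counter-based seed derivation: every random draw in a trial flows from one
# master seed through this hash, so any sub-stream is reproducible on its own.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1D unit-sum Gaussian kernel in voxel units, truncated at `trunc` sigmas.
gauss_kernel1d <- function(sigma_vox, trunc = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(trunc * sigma_vox)))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

# Banded convolution matrix: out[i] = sum_u k[u] * a[i + u - r - 1], zero
# padded at the edges. Symmetric kernels make convolution == correlation.
band_matrix <- function(k, n) {
  r <- (length(k) - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    ok <- idx >= 1 & idx <= n
    W[idx[ok], j] <- k[ok]
  }
  W
}

# Separable convolution of a 3D array (real or complex) with per-dimension
# 1D kernels, via BLAS matrix products. Zero padding at array edges.
conv_separable <- function(a, kernels) {
  d <- dim(a)
  for (ax in seq_along(d)) {
    k <- kernels[[ax]]
    if (is.null(k)) next
    if (length(k) == 1L) { a <- a * k; next }
    n <- d[ax]
    W <- band_matrix(k, n)
    perm <- c(ax, seq_along(d)[-ax])
    m <- matrix(aperm(a, perm), nrow = n)
    a <- aperm(array(W %*% m, dim = d[perm]), order(perm))
  }
  a
}

# Raw circular complex Gaussian field with unit mean squared magnitude.
complex_gaussian <- function(dim, seed) {
  n <- prod(dim)
  with_seed(seed, {
    re <- stats::rnorm(n, sd = sqrt(0.5))
    im <- stats::rnorm(n, sd = sqrt(0.5))
  })
  array(complex(real = re, imaginary = im), dim)
}

# Smoothed unit-power speckle on arbitrary dims; sigma given in voxel units.
speckle_field <- function(dim, sigma_vox = c(0, 0, 0), seed, trunc = 4) {
  f <- complex_gaussian(dim, seed)
  kernels <- lapply(sigma_vox, function(s)
    if (s > 0) gauss_kernel1d(s, trunc) else NULL)
  f <- conv_separable(f, kernels)
  f / sqrt(mean(Mod(f)^2))
}

# Point-spread sigmas in beam-sample units for a geometry: axial width along
# range, lateral width along both angular axes converted at mid-depth.
psf_sigma_vox <- function(geometry, psf_widths_mm) {
  if (any(psf_widths_mm <= 0))
    stop("psf widths must be positive", call. = FALSE)
  fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))   # 1/2.355
  ax_sigma_mm <- psf_widths_mm[1] * fwhm_to_sigma
  lat_sigma_mm <- psf_widths_mm[2] * fwhm_to_sigma
  ang <- beam_angles(geometry)
  mid <- geometry$depth_mm / 2
  az_step_mm <- diff(ang$azimuth[1:2]) * mid
  el_step_mm <- diff(ang$elevation[1:2]) * mid
  c(ax_sigma_mm / geometry$range_step_mm,
    lat_sigma_mm / az_step_mm,
    lat_sigma_mm / el_step_mm)
}

#' Generate a fully developed speckle volume on the beam geometry
#'
#' Draws an independent circular complex Gaussian scatterer field on the beam
#' sampling, smooths it with a separable Gaussian point-spread kernel (axial
#' width along range; lateral width along both angular axes, converted to
#' sample units at mid-depth), and rescales to unit mean squared magnitude.
#' The result emulates fully developed speckle of liver parenchyma.
#'
#' @param geometry A [beam_geometry()].
#' @param psf_widths_mm Axial and lateral point-spread FWHM in mm
#'   (defaults 0.3 and 1.7, the B-mode resolution of the emulated array).
#' @param seed Integer seed; the same (geometry, widths, seed) reproduces the
#'   field bit-for-bit.
#' @return Complex array of dims `[n_range, n_azimuth, n_elevation]`.
#' @export
make_speckle_volume <- function(geometry, psf_widths_mm = c(0.3, 1.7), seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  sv <- psf_sigma_vox(geometry, psf_widths_mm)
  speckle_field(beam_dim(geometry), sv, seed)
}

#' Synthetic trial configuration
#'
#' Parameters of one simulated ablation trial: the targeted lesion size and
#' growth timing, the acquisition cadence, the coherence floor at the lesion
#' core, electronic noise level, and the point-spread widths. The defaults
#' emulate the study conditions: a 20 mm diameter spherical target, 22 s
#' acquisition cadence, 50 ms pair separation, and a generator cycle a few
#' minutes long.
#'
#' @param target_diameter_mm Diameter of the targeted ablation zone.
#' @param growth_duration_s Time for the lesion to reach target radius.
#' @param cycle_duration_s Full generator cycle (ramp plus hold) in seconds.
#' @param acquisition_interval_s Cadence of echo pair captures.
#' @param tau_ms Within-pair inter-frame interval in ms.
#' @param rho_floor Minimum coherence at the lesion core (0 = complete
#'   decoherence).
#' @param noise_snr_db Electronic SNR in dB relative to unit signal power;
#'   `Inf` disables noise.
#' @param psf_widths_mm Axial and lateral point-spread FWHM in mm.
#' @param transience_exponent Exponent linking within-pair (50 ms) coherence
#'   to the inter-acquisition coherence ratio g:
#'   `rho_pair = g^(transience_exponent * tau / interval)`. The default,
#'   `interval / tau`, makes all inter-acquisition coherence loss transient
#'   (`rho_pair = g`); a value of 1 models change accruing uniformly in time.
#' @param mask_threshold Final compounded coherence at or below which a voxel
#'   counts as ablated in the ground-truth mask.
#' @param tissue_label Metadata label: `"normal"`, `"steatotic"` or
#'   `"cirrhotic"`.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(target_diameter_mm = 20,
                         growth_duration_s = 220,
                         cycle_duration_s = 330,
                         acquisition_interval_s = 22,
                         tau_ms = 50,
                         rho_floor = 0,
                         noise_snr_db = 30,
                         psf_widths_mm = c(0.3, 1.7),
                         transience_exponent =
                           acquisition_interval_s / (tau_ms / 1000),
                         mask_threshold = 0.5,
                         tissue_label = c("normal", "steatotic", "cirrhotic")) {
  tissue_label <- match.arg(tissue_label)
  if (target_diameter_mm <= 0) stop("target_diameter_mm must be positive",
                                    call. = FALSE)
  if (growth_duration_s < 0 || growth_duration_s > cycle_duration_s)
    stop("growth_duration_s must lie in [0, cycle_duration_s]", call. = FALSE)
  if (rho_floor < 0 || rho_floor > 1)
    stop("rho_floor must lie in [0, 1]", call. = FALSE)
  if (tau_ms <= 0) stop("tau_ms must be positive", call. = FALSE)
  if (acquisition_interval_s <= 0 ||
      acquisition_interval_s > cycle_duration_s)
    stop("acquisition_interval_s must lie in (0, cycle_duration_s]",
         call. = FALSE)
  if (mask_threshold < 0 || mask_threshold > 1)
    stop("mask_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(target_diameter_mm = target_diameter_mm,
                 growth_duration_s = growth_duration_s,
                 cycle_duration_s = cycle_duration_s,
                 acquisition_interval_s = acquisition_interval_s,
                 tau_ms = tau_ms, rho_floor = rho_floor,
                 noise_snr_db = noise_snr_db,
                 psf_widths_mm = psf_widths_mm,
                 transience_exponent = transience_exponent,
                 mask_threshold = mask_threshold,
                 tissue_label = tissue_label),
            class = "trial_config")
}

# Nominal lesion radius (the half-coherence radius when rho_floor = 0) at a
# given trial time: grows linearly from 0 to the target radius over
# growth_duration_s, constant thereafter.
lesion_radius_mm <- function(config, time_s) {
  target_r <- config$target_diameter_mm / 2
  frac <- if (config$growth_duration_s <= 0) as.numeric(time_s > 0)
          else pmin(1, time_s / config$growth_duration_s)
  target_r * frac
}

# Radial coherence profile. The transition band is a raised cosine spanning
# [0.7, 1] * R_outer with R_outer = L / 0.85, which puts the coherence-0.5
# crossing exactly at the nominal radius L (for rho_floor = 0), so the mask
# rule reproduces the targeted sphere.
coherence_profile <- function(r_mm, L_mm, rho_floor) {
  p <- rep(1, length(r_mm))
  if (L_mm <= 0) return(p)
  b <- L_mm / 0.85
  a <- 0.7 * b
  inside <- r_mm <= a
  band <- r_mm > a & r_mm < b
  p[inside] <- rho_floor
  s <- (r_mm[band] - a) / (b - a)
  p[band] <- rho_floor + (1 - rho_floor) * 0.5 * (1 - cos(pi * s))
  p
}

#' Ground-truth coherence field at a trial time
#'
#' Per-voxel cumulative coherence (relative to trial start) on the Cartesian
#' grid: 1 outside the current lesion, decreasing smoothly (raised-cosine
#' radial profile) to `rho_floor` toward the core. The lesion radius grows
#' linearly from 0 at time 0 to the target radius at `growth_duration_s` and
#' is constant thereafter.
#'
#' @param config A [trial_config()].
#' @param time_s Trial clock in seconds, within `[0, cycle_duration_s]`.
#' @param grid A [cartesian_grid()].
#' @param center_mm Lesion center (default the grid center / needle tip).
#' @return An object of class `coherence_field` with fields `rho` (array in
#'   \[0,1\]), `time_s` and `grid`.
#' @export
coherence_field <- function(config, time_s, grid,
                            center_mm = c(mean(range(grid$x)),
                                          mean(range(grid$y)),
                                          mean(range(grid$z)))) {
  if (time_s < 0 || time_s > config$cycle_duration_s)
    stop("time_s must lie in [0, cycle_duration_s]", call. = FALSE)
  co <- grid_coords(grid)
  r <- sqrt((co$x - center_mm[1])^2 + (co$y - center_mm[2])^2 +
            (co$z - center_mm[3])^2)
  L <- lesion_radius_mm(config, time_s)
  rho <- coherence_profile(r, L, config$rho_floor)
  structure(list(rho = array(rho, grid_dim(grid)), time_s = time_s,
                 grid = grid, lesion_radius_mm = L, center_mm = center_mm),
            class = "coherence_field")
}

#' Synthesize one echo pair from a base speckle field
#'
#' Builds the two co-registered IQ volumes of one acquisition: `iq0` is the
#' base field plus electronic noise; `iq1` mixes the base with an independent
#' speckle field of identical statistics so that the per-voxel squared
#' coherence of the noise-free pair equals `rho^2`:
#' `iq1 = rho * base + sqrt(1 - rho^2) * fresh + noise`.
#' Noise is circular complex Gaussian at `noise_snr_db` relative to unit
#' signal power.
#'
#' @param base Complex beam-domain (or any) array with unit mean power.
#' @param rho Per-voxel coherence in \[0,1\] (scalar or array matching `base`).
#' @param tau_ms Within-pair interval in ms.
#' @param noise_snr_db SNR in dB; `Inf` for noise-free.
#' @param seed Integer seed for the fresh speckle and both noise draws.
#' @param psf_sigma_vox Per-dimension Gaussian widths (voxel units) used to
#'   smooth the fresh speckle so its statistics match the base field.
#' @param acquisition_index,acquisition_time_s Bookkeeping for trial pairs.
#' @return An object of class `echo_pair`.
#' @export
make_echo_pair <- function(base, rho, tau_ms = 50, noise_snr_db = Inf, seed,
                           psf_sigma_vox = c(0, 0, 0),
                           acquisition_index = 0L, acquisition_time_s = 0) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]", call. = FALSE)
  if (tau_ms <= 0) stop("tau_ms must be positive", call. = FALSE)
  d <- dim(base)
  fresh <- speckle_field(d, psf_sigma_vox, derive_seed(seed, 1L))
  iq1 <- rho * base + sqrt(pmax(0, 1 - rho^2)) * fresh
  if (is.finite(noise_snr_db)) {
    npow <- 10^(-noise_snr_db / 10)
    n0 <- complex_gaussian(d, derive_seed(seed, 2L)) * sqrt(npow)
    n1 <- complex_gaussian(d, derive_seed(seed, 3L)) * sqrt(npow)
    iq0 <- base + n0
    iq1 <- iq1 + n1
  } else {
    iq0 <- base
  }
  structure(list(iq0 = iq0, iq1 = iq1, tau_ms = tau_ms,
                 acquisition_index = as.integer(acquisition_index),
                 acquisition_time_s = acquisition_time_s),
            class = "echo_pair")
}

#' Simulate a full seeded ablation trial
#'
#' Emits one echo pair per acquisition at times `0, 22 s, 44 s, ...` up to the
#' cycle end. The scatterer field evolves cumulatively: between consecutive
#' acquisitions each voxel's coherence is multiplied by the per-interval ratio
#' `g_n = rho(t_n) / rho(t_(n-1))` of the ground-truth coherence field
#' (resampled from the Cartesian grid to beam coordinates), and the
#' within-pair (50 ms) coherence is `g_n` raised to
#' `transience_exponent * tau / interval`. The ground-truth mask holds the
#' voxels whose final compounded coherence is at or below
#' `config$mask_threshold`. Fully reproducible from `(config, seed)`.
#'
#' @param config A [trial_config()].
#' @param geometry A [beam_geometry()].
#' @param grid A [cartesian_grid()].
#' @param seed Master integer seed; all draws derive from it.
#' @param apex_mm Sector apex position, as in [scan_convert()].
#' @param keep_coherence Keep the per-acquisition Cartesian coherence fields
#'   in the returned object (default TRUE).
#' @return An object of class `trial_dataset` with `pairs`, `truth_mask`,
#'   `coherence_history`, `pair_coherence` (per-acquisition beam-domain
#'   within-pair coherence), `config`, `geometry`, `grid`, `seed`.
#' @export
simulate_trial <- function(config, geometry = beam_geometry(),
                           grid = cartesian_grid(), seed,
                           apex_mm = default_apex(grid),
                           keep_coherence = TRUE) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  times <- seq(0, config$cycle_duration_s, by = config$acquisition_interval_s)
  sv <- psf_sigma_vox(geometry, config$psf_widths_mm)
  base <- make_speckle_volume(geometry, config$psf_widths_mm,
                              derive_seed(seed, 0L, 0L))
  pair_exp <- config$transience_exponent *
    (config$tau_ms / 1000) / config$acquisition_interval_s
  eps <- 1e-12
  pairs <- vector("list", length(times))
  coh_hist <- if (keep_coherence) vector("list", length(times)) else NULL
  pair_coh <- vector("list", length(times))
  prev_beam <- array(1, beam_dim(geometry))
  prod_beam <- array(1, beam_dim(geometry))
  s <- base
  for (n in seq_along(times)) {
    cf <- coherence_field(config, times[n], grid)
    rho_beam <- resample_to_beam(cf$rho, grid, geometry, apex_mm, fill = 1)
    g <- ifelse(prev_beam <= eps, 1, pmin(1, pmax(0, rho_beam / prev_beam)))
    if (n > 1L) {
      fresh <- speckle_field(beam_dim(geometry), sv,
                             derive_seed(seed, n - 1L, 1L))
      s <- g * s + sqrt(pmax(0, 1 - g^2)) * fresh
    }
    rho_pair <- g^pair_exp
    pairs[[n]] <- make_echo_pair(s, rho_pair, config$tau_ms,
                                 config$noise_snr_db,
                                 derive_seed(seed, n - 1L, 2L),
                                 psf_sigma_vox = sv,
                                 acquisition_index = n - 1L,
                                 acquisition_time_s = times[n])
    prod_beam <- prod_beam * g
    prev_beam <- rho_beam
    pair_coh[[n]] <- rho_pair
    if (keep_coherence) coh_hist[[n]] <- cf
  }
  final <- coherence_field(config, config$cycle_duration_s, grid)
  truth <- ablation_mask(final$rho <= config$mask_threshold, grid,
                         provenance = "truth")
  structure(list(pairs = pairs, truth_mask = truth,
                 coherence_history = coh_hist,
                 pair_coherence = pair_coh,
                 compounded_coherence_beam = prod_beam,
                 times_s = times,
                 config = config, geometry = geometry, grid = grid,
                 apex_mm = apex_mm, seed = as.integer(seed)),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf(
    "<trial_dataset> %d pairs (%g s cadence), tissue %s, seed %d\n",
    length(x$pairs), x$config$acquisition_interval_s,
    x$config$tissue_label, x$seed))
  invisible(x)
}
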