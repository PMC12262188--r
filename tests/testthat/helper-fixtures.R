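# Small geometries, grids and trials used across tests; everything is
# generated in code with fixed seeds.

small_geometry <- function() {
  beam_geometry(n_range = 121, n_azimuth = 33, n_elevation = 25,
                depth_mm = 70)
}

small_grid <- function() cartesian_grid(extent_mm = 40, step_mm = 1)

# Trial sized for fast end-to-end runs: lesion fills within the control ROI
# well before the cycle ends.
small_trial <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(target_diameter_mm = 20, growth_duration_s = 132,
         cycle_duration_s = 220, noise_snr_db = 30),
    list(...))
  cfg <- do.call(trial_config, args)
  simulate_trial(cfg, small_geometry(), small_grid(), seed = seed)
}

# Direct-summation oracle for the windowed correlation at selected voxels:
# triple loop over the truncated separable window, no convolution tricks.
direct_windowed <- function(I0, I1, k, at) {
  r <- (length(k) - 1) / 2
  n <- dim(I0)
  vapply(seq_len(nrow(at)), function(q) {
    i <- at[q, 1]; j <- at[q, 2]; l <- at[q, 3]
    ii <- max(1, i - r):min(n[1], i + r)
    jj <- max(1, j - r):min(n[2], j + r)
    ll <- max(1, l - r):min(n[3], l + r)
    W <- outer(outer(k[ii - i + r + 1], k[jj - j + r + 1]),
               k[ll - l + r + 1])
    sum(W * I0[ii, jj, ll] * Conj(I1[ii, jj, ll]))
  }, complex(1))
}

# iid circular complex Gaussian speckle (no point spread), unit power.
iid_speckle <- function(dim, seed) echodecorr:::complex_gaussian(dim, seed)

# Brute-force AUROC: concordant-pair fraction with half credit for ties.
pair_count_auroc <- function(score, label) {
  sp <- score[label == 1]; sn <- score[label == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# Simulated outcome table with optional planted effects.
fake_outcomes <- function(n_per_group = 8, seed = 1, tissue_shift = 0,
                          rate_sd_mult = 1) {
  set.seed(seed)
  g <- expand.grid(tissue = c("normal", "steatotic", "cirrhotic"),
                   label = c("UC", "SC", "USC"),
                   stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    mu <- 4 + if (g$tissue[i] == "steatotic") tissue_shift else 0
    data.frame(tissue = g$tissue[i], label = g$label[i],
               gender = sample(c("M", "F"), n_per_group, replace = TRUE),
               volume_ml = rnorm(n_per_group, mu, 1),
               rate_ml_min = rnorm(n_per_group, 0.8,
                                   0.2 * if (g$label[i] == "SC")
                                     rate_sd_mult else 1),
               dice_vs_target = pmin(0.95, pmax(0.05,
                 rnorm(n_per_group, 0.55, 0.1))),
               final_roi_log10 = rnorm(n_per_group, -2.8, 0.3),
               duration_min = runif(n_per_group, 1, 6))
  }))
  rows$trial_id <- sprintf("T%03d", seq_len(nrow(rows)))
  outcome_table(rows)
}
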