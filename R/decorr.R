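# Echo decorrelation core: spatially windowed correlations on the Cartesian
# grid and the combined-normalized instantaneous decorrelation per
# millisecond, with its running temporal maximum.

#' Gaussian correlation window
#'
#' The isotropic 3D Gaussian window used for the zero-lag windowed
#' correlations, with width parameter `sigma_mm` (default 3 mm) and support
#' truncated at `truncation_radius_sigmas` standard deviations. Weights are
#' normalized to unit sum; the normalization cancels in the decorrelation
#' ratio but keeps correlation magnitudes interpretable.
#'
#' @param sigma_mm Gaussian width parameter in mm.
#' @param truncation_radius_sigmas Truncation radius in units of sigma.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(sigma_mm = 3, truncation_radius_sigmas = 4) {
  if (sigma_mm <= 0) stop("sigma_mm must be positive", call. = FALSE)
  if (truncation_radius_sigmas <= 0)
    stop("truncation radius must be positive", call. = FALSE)
  structure(list(sigma_mm = sigma_mm,
                 truncation_radius_sigmas = truncation_radius_sigmas),
            class = "window_spec")
}

window_kernel1d <- function(window, step_mm) {
  gauss_kernel1d(window$sigma_mm / step_mm, window$truncation_radius_sigmas)
}

#' Zero-lag spatially windowed correlations of a Cartesian volume pair
#'
#' Computes, at every voxel r, the windowed cross-correlation
#' `R01(r) = sum w(r - r') I0(r') Conj(I1(r'))` and the two windowed
#' autocorrelations `R00`, `R11`, by separable convolution with the Gaussian
#' window. The Cauchy-Schwarz inequality `|R01|^2 <= R00 * R11` holds at
#' every voxel. Invalid voxels must be zero-filled by the caller (as
#' [scan_convert()] does); they then contribute nothing to any window sum.
#'
#' @param I0,I1 Complex Cartesian arrays of identical dims.
#' @param window A [window_spec()].
#' @param step_mm Voxel pitch of the grid in mm.
#' @param validity Logical array of voxels carrying data (inside the imaged
#'   sector); `NULL` means all voxels. Used by the edge correction.
#' @param edge_correction Renormalize each window sum by the local weight
#'   mass over valid in-grid voxels (normalized convolution). Without it,
#'   windows overlapping the sector edge or the grid boundary are attenuated
#'   by the zero padding, which depresses the spatial average of beta^2 and
#'   biases the decorrelation map upward away from boundaries. The common
#'   scale factor cancels in the decorrelation ratio, so this only evens out
#'   boundary voxels. Default `TRUE`.
#' @return List with `R01` (complex), `R00`, `R11` (nonnegative real).
#' @export
windowed_correlations <- function(I0, I1, window = window_spec(),
                                  step_mm = 0.5, validity = NULL,
                                  edge_correction = TRUE) {
  if (!identical(dim(I0), dim(I1)))
    stop("I0 and I1 must share dimensions", call. = FALSE)
  k <- window_kernel1d(window, step_mm)
  kern <- list(k, k, k)
  R01 <- conv_separable(I0 * Conj(I1), kern)
  R00 <- pmax(0, Re(conv_separable(Mod(I0)^2, kern)))
  R11 <- pmax(0, Re(conv_separable(Mod(I1)^2, kern)))
  dim(R00) <- dim(I0); dim(R11) <- dim(I0)
  if (edge_correction) {
    v <- if (is.null(validity)) array(1, dim(I0)) else validity + 0
    wmass <- Re(conv_separable(v, kern))
    wmass <- pmax(wmass, 1e-12)
    R01 <- R01 / wmass
    R00 <- R00 / wmass
    R11 <- R11 / wmass
  }
  list(R01 = R01, R00 = R00, R11 = R11)
}

#' Instantaneous combined-normalized echo decorrelation map
#'
#' Per-voxel decorrelation per millisecond between the two volumes of an
#' echo pair:
#' \deqn{\Delta_{inst}(r) = \frac{2[\beta^2(r) - |R_{01}(r)|^2]}
#'   {\tau\,[\beta^2(r) + \overline{\beta^2}]}}
#' where \eqn{\beta^2 = R_{00} R_{11}} and \eqn{\overline{\beta^2}} is the
#' spatial average of \eqn{\beta^2} over the cubic volume. The combined
#' normalization keeps the map in `[0, 2/tau]` and suppresses spurious
#' decorrelation where echo energy is low. By default the spatial average
#' runs over valid voxels only (the sector does not image the cube's
#' corners); `beta_bar_mode = "full"` averages over the whole cube with the
#' zero-filled invalid voxels included, for strict replication of a
#' full-cube average.
#'
#' @param R01,R00,R11 Outputs of [windowed_correlations()].
#' @param tau_ms Within-pair interval in ms.
#' @param validity Logical array flagging voxels inside the imaged sector;
#'   `NULL` means all valid.
#' @param acquisition_index Bookkeeping index n.
#' @param beta_bar_mode `"valid"` (default) or `"full"`.
#' @return An object of class `decorr_map`: fields `delta` (ms^-1, `NA` at
#'   invalid voxels), `validity`, `tau_ms`, `beta_bar`, `acquisition_index`.
#' @export
instantaneous_decorrelation <- function(R01, R00, R11, tau_ms = 50,
                                        validity = NULL,
                                        acquisition_index = 0L,
                                        beta_bar_mode = c("valid", "full")) {
  beta_bar_mode <- match.arg(beta_bar_mode)
  if (tau_ms <= 0) stop("tau_ms must be positive", call. = FALSE)
  if (is.null(validity)) validity <- array(TRUE, dim(R00))
  if (!any(validity)) stop("no valid voxels", call. = FALSE)
  beta2 <- R00 * R11
  beta_bar <- if (beta_bar_mode == "valid") mean(beta2[validity])
              else mean(beta2)
  if (beta_bar <= 0) stop("degenerate input: spatial average of beta^2 is 0",
                          call. = FALSE)
  delta <- 2 * (beta2 - Mod(R01)^2) / (tau_ms * (beta2 + beta_bar))
  delta[!validity] <- NA_real_
  dmax <- max(delta[validity])
  dmin <- min(delta[validity])
  if (dmin < -1e-12 || dmax > 2 / tau_ms + 1e-12)
    stop("decorrelation bound violated: map outside [0, 2/tau]",
         call. = FALSE)
  structure(list(delta = delta, validity = validity, tau_ms = tau_ms,
                 beta_bar = beta_bar,
                 acquisition_index = as.integer(acquisition_index)),
            class = "decorr_map")
}

#' Compute the decorrelation map of an echo pair on the Cartesian grid
#'
#' Convenience wrapper: scan-converts both IQ volumes of a pair, forms the
#' windowed correlations, and evaluates the instantaneous decorrelation map.
#'
#' @param pair An `echo_pair` (see [make_echo_pair()]).
#' @param geometry,grid,apex_mm Scan conversion parameters.
#' @param window A [window_spec()].
#' @param beta_bar_mode Passed to [instantaneous_decorrelation()].
#' @return A `decorr_map`.
#' @export
pair_decorrelation <- function(pair, geometry, grid,
                               apex_mm = default_apex(grid),
                               window = window_spec(),
                               beta_bar_mode = "valid") {
  s0 <- scan_convert(pair$iq0, geometry, grid, apex_mm)
  s1 <- scan_convert(pair$iq1, geometry, grid, apex_mm)
  w <- windowed_correlations(s0$field, s1$field, window, grid$step_mm,
                             validity = s0$validity)
  instantaneous_decorrelation(w$R01, w$R00, w$R11, pair$tau_ms,
                              s0$validity,
                              acquisition_index = pair$acquisition_index,
                              beta_bar_mode = beta_bar_mode)
}

#' Empty cumulative decorrelation map
#'
#' @param grid A [cartesian_grid()].
#' @return An object of class `cumulative_map` with all-`NA` `delta` and
#'   `n_updates = 0`.
#' @export
empty_cumulative <- function(grid) {
  structure(list(delta = array(NA_real_, grid_dim(grid)), n_updates = 0L,
                 grid = grid),
            class = "cumulative_map")
}

#' Update a cumulative decorrelation map with a new instantaneous map
#'
#' Elementwise temporal maximum: each voxel of the cumulative map becomes the
#' larger of its current value and the new instantaneous value. Voxels
#' invalid in the instantaneous map leave the cumulative map unchanged.
#'
#' @param cum A `cumulative_map` (see [empty_cumulative()]).
#' @param inst A `decorr_map`.
#' @return The updated `cumulative_map`.
#' @export
update_cumulative <- function(cum, inst) {
  if (!identical(dim(cum$delta), dim(inst$delta)))
    stop("cumulative and instantaneous maps must share a grid", call. = FALSE)
  d <- inst$delta
  upd <- inst$validity & !is.na(d)
  old <- cum$delta
  take <- upd & (is.na(old) | d > old)
  old[take] <- d[take]
  cum$delta <- old
  cum$n_updates <- cum$n_updates + 1L
  cum
}

#' @export
print.cumulative_map <- function(x, ...) {
  cat(sprintf("<cumulative_map> %s, %d updates, max %.3g ms^-1\n",
              paste(dim(x$delta), collapse = "x"), x$n_updates,
              suppressWarnings(max(x$delta, na.rm = TRUE))))
  invisible(x)
}

#' Log-compressed B-mode envelope
#'
#' Returns `20 * log10(|I0|)` clipped to a dynamic range below the peak;
#' zero-magnitude samples map to the floor.
#'
#' @param I0 Complex (or real) array.
#' @param dynamic_range_db Displayed dynamic range in dB (default 65).
#' @return Real array of dB values in `[peak - dynamic_range_db, peak]`.
#' @export
bmode_envelope <- function(I0, dynamic_range_db = 65) {
  env <- 20 * log10(Mod(I0))
  finite <- is.finite(env)
  if (!any(finite)) stop("all-zero field has no envelope", call. = FALSE)
  peak <- max(env[finite])
  env <- pmin(pmax(env, peak - dynamic_range_db), peak)
  dim(env) <- dim(I0)
  env
}
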