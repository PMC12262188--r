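#' Phased-array sector beam geometry
#'
#' Describes the beam-domain sampling of a matrix-array sector volume:
#' `n_range` samples along each scan line, `n_azimuth` x `n_elevation` lines
#' spanning the given angular sectors, to the stated imaging depth. Beam-domain
#' arrays are indexed `[range, azimuth, elevation]`.
#'
#' @param n_range Number of range samples per scan line.
#' @param n_azimuth,n_elevation Number of scan lines in each angular direction.
#' @param azimuth_span_deg,elevation_span_deg Total sector angles in degrees.
#' @param depth_mm Imaging depth in mm.
#' @param range_step_mm Range sample spacing; defaults to
#'   `depth_mm / (n_range - 1)` so the line exactly covers the depth.
#' @return An object of class `beam_geometry`.
#' @examples
#' g <- beam_geometry()          # the default 85 x 67 line, 70 mm configuration
#' g$range_step_mm
#' @export
beam_geometry <- function(n_range = 485L, n_azimuth = 85L, n_elevation = 67L,
                          azimuth_span_deg = 90, elevation_span_deg = 90,
                          depth_mm = 70,
                          range_step_mm = depth_mm / (n_range - 1)) {
  n_range <- as.integer(n_range)
  n_azimuth <- as.integer(n_azimuth)
  n_elevation <- as.integer(n_elevation)
  if (any(c(n_range, n_azimuth, n_elevation) < 2L))
    stop("all sample/line counts must be >= 2", call. = FALSE)
  if (azimuth_span_deg <= 0 || azimuth_span_deg >= 180 ||
      elevation_span_deg <= 0 || elevation_span_deg >= 180)
    stop("sector spans must lie in (0, 180) degrees", call. = FALSE)
  if (range_step_mm <= 0)
    stop("range_step_mm must be positive", call. = FALSE)
  if (abs((n_range - 1) * range_step_mm - depth_mm) > 1e-9)
    stop("(n_range - 1) * range_step_mm must equal depth_mm", call. = FALSE)
  structure(list(n_range = n_range, n_azimuth = n_azimuth,
                 n_elevation = n_elevation,
                 azimuth_span_deg = azimuth_span_deg,
                 elevation_span_deg = elevation_span_deg,
                 depth_mm = depth_mm, range_step_mm = range_step_mm),
            class = "beam_geometry")
}

#' @export
print.beam_geometry <- function(x, ...) {
  cat(sprintf("<beam_geometry> %d x %d x %d (range x az x el), %g x %g deg, depth %g mm\n",
              x$n_range, x$n_azimuth, x$n_elevation,
              x$azimuth_span_deg, x$elevation_span_deg, x$depth_mm))
  invisible(x)
}

beam_dim <- function(geometry) {
  c(geometry$n_range, geometry$n_azimuth, geometry$n_elevation)
}

# Angular sampling in radians, centered on the beam axis.
beam_angles <- function(geometry) {
  list(
    azimuth = seq(-geometry$azimuth_span_deg / 2, geometry$azimuth_span_deg / 2,
                  length.out = geometry$n_azimuth) * pi / 180,
    elevation = seq(-geometry$elevation_span_deg / 2,
                    geometry$elevation_span_deg / 2,
                    length.out = geometry$n_elevation) * pi / 180
  )
}

#' Isotropic Cartesian reconstruction grid
#'
#' The Cartesian grid on which decorrelation maps, coherence fields and
#' ablation masks live. Axis convention: x = elevation, y = azimuth,
#' z = range; arrays are indexed `[x, y, z]`. Coordinates are voxel centers,
#' with the grid centered on the origin (the needle tip) by default.
#'
#' @param extent_mm Extent covered per axis (inclusive endpoints), in mm.
#' @param step_mm Isotropic voxel pitch `l` in mm.
#' @param origin_mm Position of voxel (1,1,1)'s center; defaults to
#'   `-extent_mm / 2` per axis, centering the grid on the origin.
#' @return An object of class `cartesian_grid` with per-axis coordinate
#'   vectors `x`, `y`, `z`.
#' @examples
#' g <- cartesian_grid()    # 60 mm at 0.5 mm: 121 points per axis
#' g$n
#' @export
cartesian_grid <- function(extent_mm = 60, step_mm = 0.5,
                           origin_mm = rep(-extent_mm / 2, 3)) {
  if (step_mm <= 0) stop("step_mm must be positive", call. = FALSE)
  n <- extent_mm / step_mm + 1
  if (abs(n - round(n)) > 1e-9)
    stop("extent_mm must be an integer multiple of step_mm", call. = FALSE)
  n <- as.integer(round(n))
  if (abs((n - 1) * step_mm - extent_mm) > 1e-9)
    stop("grid arithmetic failed consistency check", call. = FALSE)
  ax <- lapply(1:3, function(i) origin_mm[i] + (seq_len(n) - 1) * step_mm)
  structure(list(extent_mm = extent_mm, step_mm = step_mm, n = n,
                 origin_mm = origin_mm,
                 x = ax[[1]], y = ax[[2]], z = ax[[3]]),
            class = "cartesian_grid")
}

#' @export
print.cartesian_grid <- function(x, ...) {
  cat(sprintf("<cartesian_grid> %d^3 voxels, %g mm pitch, %g mm extent\n",
              x$n, x$step_mm, x$extent_mm))
  invisible(x)
}

grid_dim <- function(grid) rep(grid$n, 3L)

# Default transducer apex: on the z (range) axis through the grid center,
# 30 mm before it, so the needle tip at the grid center sits at 30 mm range.
default_apex <- function(grid, standoff_mm = 30) {
  c(mean(range(grid$x)), mean(range(grid$y)), mean(range(grid$z)) - standoff_mm)
}

# Coordinate arrays (mm) for every voxel of the grid, as long vectors in
# array order [x, y, z].
grid_coords <- function(grid) {
  n <- grid$n
  list(x = rep(grid$x, times = n * n),
       y = rep(rep(grid$y, each = n), times = n),
       z = rep(grid$z, each = n * n))
}

# Vectorized trilinear interpolation on a 3D array at fractional indices
# (fi, fj, fk), 1-based. Out-of-range queries must be pre-masked by `ok`.
trilinear <- function(vol, fi, fj, fk, ok) {
  d <- dim(vol)
  out <- rep(if (is.complex(vol)) NA_complex_ else NA_real_, length(fi))
  if (!any(ok)) return(out)
  fi <- fi[ok]; fj <- fj[ok]; fk <- fk[ok]
  i0 <- pmin(pmax(floor(fi), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(fj), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(fk), 1), d[3] - 1)
  wi <- fi - i0; wj <- fj - j0; wk <- fk - k0
  s1 <- d[1]; s2 <- d[1] * d[2]
  base <- (i0 - 1) + (j0 - 1) * s1 + (k0 - 1) * s2 + 1
  v000 <- vol[base];            v100 <- vol[base + 1]
  v010 <- vol[base + s1];       v110 <- vol[base + 1 + s1]
  v001 <- vol[base + s2];       v101 <- vol[base + 1 + s2]
  v011 <- vol[base + s1 + s2];  v111 <- vol[base + 1 + s1 + s2]
  out[ok] <-
    v000 * (1 - wi) * (1 - wj) * (1 - wk) + v100 * wi * (1 - wj) * (1 - wk) +
    v010 * (1 - wi) * wj       * (1 - wk) + v110 * wi * wj       * (1 - wk) +
    v001 * (1 - wi) * (1 - wj) * wk       + v101 * wi * (1 - wj) * wk +
    v011 * (1 - wi) * wj       * wk       + v111 * wi * wj       * wk
  out
}

# Map Cartesian voxel coordinates to beam coordinates under the
# separable-angle sector convention: azimuth angle in the y-z plane,
# elevation angle in the x-z plane, range along the beam.
cart_to_beam_coords <- function(xx, yy, zz, geometry, apex_mm) {
  dx <- xx - apex_mm[1]; dy <- yy - apex_mm[2]; dz <- zz - apex_mm[3]
  rng <- sqrt(dx^2 + dy^2 + dz^2)
  az <- atan2(dy, dz)
  el <- atan2(dx, dz)
  list(range = rng, azimuth = az, elevation = el, forward = dz > 0)
}

#' Scan-convert a beam-domain sector volume to the Cartesian grid
#'
#' Resamples a (complex or real) beam-domain field onto the Cartesian grid by
#' trilinear interpolation in beam coordinates (range, azimuth angle,
#' elevation angle). Voxels outside the imaged sector -- behind the apex,
#' beyond the angular span, or deeper than the imaging depth -- are flagged
#' invalid and set to zero.
#'
#' @param iq Beam-domain array, dims `[n_range, n_azimuth, n_elevation]`.
#' @param geometry A [beam_geometry()].
#' @param grid A [cartesian_grid()].
#' @param apex_mm Position of the sector apex in grid coordinates; default
#'   places it 30 mm before the grid center along -z.
#' @return A list with `field` (Cartesian array, zero where invalid) and
#'   `validity` (logical array).
#' @export
scan_convert <- function(iq, geometry, grid, apex_mm = default_apex(grid)) {
  if (!identical(dim(iq), as.integer(beam_dim(geometry))))
    stop("iq dimensions do not match geometry", call. = FALSE)
  co <- grid_coords(grid)
  bc <- cart_to_beam_coords(co$x, co$y, co$z, geometry, apex_mm)
  ang <- beam_angles(geometry)
  half_az <- geometry$azimuth_span_deg / 2 * pi / 180
  half_el <- geometry$elevation_span_deg / 2 * pi / 180
  ok <- bc$forward &
    bc$range <= geometry$depth_mm &
    abs(bc$azimuth) <= half_az & abs(bc$elevation) <= half_el
  if (!any(ok))
    stop("grid lies entirely outside the imaged sector", call. = FALSE)
  fi <- bc$range / geometry$range_step_mm + 1
  fj <- (bc$azimuth - ang$azimuth[1]) / diff(ang$azimuth[1:2]) + 1
  fk <- (bc$elevation - ang$elevation[1]) / diff(ang$elevation[1:2]) + 1
  vals <- trilinear(iq, fi, fj, fk, ok)
  vals[!ok] <- if (is.complex(iq)) 0 + 0i else 0
  list(field = array(vals, grid_dim(grid)),
       validity = array(ok, grid_dim(grid)))
}

#' Resample a Cartesian field onto the beam sampling (inverse scan conversion)
#'
#' Evaluates a real Cartesian field at every beam sample position by
#' trilinear interpolation; positions outside the Cartesian grid take `fill`.
#' Used to carry ground-truth coherence fields, defined on the Cartesian grid,
#' into the beam domain where echoes are synthesized.
#'
#' @param field Real Cartesian array on `grid`.
#' @param grid,geometry,apex_mm As in [scan_convert()].
#' @param fill Value for beam samples outside the grid (default 1, i.e.
#'   unchanged tissue for a coherence field).
#' @return Beam-domain array, dims `[n_range, n_azimuth, n_elevation]`.
#' @export
resample_to_beam <- function(field, grid, geometry,
                             apex_mm = default_apex(grid), fill = 1) {
  ang <- beam_angles(geometry)
  rng <- (seq_len(geometry$n_range) - 1) * geometry$range_step_mm
  nb <- beam_dim(geometry)
  R <- rep(rng, times = nb[2] * nb[3])
  A <- rep(rep(ang$azimuth, each = nb[1]), times = nb[3])
  E <- rep(ang$elevation, each = nb[1] * nb[2])
  ta <- tan(A); te <- tan(E)
  dz <- R / sqrt(1 + ta^2 + te^2)
  dy <- dz * ta
  dx <- dz * te
  xx <- apex_mm[1] + dx; yy <- apex_mm[2] + dy; zz <- apex_mm[3] + dz
  fi <- (xx - grid$x[1]) / grid$step_mm + 1
  fj <- (yy - grid$y[1]) / grid$step_mm + 1
  fk <- (zz - grid$z[1]) / grid$step_mm + 1
  n <- grid$n
  eps <- 1e-9
  ok <- fi >= 1 - eps & fi <= n + eps & fj >= 1 - eps & fj <= n + eps &
    fk >= 1 - eps & fk <= n + eps
  vals <- trilinear(field, pmin(pmax(fi, 1), n), pmin(pmax(fj, 1), n),
                    pmin(pmax(fk, 1), n), ok)
  vals[!ok] <- fill
  array(vals, nb)
}
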