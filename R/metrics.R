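# Ablation-zone geometry and outcome metrics: sphere masks, volumes, rates,
# Dice overlap, and the 2D-section / 3D-reconstruction round trip emulating
# histology processing of sliced specimens.

#' Binary ablation mask on the Cartesian grid
#'
#' @param mask Logical (or 0/1) array on the grid.
#' @param grid A [cartesian_grid()].
#' @param provenance One of `"truth"`, `"reconstructed"`, `"target"`.
#' @return An object of class `ablation_mask`.
#' @export
ablation_mask <- function(mask, grid,
                          provenance = c("truth", "reconstructed", "target")) {
  provenance <- match.arg(provenance)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), grid_dim(grid)))
    stop("mask dimensions do not match grid", call. = FALSE)
  structure(list(mask = mask, grid = grid, provenance = provenance),
            class = "ablation_mask")
}

#' @export
print.ablation_mask <- function(x, ...) {
  cat(sprintf("<ablation_mask> (%s) %d voxels, %.3f ml\n",
              x$provenance, sum(x$mask), mask_volume_ml(x)))
  invisible(x)
}

#' Spherical mask on the Cartesian grid
#'
#' Voxels whose centers lie within the closed ball of the given diameter.
#' Used for the control ROI (20 mm), the evaluation ROI (50 mm diameter,
#' i.e. 25 mm radius) and targeted ablation zones.
#'
#' @param grid A [cartesian_grid()].
#' @param center_mm Ball center in grid coordinates.
#' @param diameter_mm Ball diameter in mm.
#' @param provenance Mask provenance tag.
#' @return An `ablation_mask`.
#' @export
sphere_mask <- function(grid, center_mm = c(0, 0, 0), diameter_mm,
                        provenance = "target") {
  co <- grid_coords(grid)
  r2 <- (co$x - center_mm[1])^2 + (co$y - center_mm[2])^2 +
    (co$z - center_mm[3])^2
  m <- array(r2 <= (diameter_mm / 2)^2 + 1e-12, grid_dim(grid))
  ablation_mask(m, grid, provenance)
}

#' Mask volume in milliliters
#'
#' Voxel count times the voxel volume (`step_mm^3`), converted from mm^3 to
#' ml.
#'
#' @param mask An `ablation_mask` or logical array (then `grid` is required).
#' @param grid Grid for plain arrays.
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask, grid = NULL) {
  if (inherits(mask, "ablation_mask")) {
    grid <- mask$grid
    mask <- mask$mask
  }
  if (is.null(grid)) stop("grid required for plain arrays", call. = FALSE)
  sum(mask) * grid$step_mm^3 / 1000
}

#' Ablation rate
#'
#' @param volume_ml Measured ablated volume in ml.
#' @param duration_min RF-on duration in minutes.
#' @return Rate in ml per minute.
#' @export
ablation_rate <- function(volume_ml, duration_min) {
  if (any(duration_min <= 0))
    stop("duration_min must be positive", call. = FALSE)
  volume_ml / duration_min
}

#' Dice overlap coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks are defined to have
#' Dice 1 (identity convention).
#'
#' @param a,b `ablation_mask` objects or logical arrays of equal dims.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (inherits(a, "ablation_mask")) a <- a$mask
  if (inherits(b, "ablation_mask")) b <- b$mask
  if (!identical(dim(a), dim(b)))
    stop("masks must share dimensions", call. = FALSE)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Section a mask into slabs and reconstruct it, emulating histology
#'
#' Slabs the mask along the elevation axis at the given thickness, takes each
#' slab's mid-plane cross-section as the segmented 2D section, and
#' reconstructs the 3D zone by extruding each section across its slab -- the
#' geometric round trip of slicing an ablated specimen, scanning the slices,
#' and re-registering them at their elevational positions. The last slab may
#' be thinner if the extent is not a multiple of the thickness. The
#' reconstruction error this introduces shrinks with the slab thickness.
#'
#' @param mask An `ablation_mask`.
#' @param thickness_mm Section thickness in mm (the emulated study sliced at
#'   3--4 mm).
#' @return An `ablation_mask` with provenance `"reconstructed"`.
#' @export
section_and_reconstruct <- function(mask, thickness_mm = 3.5) {
  if (!inherits(mask, "ablation_mask"))
    stop("mask must be an ablation_mask", call. = FALSE)
  if (thickness_mm <= 0) stop("thickness must be positive", call. = FALSE)
  grid <- mask$grid
  m <- mask$mask
  n <- grid$n
  step <- grid$step_mm
  # elevation axis is x = array dim 1; slab boundaries in voxel index units
  vox_per_slab <- thickness_mm / step
  starts <- seq(1, n, by = vox_per_slab)
  out <- array(FALSE, dim(m))
  for (s in starts) {
    i0 <- as.integer(ceiling(s - 1e-9))
    i1 <- min(n, as.integer(floor(s + vox_per_slab - 1e-9)))
    if (i1 < i0) next
    mid <- as.integer(round((i0 + i1) / 2))
    section <- m[mid, , ]
    out[i0:i1, , ] <- rep(section, each = i1 - i0 + 1)
  }
  ablation_mask(out, grid, provenance = "reconstructed")
}
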