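#' Calibrated density volume
#'
#' The raw substrate of every analysis stage: a 3D grid of calibrated
#' mineral density in mgHA/cm^3 on an isotropic voxel grid. The first array
#' index is the axial slice along the anatomical long axis; the second and
#' third indices are the in-plane row and column.
#'
#' @param values 3D numeric array of densities (mgHA/cm^3).
#' @param voxel_size Isotropic voxel edge length in micrometres (> 0).
#' @return An object of class `density_volume`.
#' @examples
#' v <- density_volume(array(0, c(4, 4, 4)), voxel_size = 12)
#' dim(v)
#' @export
density_volume <- function(values, voxel_size) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all three voxel dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || !is.finite(voxel_size) ||
      voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)", call. = FALSE)
  if (!all(is.finite(values)))
    stop("density values must be finite", call. = FALSE)
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size)),
    class = "density_volume"
  )
}

#' Binary bone mask
#'
#' A segmented bone/non-bone mask on the same grid as its source density
#' volume, carrying the segmentation parameters as provenance.
#'
#' @param mask 3D logical array (`TRUE` = bone).
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param provenance Named list of the parameters that produced the mask.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, voxel_size, provenance = list()) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)", call. = FALSE)
  structure(
    list(mask = mask, voxel_size = as.numeric(voxel_size), provenance = provenance),
    class = "binary_volume"
  )
}

#' @export
dim.density_volume <- function(x) dim(x$values)

#' @export
dim.binary_volume <- function(x) dim(x$mask)

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels @ %g um\n", d[1], d[2], d[3],
              x$voxel_size))
  cat(sprintf("  density range: [%.1f, %.1f] mgHA/cm^3\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %g um, %d bone voxels (%.1f%%)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

# voxel volume in mm^3 (edge in um -> mm)
voxel_volume_mm3 <- function(voxel_size) (voxel_size / 1000)^3

as_mask_array <- function(x) {
  if (inherits(x, "binary_volume")) x$mask
  else if (is.array(x) && length(dim(x)) == 3L) {
    storage.mode(x) <- "logical"
    x
  } else stop("expected a binary_volume or 3D array", call. = FALSE)
}

#' Ground truth descriptor for a synthetic phantom
#'
#' Records what a phantom generator knows analytically about the structure it
#' emitted, so downstream measurements can be checked against construction.
#'
#' @param true_bvtv Bone volume fraction in `[0, 1]`.
#' @param principal_axis Unit 3-vector of the dominant structural axis, or
#'   `NULL` when the structure has no preferred direction.
#' @param betti1 Number of independent loops when known analytically
#'   (`NA` otherwise).
#' @param component_count Number of connected components (`NA` if unknown).
#' @param extra Named list of generator-specific ground truth (compartment
#'   masks, structural-element labels, plate normals, ...).
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(true_bvtv, principal_axis = NULL, betti1 = NA_integer_,
                          component_count = NA_integer_, extra = list()) {
  stopifnot(is.numeric(true_bvtv), length(true_bvtv) == 1L,
            true_bvtv >= 0, true_bvtv <= 1)
  if (!is.null(principal_axis)) {
    stopifnot(length(principal_axis) == 3L)
    nrm <- sqrt(sum(principal_axis^2))
    if (abs(nrm - 1) > 1e-8)
      principal_axis <- principal_axis / nrm
  }
  structure(
    list(true_bvtv = true_bvtv, principal_axis = principal_axis,
         betti1 = betti1, component_count = component_count, extra = extra),
    class = "phantom_truth"
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> BV/TV = %.4f", x$true_bvtv))
  if (!is.null(x$principal_axis))
    cat(sprintf(", principal axis = (%.2f, %.2f, %.2f)",
                x$principal_axis[1], x$principal_axis[2], x$principal_axis[3]))
  if (!is.na(x$betti1)) cat(sprintf(", beta1 = %d", x$betti1))
  cat("\n")
  invisible(x)
}
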