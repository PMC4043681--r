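# Directional sampling and the classical test-line mean intercept length.
# The test-line estimator is the field's traditional MIL and serves as the
# independent oracle for the surface-projection estimator.

#' Quasi-uniform hemisphere directions
#'
#' Deterministic spherical Fibonacci lattice on the upper hemisphere.
#' MIL is antipodally symmetric, so one hemisphere suffices; the lattice
#' gives quasi-uniform coverage and, for n >= 128, a direction set whose
#' mean outer product is close to I/3 (the isotropy condition).
#'
#' @param n Number of directions (>= 9, the minimum to overdetermine the
#'   six-parameter fabric tensor fit).
#' @return An `n x 3` matrix of unit row vectors, class `direction_set`.
#' @examples
#' d <- sample_directions(64)
#' range(rowSums(d^2))
#' @export
sample_directions <- function(n) {
  if (!(is.numeric(n) && length(n) == 1L && n >= 9))
    stop("`n` must be >= 9 (six tensor parameters must be overdetermined)",
         call. = FALSE)
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- (i + 0.5) / n                     # strictly inside (0, 1): no equator pairs
  phi <- i * pi * (3 - sqrt(5))          # golden angle
  s <- sqrt(1 - z^2)
  d <- cbind(x = s * cos(phi), y = s * sin(phi), z = z)
  class(d) <- c("direction_set", class(d))
  d
}

as_direction_matrix <- function(directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1)
  directions <- unclass(directions)
  stopifnot(ncol(directions) == 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) directions <- directions / nrm
  directions
}

# orthonormal basis perpendicular to a unit vector
perp_basis <- function(d) {
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Prepare a bone field for test-line sampling
#'
#' Test lines sample the bone phase as the 0.5 level set of the Gaussian
#' pre-smoothed binary field -- the same level set the surface triangulation
#' extracts. Sampling the raw staircase instead would count spurious
#' crossings on oblique rays and bias MIL low. Preparing the field once and
#' passing it to [mil_test_lines()] for many directions avoids re-smoothing.
#'
#' @param mask A [binary_volume] containing bone.
#' @param smooth_sigma,smooth_support Pre-smoothing Gaussian width and
#'   truncation radius in voxels (defaults match [triangulate_surface()]);
#'   `smooth_sigma = 0` samples the raw binary field.
#' @return An object of class `mil_field`.
#' @export
prepare_mil_field <- function(mask, smooth_sigma = 0.9, smooth_support = 2L) {
  A <- as_mask_array(mask)
  if (!any(A)) stop("mask contains no bone", call. = FALSE)
  vs <- mask$voxel_size
  field <- array(as.double(A), dim(A))
  if (smooth_sigma > 0 && smooth_support > 0) {
    sm <- smooth_array(field, smooth_sigma, as.integer(smooth_support))
    if (any(sm >= 0.5)) field <- sm
    else warning("pre-smoothing erased the bone phase; sampling the raw binary field",
                 call. = FALSE)
  }
  structure(list(field = field, voxel_size = vs, dim = dim(A)),
            class = "mil_field")
}

# trilinear interpolation of a 3D field at scattered points (outside -> 0)
trilinear_sample <- function(field, dm, x, y, z) {
  v <- numeric(length(x))
  ok <- x >= 1 & x <= dm[1] & y >= 1 & y <= dm[2] & z >= 1 & z <= dm[3]
  if (!any(ok)) return(v)
  x <- pmin(x[ok], dm[1] - 1e-9); y <- pmin(y[ok], dm[2] - 1e-9)
  z <- pmin(z[ok], dm[3] - 1e-9)
  i0 <- pmax(floor(x), 1); j0 <- pmax(floor(y), 1); k0 <- pmax(floor(z), 1)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  n12 <- dm[1] * dm[2]
  base <- i0 + (j0 - 1) * dm[1] + (k0 - 1) * n12
  acc <-
    field[base] * (1 - fx) * (1 - fy) * (1 - fz) +
    field[base + 1] * fx * (1 - fy) * (1 - fz) +
    field[base + dm[1]] * (1 - fx) * fy * (1 - fz) +
    field[base + dm[1] + 1] * fx * fy * (1 - fz) +
    field[base + n12] * (1 - fx) * (1 - fy) * fz +
    field[base + n12 + 1] * fx * (1 - fy) * fz +
    field[base + n12 + dm[1]] * (1 - fx) * fy * fz +
    field[base + n12 + dm[1] + 1] * fx * fy * fz
  v[ok] <- acc
  v
}

#' Test-line mean intercept length along one direction
#'
#' Casts a grid of parallel rays through the region's bounding box with the
#' stated perpendicular spacing, samples the bone phase (the 0.5 level of
#' the prepared field, trilinearly interpolated) at sub-voxel steps, and
#' returns MIL = (total traversed length inside bone) / (number of
#' marrow-to-bone entry crossings). Rays that carry bone but never cross an
#' interface (boundary-spanning struts) contribute their bone length with
#' zero crossings; crossings are only counted strictly inside the region,
#' so rays entering through a region face do not inflate the interface
#' count.
#'
#' @param mask A [binary_volume] containing bone, or a prepared
#'   [prepare_mil_field()] object (cheaper when evaluating many directions).
#' @param direction Unit 3-vector.
#' @param line_spacing Perpendicular ray spacing in voxels (default 2).
#' @param step Sampling step along the ray in voxels (<= 0.5; default 0.5).
#' @return MIL in micrometres. If no ray records a crossing the MIL is the
#'   total bone length capped at the bounding-box diagonal, with a warning.
#' @export
mil_test_lines <- function(mask, direction, line_spacing = 2, step = 0.5) {
  fld <- if (inherits(mask, "mil_field")) mask else prepare_mil_field(mask)
  stopifnot(step <= 0.5, step > 0, line_spacing > 0)
  vs <- fld$voxel_size
  dm <- fld$dim
  field <- fld$field
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  ctr <- (dm + 1) / 2
  R <- sqrt(sum(dm^2)) / 2
  b <- perp_basis(d)
  offs <- seq(-R, R, by = line_spacing)
  grid <- expand.grid(a = offs, b = offs)
  grid <- grid[grid$a^2 + grid$b^2 <= R^2 + 2 * line_spacing^2, , drop = FALSE]
  n_ray <- nrow(grid)
  o1 <- ctr[1] + grid$a * b$u[1] + grid$b * b$v[1]
  o2 <- ctr[2] + grid$a * b$u[2] + grid$b * b$v[2]
  o3 <- ctr[3] + grid$a * b$u[3] + grid$b * b$v[3]
  ts <- seq(-R, R, by = step)
  prev_bone <- rep(FALSE, n_ray)
  prev_inb <- rep(FALSE, n_ray)
  n_bone_samples <- 0
  n_entries <- 0
  for (t in ts) {
    x <- o1 + t * d[1]
    y <- o2 + t * d[2]
    z <- o3 + t * d[3]
    inb <- x >= 1 & x <= dm[1] & y >= 1 & y <= dm[2] & z >= 1 & z <= dm[3]
    bone <- trilinear_sample(field, dm, x, y, z) >= 0.5
    n_bone_samples <- n_bone_samples + sum(bone)
    n_entries <- n_entries + sum(prev_inb & !prev_bone & inb & bone)
    prev_bone <- bone
    prev_inb <- inb
  }
  total_len <- n_bone_samples * step * vs
  diag_um <- sqrt(sum(dm^2)) * vs
  if (n_entries == 0) {
    warning("no marrow-to-bone crossings on any test line; MIL capped at the bounding-box diagonal",
            call. = FALSE)
    return(min(total_len, diag_um))
  }
  total_len / n_entries
}
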