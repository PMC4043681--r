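# Synthetic bone phantoms with analytically known structure.
#
# Density convention: bone voxels at 700 mgHA/cm^3, background at 0, so the
# standard segmentation threshold of 439.0 mgHA/cm^3 cleanly bisects the two
# phases before any noise is added.

PHANTOM_BONE_DENSITY <- 700
PHANTOM_BG_DENSITY <- 0

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_shape <- function(shape) {
  if (length(shape) != 3L || any(shape < 1) || any(shape != round(shape)))
    stop("`shape` must be three positive integers", call. = FALSE)
  as.integer(shape)
}

unit_axis <- function(axis) {
  v <- c(0, 0, 0)
  v[axis] <- 1
  v
}

#' Parallel-plate phantom (organized anisotropic bone stand-in)
#'
#' Periodic parallel plates perpendicular to one axis. Healthy, organized
#' bone is strongly anisotropic; the plate lattice is the cleanest structure
#' with a known volume fraction and a known structural plane (the longest
#' mean intercept length lies in the plate plane).
#'
#' @param shape Integer vector of three voxel dimensions (slice, row, column).
#' @param voxel_size Voxel edge in micrometres.
#' @param plate_thickness,plate_spacing Plate thickness and gap in voxels
#'   (each >= 1).
#' @param normal_axis Axis index (1..3) the plates are perpendicular to.
#' @param bone_density,bg_density Densities assigned to bone and background
#'   voxels (mgHA/cm^3); bone must exceed background.
#' @return A list with elements `volume` (a [density_volume]) and `truth`
#'   (a [phantom_truth]; `extra$plate_normal` holds the plate normal).
#' @examples
#' p <- make_plate_phantom(c(16, 16, 16), plate_thickness = 2, plate_spacing = 2)
#' p$truth$true_bvtv
#' @export
make_plate_phantom <- function(shape, voxel_size = 12, plate_thickness = 2,
                               plate_spacing = 2, normal_axis = 1,
                               bone_density = PHANTOM_BONE_DENSITY,
                               bg_density = PHANTOM_BG_DENSITY) {
  shape <- check_shape(shape)
  stopifnot(plate_thickness >= 1, plate_spacing >= 1, bone_density > bg_density,
            normal_axis %in% 1:3)
  period <- plate_thickness + plate_spacing
  if (shape[normal_axis] < period)
    stop(sprintf("shape along axis %d (%d voxels) is smaller than one plate period (%d voxels)",
                 normal_axis, shape[normal_axis], period), call. = FALSE)
  idx <- seq_len(shape[normal_axis])
  in_plate <- ((idx - 1L) %% period) < plate_thickness
  vals <- array(bg_density, shape)
  sel <- switch(normal_axis,
                `1` = in_plate,
                `2` = rep(in_plate, each = shape[1]),
                `3` = rep(in_plate, each = shape[1] * shape[2]))
  vals[which(rep_len(sel, prod(shape)))] <- bone_density
  vol <- density_volume(vals, voxel_size)
  truth <- phantom_truth(
    true_bvtv = mean(vals == bone_density),
    principal_axis = NULL,
    component_count = sum(((idx - 1L) %% period) == 0L),
    extra = list(plate_normal = unit_axis(normal_axis),
                 plate_thickness = plate_thickness,
                 plate_spacing = plate_spacing)
  )
  list(volume = vol, truth = truth)
}

# precomputed voxel offsets within a sphere of given radius
sphere_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Isotropic Boolean phantom (union of random spheres)
#'
#' A Boolean model: spheres of fixed radius at Poisson-random centers, with
#' the number of spheres adjusted until the achieved bone volume fraction is
#' within 0.02 of the target. Isotropic by construction -- the directional
#' mean-intercept-length distribution is a sphere, the reference condition
#' for degree of anisotropy DA = 1.
#'
#' @inheritParams make_plate_phantom
#' @param sphere_radius Grain radius in voxels (>= 2).
#' @param target_bvtv Target bone volume fraction, strictly in (0, 1).
#' @param seed Integer RNG seed; identical seeds give bit-identical volumes.
#' @return A list with `volume` and `truth` (`principal_axis = NULL`).
#' @export
make_isotropic_boolean <- function(shape, voxel_size = 12, sphere_radius = 5,
                                   target_bvtv = 0.3, seed = 1,
                                   bone_density = PHANTOM_BONE_DENSITY,
                                   bg_density = PHANTOM_BG_DENSITY) {
  shape <- check_shape(shape)
  if (!(target_bvtv > 0 && target_bvtv < 1))
    stop("`target_bvtv` must be strictly between 0 and 1", call. = FALSE)
  if (sphere_radius < 2) stop("`sphere_radius` must be >= 2", call. = FALSE)
  if (2 * sphere_radius > max(shape))
    stop("sphere does not fit in the volume; target unreachable", call. = FALSE)
  offs <- sphere_offsets(sphere_radius)
  v_sph <- nrow(offs)
  total <- prod(shape)
  mask <- array(FALSE, shape)
  with_seed(seed, {
    # expected Boolean-model count over the radius-extended center domain
    ext <- prod(shape + 2 * ceiling(sphere_radius))
    n_exp <- max(1, ceiling(-log1p(-target_bvtv) * ext / v_sph))
    achieved <- 0
    guard <- 0L
    # small volumes take one sphere at a time so the overshoot stays well
    # inside the +/- 0.02 contract
    batch_cap <- if (total < 2e5) 1L else 25L
    while (achieved < target_bvtv && guard < 10000L) {
      guard <- guard + 1L
      n_batch <- max(1L, min(batch_cap, ceiling(n_exp / 10)))
      centers <- cbind(
        round(stats::runif(n_batch, 1 - sphere_radius, shape[1] + sphere_radius)),
        round(stats::runif(n_batch, 1 - sphere_radius, shape[2] + sphere_radius)),
        round(stats::runif(n_batch, 1 - sphere_radius, shape[3] + sphere_radius))
      )
      pts <- cbind(
        rep(centers[, 1], each = v_sph) + offs[, 1],
        rep(centers[, 2], each = v_sph) + offs[, 2],
        rep(centers[, 3], each = v_sph) + offs[, 3]
      )
      ok <- pts[, 1] >= 1 & pts[, 1] <= shape[1] &
            pts[, 2] >= 1 & pts[, 2] <= shape[2] &
            pts[, 3] >= 1 & pts[, 3] <= shape[3]
      lin <- pts[ok, 1] + (pts[ok, 2] - 1) * shape[1] +
        (pts[ok, 3] - 1) * shape[1] * shape[2]
      mask[lin] <- TRUE
      achieved <- sum(mask) / total
    }
  })
  achieved <- sum(mask) / total
  if (abs(achieved - target_bvtv) > 0.02)
    stop(sprintf("target BV/TV %.2f unreachable (achieved %.3f) at this radius/shape",
                 target_bvtv, achieved), call. = FALSE)
  vals <- array(bg_density, shape)
  vals[mask] <- bone_density
  list(volume = density_volume(vals, voxel_size),
       truth = phantom_truth(true_bvtv = achieved, principal_axis = NULL,
                             extra = list(sphere_radius = sphere_radius,
                                          target_bvtv = target_bvtv, seed = seed)))
}

#' Cortical cylinder phantom (diaphysis-like shell)
#'
#' A hollow (or, with `inner_radius = 0`, solid) circular tube along one
#' axis, emulating the diaphyseal cortex. The long bone's primary axis is
#' the tube axis.
#'
#' @inheritParams make_plate_phantom
#' @param outer_radius,inner_radius Shell radii in voxels,
#'   `0 <= inner_radius < outer_radius`; the tube must fit inside the
#'   cross-section.
#' @param axis Axis index (1..3) of the tube.
#' @return A list with `volume` and `truth` (`principal_axis` = tube axis;
#'   `extra$analytic_bvtv` = pi (R^2 - r^2) / cross-section area).
#' @export
make_cortical_cylinder <- function(shape, voxel_size = 12, outer_radius,
                                   inner_radius = 0, axis = 1,
                                   bone_density = PHANTOM_BONE_DENSITY,
                                   bg_density = PHANTOM_BG_DENSITY) {
  shape <- check_shape(shape)
  stopifnot(axis %in% 1:3)
  if (!(inner_radius >= 0 && inner_radius < outer_radius))
    stop("need 0 <= inner_radius < outer_radius", call. = FALSE)
  cross <- shape[-axis]
  if (2 * outer_radius > min(cross))
    stop("cylinder does not fit in the cross-section", call. = FALSE)
  c1 <- (cross[1] + 1) / 2
  c2 <- (cross[2] + 1) / 2
  r2 <- outer(seq_len(cross[1]) - c1, seq_len(cross[2]) - c2,
              function(a, b) a^2 + b^2)
  ring <- r2 <= outer_radius^2 & r2 > inner_radius^2
  vals <- array(bg_density, shape)
  n_ax <- shape[axis]
  ring_rep <- switch(axis,
                     `1` = aperm(array(ring, c(cross, n_ax)), c(3, 1, 2)),
                     `2` = aperm(array(ring, c(cross, n_ax)), c(1, 3, 2)),
                     `3` = array(ring, c(cross, n_ax)))
  vals[ring_rep] <- bone_density
  list(
    volume = density_volume(vals, voxel_size),
    truth = phantom_truth(
      true_bvtv = mean(ring_rep),
      principal_axis = unit_axis(axis),
      component_count = 1L,
      extra = list(axis = axis, outer_radius = outer_radius,
                   inner_radius = inner_radius,
                   analytic_bvtv = pi * (outer_radius^2 - inner_radius^2) /
                     prod(cross))
    )
  )
}

#' Metaphysis-like composite phantom (flared cortical shell + trabecular lattice)
#'
#' A cortical shell along the long axis, widening linearly like the
#' metaphyseal flare of a real long bone and carrying gentle circumferential
#' surface ridging (real periosteal surfaces are not smooth), enclosing an
#' interior trabecular lattice aligned with the long axis the way
#' metaphyseal trabeculae align with load: a central honeycomb prism whose
#' axial channels carry the structure's independent loops, surrounded by a
#' ring of free vertical rods. All interior structures are prismatic along
#' the long axis, so the phantom has a strong, known principal direction,
#' and every structural element (the honeycomb, each rod) is recorded with
#' a label so osteolysis can remove whole elements. Ground-truth compartment
#' masks are recorded for compartment-splitting tests.
#'
#' @inheritParams make_cortical_cylinder
#' @param outer_radius,inner_radius Shell radii in voxels at the first
#'   slice; `inner_radius` must be at least 12 so the honeycomb fits.
#' @param n_rods Number of free vertical rods around the honeycomb
#'   (default 6).
#' @param rod_radius Rod radius in voxels (default 2.2).
#' @param hole_radius Radius of the honeycomb's axial channels in voxels
#'   (default 2; channels below ~2 voxels close under mesh smoothing).
#' @param flare Fractional linear radius increase over the phantom length
#'   (default 0.15, a gentle metaphyseal cone).
#' @param ridge_amplitude,ridge_period Amplitude (voxels) and axial period
#'   (slices) of the circumferential periosteal ridging;
#'   `ridge_amplitude = 0` disables.
#' @param seed Integer seed; randomizes the lattice orientation and rod
#'   placement jitter.
#' @return A list with `volume` and `truth`; `truth$extra` carries logical
#'   `cortical` and `trabecular` masks (disjoint, covering all bone), an
#'   integer `elements` array labelling each trabecular element (0 = not
#'   bone; 1 = honeycomb; 2.. = rods), and the per-slice squared outer
#'   radii `outer_r2` used by [apply_tumor()].
#' @export
make_metaphysis_like <- function(shape, voxel_size = 12, outer_radius,
                                 inner_radius, n_rods = 6, rod_radius = 2.2,
                                 hole_radius = 2, flare = 0.15,
                                 ridge_amplitude = 1.5, ridge_period = 8L,
                                 axis = 1, seed = 1,
                                 bone_density = PHANTOM_BONE_DENSITY,
                                 bg_density = PHANTOM_BG_DENSITY) {
  shape <- check_shape(shape)
  if (axis != 1)
    stop("the composite phantom uses axis 1 (the slice axis) as the long axis",
         call. = FALSE)
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop("need 0 < inner_radius < outer_radius", call. = FALSE)
  if (inner_radius < 12)
    stop("inner_radius must be >= 12 voxels for the honeycomb lattice: parameter conflict",
         call. = FALSE)
  stopifnot(n_rods >= 0, rod_radius >= 1.5, hole_radius >= 1.5)
  n1 <- shape[1]
  cross <- shape[-1]
  grow <- 1 + flare * (seq_len(n1) - 1) / max(1, n1 - 1)
  ridge <- if (ridge_amplitude > 0)
    ridge_amplitude * ((seq_len(n1) - 1L) %% ridge_period < ridge_period / 2)
  else rep(0, n1)
  outer_r <- outer_radius * grow + ridge
  inner_r <- inner_radius * grow
  if (2 * max(outer_r) > min(cross))
    stop("flared shell does not fit in the cross-section", call. = FALSE)
  c1 <- (cross[1] + 1) / 2
  c2 <- (cross[2] + 1) / 2
  r2 <- outer(seq_len(cross[1]) - c1, seq_len(cross[2]) - c2,
              function(a, b) a^2 + b^2)
  r2v <- as.vector(r2)
  # (slice, in-plane) occupancy from per-slice radii
  cort_flat <- outer(seq_len(n1), r2v,
                     function(i, r) r <= outer_r[i]^2 & r > inner_r[i]^2)
  cortical <- array(cort_flat, shape)
  X <- as.vector(outer(seq_len(cross[1]) - c1, rep(1, cross[2])))
  Y <- as.vector(outer(rep(1, cross[1]), seq_len(cross[2]) - c2))
  pars <- with_seed(seed, list(
    phi0 = stats::runif(1, 0, 2 * pi),
    rod_dth = stats::runif(n_rods, -0.08, 0.08),
    rod_dr = stats::runif(n_rods, -0.4, 0.4)
  ))
  # element 1: honeycomb prism (disc with 7 axial channels: center + hex ring)
  hc_radius <- inner_radius - 6
  hole_pitch <- hc_radius - hole_radius - 2
  hc <- sqrt(X^2 + Y^2) <= hc_radius
  for (h in 0:6) {
    hx <- if (h == 0) 0 else hole_pitch * cos(pars$phi0 + (h - 1) * pi / 3)
    hy <- if (h == 0) 0 else hole_pitch * sin(pars$phi0 + (h - 1) * pi / 3)
    hc <- hc & !((X - hx)^2 + (Y - hy)^2 <= hole_radius^2)
  }
  plane_el <- integer(length(r2v))
  plane_el[hc] <- 1L
  # elements 2..: free rods on a ring between honeycomb and shell
  rod_ring <- inner_radius - 3
  for (j in seq_len(n_rods)) {
    th <- pars$phi0 + pi / 6 + (j - 1) * 2 * pi / max(1, n_rods) + pars$rod_dth[j]
    rr <- rod_ring + pars$rod_dr[j]
    hit <- (X - rr * cos(th))^2 + (Y - rr * sin(th))^2 <= rod_radius^2
    plane_el[plane_el == 0L & hit] <- 1L + j
  }
  el_flat <- outer(seq_len(n1), seq_along(r2v),
                   function(i, j) ifelse(r2v[j] <= inner_r[i]^2,
                                         plane_el[j], 0L))
  elements <- array(as.integer(el_flat), shape)
  trabecular <- elements > 0L
  vals <- array(bg_density, shape)
  vals[cortical | trabecular] <- bone_density
  truth <- phantom_truth(
    true_bvtv = mean(cortical | trabecular),
    principal_axis = unit_axis(axis),
    component_count = 1L,
    extra = list(cortical = cortical, trabecular = trabecular,
                 elements = elements, axis = axis,
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 outer_r2 = outer_r^2, flare = flare,
                 n_rods = n_rods, rod_radius = rod_radius,
                 hole_radius = hole_radius, seed = seed)
  )
  list(volume = density_volume(vals, voxel_size), truth = truth)
}

#' Tumor perturbation parameters
#'
#' @param lysis_fraction Fraction in `[0, 1]` of trabecular structural
#'   elements (whole plates, not individual voxels) removed; element-wise
#'   removal degrades connectivity the way tumor permeation does.
#' @param woven_fraction Target bone volume fraction of randomly oriented
#'   spicules deposited in the periosteal band outside the cortex, in `[0, 1]`.
#' @param breach If `TRUE`, a cortical window (one quadrant, middle third of
#'   the long axis) is removed, emulating cortical transgression.
#' @param seed Integer RNG seed (same seed, same volume).
#' @param band_width Radial extent of the periosteal band in voxels.
#' @return An object of class `tumor_params`.
#' @export
tumor_params <- function(lysis_fraction = 0, woven_fraction = 0, breach = FALSE,
                         seed = 1, band_width = 14) {
  stopifnot(lysis_fraction >= 0, lysis_fraction <= 1,
            woven_fraction >= 0, woven_fraction <= 1, band_width >= 2)
  structure(list(lysis_fraction = lysis_fraction, woven_fraction = woven_fraction,
                 breach = isTRUE(breach), seed = as.integer(seed),
                 band_width = band_width),
            class = "tumor_params")
}

# voxelize one cylindrical spicule into linear indices (clipped to shape)
spicule_voxels <- function(center, direction, radius, length, shape) {
  half <- length / 2
  lo <- pmax(1L, floor(center - half - radius))
  hi <- pmin(shape, ceiling(center + half + radius))
  if (any(lo > hi)) return(integer(0))
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  d <- cbind(g$x - center[1], g$y - center[2], g$z - center[3])
  t_par <- d %*% direction
  perp2 <- rowSums(d^2) - t_par^2
  keep <- abs(t_par) <= half & perp2 <= radius^2
  g <- g[keep, , drop = FALSE]
  g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2]
}

#' Apply tumor-like osteolysis and periosteal woven bone to a phantom
#'
#' Emulates what an aggressive bone tumor does to the composite phantom:
#' removes whole trabecular structural elements (osteolysis), optionally
#' breaches the cortex, and deposits short cylindrical spicules of random
#' orientation in the periosteal band (disorganized woven-bone reaction)
#' until the requested fraction of that band is bone. Deterministic under
#' the seed in `params`.
#'
#' @param vol A [density_volume] produced by [make_metaphysis_like()].
#' @param truth The matching [phantom_truth] (must carry compartment labels).
#' @param params A [tumor_params] object.
#' @return A [density_volume]; with all-zero parameters the input is
#'   returned unchanged.
#' @export
apply_tumor <- function(vol, truth, params = tumor_params()) {
  stopifnot(inherits(vol, "density_volume"), inherits(params, "tumor_params"))
  ex <- truth$extra
  if (is.null(ex$cortical) || is.null(ex$trabecular) || is.null(ex$elements))
    stop("phantom truth does not carry compartment labels (cortical/trabecular/elements)",
         call. = FALSE)
  if (params$lysis_fraction == 0 && params$woven_fraction == 0 && !params$breach)
    return(vol)
  shape <- dim(vol$values)
  vals <- vol$values
  bone_density <- max(vals)
  bg <- min(vals)
  with_seed(params$seed, {
    if (params$lysis_fraction > 0) {
      ids <- setdiff(sort(unique(as.vector(ex$elements))), 0L)
      n_rm <- round(params$lysis_fraction * length(ids))
      if (params$lysis_fraction >= 1) n_rm <- length(ids)
      if (n_rm > 0) {
        rm_ids <- sample(ids, n_rm)
        vals[ex$elements %in% rm_ids] <- bg
      }
      if (params$lysis_fraction >= 1) vals[ex$trabecular] <- bg
    }
    if (params$breach) {
      cross <- shape[-1]
      c1 <- (cross[1] + 1) / 2
      c2 <- (cross[2] + 1) / 2
      quad <- outer(seq_len(cross[1]) - c1, seq_len(cross[2]) - c2,
                    function(a, b) a > 0 & b > 0)
      zmid <- seq(floor(shape[1] / 3) + 1, ceiling(2 * shape[1] / 3))
      win <- array(FALSE, shape)
      win[zmid, , ] <- rep(quad, each = length(zmid))
      vals[win & ex$cortical] <- bg
    }
    if (params$woven_fraction > 0) {
      cross <- shape[-1]
      c1 <- (cross[1] + 1) / 2
      c2 <- (cross[2] + 1) / 2
      r2 <- outer(seq_len(cross[1]) - c1, seq_len(cross[2]) - c2,
                  function(a, b) a^2 + b^2)
      o2 <- ex$outer_r2 %||% rep(ex$outer_radius^2, shape[1])
      r2v <- as.vector(r2)
      bw <- params$band_width
      band <- array(outer(seq_len(shape[1]), r2v,
                          function(i, r) r > o2[i] & r <= (sqrt(o2[i]) + bw)^2),
                    shape)
      band_idx <- which(band)
      n_band <- length(band_idx)
      if (n_band == 0)
        stop("periosteal band lies outside the volume; enlarge the cross-section",
             call. = FALSE)
      target_n <- params$woven_fraction * n_band
      guard <- 0L
      while (sum(vals[band_idx] >= bone_density) < target_n && guard < 20000L) {
        guard <- guard + 1L
        ctr_lin <- band_idx[sample.int(n_band, 1)]
        ctr <- c((ctr_lin - 1) %% shape[1] + 1,
                 ((ctr_lin - 1) %/% shape[1]) %% shape[2] + 1,
                 (ctr_lin - 1) %/% (shape[1] * shape[2]) + 1)
        # orientation uniform on the sphere
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        rad <- stats::runif(1, 2, 4)
        len <- stats::runif(1, 10, 30)
        lin <- spicule_voxels(ctr, u, rad, len, shape)
        if (length(lin)) {
          # keep spicule bone strictly outside the (per-slice) cortex
          si <- (lin - 1) %% shape[1] + 1
          j <- ((lin - 1) %/% shape[1]) %% shape[2] + 1
          k <- (lin - 1) %/% (shape[1] * shape[2]) + 1
          rr <- (j - c1)^2 + (k - c2)^2
          lin <- lin[rr > o2[si]]
          vals[lin] <- bone_density
        }
      }
    }
  })
  out <- density_volume(vals, vol$voxel_size)
  out$tumor <- unclass(params)
  out
}

#' Add zero-mean Gaussian density noise
#'
#' @param vol A [density_volume].
#' @param sigma_density Noise standard deviation in mgHA/cm^3 (>= 0);
#'   `0` returns the input bit-identically.
#' @param seed Integer RNG seed; same seed gives the identical noise field.
#' @return A [density_volume].
#' @export
add_noise <- function(vol, sigma_density, seed = 1) {
  stopifnot(inherits(vol, "density_volume"), sigma_density >= 0)
  if (sigma_density == 0) return(vol)
  noise <- with_seed(seed, stats::rnorm(length(vol$values), 0, sigma_density))
  density_volume(vol$values + array(noise, dim(vol$values)), vol$voxel_size)
}
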