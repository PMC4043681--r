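# exact box mesh (12 triangles, outward normals) for closed-form checks
box_mesh <- function(a, b, c_) {
  v <- rbind(c(0, 0, 0), c(a, 0, 0), c(0, b, 0), c(a, b, 0),
             c(0, 0, c_), c(a, 0, c_), c(0, b, c_), c(a, b, c_))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = c, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = b, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6)    # x = a, normal +x
  )
  e1 <- v[tri[, 2], ] - v[tri[, 1], ]
  e2 <- v[tri[, 3], ] - v[tri[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  structure(list(vertices = v, triangles = tri, normal = n / len,
                 area = len / 2, on_cut = rep(FALSE, 12), voxel_size = 1,
                 grid_dim = c(a, b, c_)),
            class = "triangle_mesh")
}

test_that("surface-projection MIL is exact on an analytic box mesh", {
  m <- box_mesh(3, 5, 7)
  bv <- 3 * 5 * 7
  expect_equal(mil_surface_projection(m, bv, c(1, 0, 0)), 3, tolerance = 1e-12)
  expect_equal(mil_surface_projection(m, bv, c(0, 1, 0)), 5, tolerance = 1e-12)
  expect_equal(mil_surface_projection(m, bv, c(0, 0, 1)), 7, tolerance = 1e-12)
})

test_that("surface-projection MIL on a voxel sphere matches 4R/3 in all directions", {
  s <- binary_volume(sphere_mask(10), 1)
  mesh <- triangulate_surface(s)
  bv <- sum(s$mask)
  mils <- mil_surface_projection(mesh, bv, sample_directions(32))
  expect_lt(max(abs(mils - 40 / 3)) / (40 / 3), 0.05)
})

test_that("zero projected area is capped with a warning", {
  # plates normal to axis 1 viewed along an in-plane direction
  ph <- make_plate_phantom(c(24, 24, 24), plate_thickness = 2,
                           plate_spacing = 4, normal_axis = 1)
  m <- segment_bone(ph$volume)
  mesh <- triangulate_surface(m)
  bv <- sum(m$mask) * 12^3
  expect_warning(mil <- mil_surface_projection(mesh, bv, c(0, 1, 0)),
                 "capped")
  expect_equal(mil, sqrt(3 * 24^2) * 12, tolerance = 1e-9)
})

test_that("tensor fit recovers constants and known tensors", {
  d <- sample_directions(32)
  iso <- fit_fabric_tensor(d, rep(250, 32))
  expect_equal(iso$M, diag(3) / 250^2, tolerance = 1e-12)
  expect_equal(iso$da, 1, tolerance = 1e-10)
  # parameter recovery from a synthetic MIL field
  M0 <- matrix(c(4e-4, 5e-5, 1e-5,
                 5e-5, 2.5e-4, 2e-5,
                 1e-5, 2e-5, 1e-4), 3, 3)
  d64 <- sample_directions(64)
  mils <- rowSums((d64 %*% M0) * d64)^(-1/2)
  ft <- fit_fabric_tensor(d64, mils)
  expect_lt(max(abs(ft$M - M0)), 1e-8)
  expect_equal(ft$da, sqrt(max(eigen(M0)$values) / min(eigen(M0)$values)),
               tolerance = 1e-8)
  expect_true(all(diff(ft$principal_mil) <= 0))
  expect_true(all(ft$eigenvalues > 0))
})

test_that("tensor fit is equivariant under axis permutation", {
  M0 <- diag(c(4e-4, 2.5e-4, 1e-4))
  d <- sample_directions(64)
  mils <- rowSums((d %*% M0) * d)^(-1/2)
  ft <- fit_fabric_tensor(d, mils)
  dp <- unclass(d)[, c(3, 1, 2)]
  ftp <- fit_fabric_tensor(dp, mils)
  expect_equal(ftp$da, ft$da, tolerance = 1e-10)
  expect_equal(sort(diag(ftp$M)), sort(diag(ft$M)), tolerance = 1e-10)
})

test_that("degenerate MIL fields are rejected as non-positive-definite", {
  d <- sample_directions(32)
  # MIL ~ |n_x|^-1: the fitted form has (near-)zero eigenvalues
  mils <- pmin(abs(unclass(d)[, 1]), 1)^(-1)
  expect_error(fit_fabric_tensor(d, mils), "not positive definite")
  expect_error(fit_fabric_tensor(d, rep(-1, 32)), "positive")
  expect_error(fit_fabric_tensor(sample_directions(16), rep(1, 9)),
               "match")
})

test_that("DA separates organized from isotropic structures at small scale", {
  iso <- make_isotropic_boolean(c(48, 48, 48), sphere_radius = 5,
                                target_bvtv = 0.3, seed = 2)
  ft_iso <- degree_of_anisotropy(segment_bone(iso$volume), n_directions = 64)
  expect_gte(ft_iso$da, 1)
  expect_lte(ft_iso$da, 1.15)
  pl <- make_plate_phantom(c(48, 48, 48), plate_thickness = 2,
                           plate_spacing = 4)
  ft_pl <- suppressWarnings(
    degree_of_anisotropy(segment_bone(pl$volume), n_directions = 64))
  expect_gt(ft_pl$da, ft_iso$da)
  # longest principal MIL lies in the plate plane
  expect_lt(abs(ft_pl$directions[1, 1]), 0.2)
  cyl <- make_cortical_cylinder(c(48, 48, 48), outer_radius = 16,
                                inner_radius = 11)
  ft_cy <- suppressWarnings(
    degree_of_anisotropy(segment_bone(cyl$volume), n_directions = 64))
  expect_gt(ft_cy$da, ft_iso$da)
  ang <- acos(min(1, abs(sum(ft_cy$directions[, 1] * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 10)
})

test_that("DA is >= 1 and exactly invariant under axis permutations", {
  for (s in 1:3) {
    a <- random_blob_mask(s)
    ft <- suppressWarnings(
      degree_of_anisotropy(binary_volume(a, 12), n_directions = 64))
    expect_gte(ft$da, 1)
    # mesh and symmetrized direction multiset are both permutation-invariant
    ftp <- suppressWarnings(
      degree_of_anisotropy(binary_volume(aperm(a, c(2, 3, 1)), 12),
                           n_directions = 64))
    expect_equal(ftp$da, ft$da, tolerance = 1e-9)
    # reflections change the tet decomposition; agreement is approximate
    ftr <- suppressWarnings(
      degree_of_anisotropy(binary_volume(a[dim(a)[1]:1, , ], 12),
                           n_directions = 64))
    expect_equal(ftr$da, ft$da, tolerance = 0.10)
  }
})

test_that("fabric results tidy, glance and plot", {
  s <- binary_volume(sphere_mask(8), 12)
  ft <- degree_of_anisotropy(s, n_directions = 32)
  td <- tidy(ft)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$component, c("L1", "L2", "L3"))
  expect_equal(td$mil, ft$principal_mil)
  gl <- glance(ft)
  expect_identical(names(gl),
                   c("da", "mil_longest", "mil_shortest", "n_directions",
                     "r_squared"))
  expect_identical(gl$n_directions, 32L)
  p <- autoplot(ft)
  expect_s3_class(p, "ggplot")
})
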