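test_that("plate phantom has the constructed volume fraction and rejects bad shapes", {
  p <- make_plate_phantom(c(16, 16, 16), plate_thickness = 2, plate_spacing = 2)
  expect_equal(p$truth$true_bvtv, 0.5)
  p2 <- make_plate_phantom(c(16, 16, 16), plate_thickness = 1, plate_spacing = 3)
  expect_equal(p2$truth$true_bvtv, 0.25)
  # brute-force voxel count agrees exactly on a period-aligned shape
  p3 <- make_plate_phantom(c(12, 7, 9), plate_thickness = 2, plate_spacing = 4,
                           normal_axis = 1)
  expect_identical(sum(p3$volume$values == 700),
                   as.integer(p3$truth$true_bvtv * prod(c(12, 7, 9))))
  expect_equal(p3$truth$true_bvtv, 2 / 6)
  expect_error(make_plate_phantom(c(3, 16, 16), plate_thickness = 2,
                                  plate_spacing = 2), "smaller than one")
  expect_error(make_plate_phantom(c(8, 8, 8), bone_density = 0,
                                  bg_density = 0))
})

test_that("Boolean phantom hits its target fraction deterministically", {
  b <- make_isotropic_boolean(c(32, 32, 32), sphere_radius = 4,
                              target_bvtv = 0.3, seed = 7)
  expect_gte(b$truth$true_bvtv, 0.28)
  expect_lte(b$truth$true_bvtv, 0.32)
  expect_identical(mean(b$volume$values == 700), b$truth$true_bvtv)
  expect_null(b$truth$principal_axis)
  b2 <- make_isotropic_boolean(c(32, 32, 32), sphere_radius = 4,
                               target_bvtv = 0.3, seed = 7)
  expect_identical(b$volume$values, b2$volume$values)
  expect_error(make_isotropic_boolean(c(32, 32, 32), target_bvtv = 0),
               "between 0 and 1")
  expect_error(make_isotropic_boolean(c(32, 32, 32), sphere_radius = 1,
                                      target_bvtv = 0.3))
})

test_that("cortical cylinder matches analytic fraction and topology", {
  cyl <- make_cortical_cylinder(c(12, 30, 30), outer_radius = 12,
                                inner_radius = 8)
  expect_lt(abs(cyl$truth$true_bvtv - cyl$truth$extra$analytic_bvtv), 0.03)
  expect_equal(cyl$truth$principal_axis, c(1, 0, 0))
  solid <- make_cortical_cylinder(c(8, 20, 20), outer_radius = 7)
  expect_identical(euler_characteristic(solid$volume$values == 700), 1L)
  # the hollow tube retracts to an annulus: one independent loop, chi = 0
  tube <- cyl$volume$values == 700
  expect_identical(euler_characteristic(tube), 0L)
  # capping both ends with solid discs encloses a cavity instead: chi = 2
  disc <- array(FALSE, dim(tube))
  r2 <- outer(seq_len(30) - 15.5, seq_len(30) - 15.5, function(a, b) a^2 + b^2)
  disc[1, , ] <- r2 <= 144
  disc[12, , ] <- r2 <= 144
  expect_identical(euler_characteristic(tube | disc), 2L)
  # axis permutation of arguments gives the axis-permuted volume
  c1 <- make_cortical_cylinder(c(6, 20, 20), outer_radius = 8,
                               inner_radius = 5, axis = 1)
  c2 <- make_cortical_cylinder(c(20, 6, 20), outer_radius = 8,
                               inner_radius = 5, axis = 2)
  expect_identical(aperm(c1$volume$values, c(2, 1, 3)), c2$volume$values)
  expect_error(make_cortical_cylinder(c(8, 20, 20), outer_radius = 5,
                                      inner_radius = 6), "inner_radius")
  expect_error(make_cortical_cylinder(c(8, 10, 10), outer_radius = 9),
               "fit")
})

test_that("composite phantom records disjoint covering compartment truth", {
  ph <- do.call(make_metaphysis_like, small_meta_args(seed = 4))
  ex <- ph$truth$extra
  bone <- ph$volume$values == 700
  expect_false(any(ex$cortical & ex$trabecular))
  expect_identical(ex$cortical | ex$trabecular, bone)
  expect_identical(ex$trabecular, ex$elements > 0L)
  # composite BV/TV is the sum of the disjoint compartment fractions
  expect_equal(ph$truth$true_bvtv, mean(ex$cortical) + mean(ex$trabecular))
  expect_error(do.call(make_metaphysis_like,
                       c(list(shape = c(20, 40, 40), outer_radius = 12,
                              inner_radius = 8))),
               "parameter conflict")
})

test_that("tumor perturbation follows its contracts", {
  ph <- do.call(make_metaphysis_like, small_meta_args(seed = 5))
  # all-zero parameters: identity
  out0 <- apply_tumor(ph$volume, ph$truth, tumor_params())
  expect_identical(out0$values, ph$volume$values)
  # complete lysis removes every interior trabecular voxel
  out1 <- apply_tumor(ph$volume, ph$truth, tumor_params(lysis_fraction = 1))
  expect_identical(sum(out1$values[ph$truth$extra$trabecular] == 700), 0L)
  # interior bone is non-increasing in lysis_fraction
  lys_count <- vapply(c(0, 0.4, 0.8, 1), function(l) {
    v <- apply_tumor(ph$volume, ph$truth, tumor_params(lysis_fraction = l,
                                                       seed = 9))
    sum(v$values[ph$truth$extra$trabecular] == 700)
  }, numeric(1))
  expect_true(all(diff(lys_count) <= 0))
  # woven bone strictly increases total bone; non-decreasing in fraction
  wov_count <- vapply(c(0, 0.2, 0.4), function(w) {
    v <- apply_tumor(ph$volume, ph$truth,
                     tumor_params(woven_fraction = w, seed = 9, band_width = 7))
    sum(v$values == 700)
  }, numeric(1))
  expect_true(all(diff(wov_count) > 0))
  # deterministic under seed
  a <- apply_tumor(ph$volume, ph$truth,
                   tumor_params(lysis_fraction = 0.5, woven_fraction = 0.2,
                                breach = TRUE, seed = 3, band_width = 7))
  b <- apply_tumor(ph$volume, ph$truth,
                   tumor_params(lysis_fraction = 0.5, woven_fraction = 0.2,
                                breach = TRUE, seed = 3, band_width = 7))
  expect_identical(a$values, b$values)
  # missing compartment labels rejected
  bare <- phantom_truth(0.5)
  expect_error(apply_tumor(ph$volume, bare, tumor_params(lysis_fraction = 1)),
               "compartment labels")
})

test_that("density noise is zero-mean, seeded, and optional", {
  ph <- make_plate_phantom(c(48, 48, 48))
  expect_identical(add_noise(ph$volume, 0), ph$volume)
  n1 <- add_noise(ph$volume, 30, seed = 2)
  n2 <- add_noise(ph$volume, 30, seed = 2)
  expect_identical(n1$values, n2$values)
  resid <- n1$values - ph$volume$values
  n <- length(resid)
  expect_gte(n, 1e5)
  expect_lt(abs(mean(resid)), 3 * 30 / sqrt(n))
  expect_error(add_noise(ph$volume, -1))
})
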