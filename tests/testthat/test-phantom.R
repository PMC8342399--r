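test_that("deformation fields evaluate to their closed forms", {
  none <- deformation_model("none")
  expect_equal(evaluate_deformation(cbind(123.4, -5, 67), none),
               cbind(dx = 0, dy = 0, dz = 0))

  uc <- deformation_model("uniform_contraction", center = c(0, 0, 0),
                          contraction_fraction = 0.01)
  expect_equal(as.numeric(evaluate_deformation(c(100, 0, 0), uc)),
               c(-1, 0, 0))

  drift <- deformation_model("axial_drift", axial_shift = -7.5)
  expect_equal(as.numeric(evaluate_deformation(c(5, 5, 5), drift)),
               c(0, 0, -7.5))

  # composite_sum equals the sum of separately evaluated parts
  sw <- deformation_model("swirl", center = c(100, 200, 0), swirl_angle = 3)
  comp <- deformation_model("composite_sum", parts = list(uc, drift, sw))
  pts <- matrix(runif(30, -500, 500), ncol = 3)
  expect_equal(evaluate_deformation(pts, comp),
               evaluate_deformation(pts, uc) + evaluate_deformation(pts, drift) +
                 evaluate_deformation(pts, sw),
               tolerance = 1e-12)

  expect_error(deformation_model("shear"), "unknown deformation kind")
})

test_that("swirl rotates about the vertical axis by its stated rate", {
  sw <- deformation_model("swirl", center = c(0, 0, 0), swirl_angle = 10)
  p <- c(1000, 0, 50)  # 1 mm radius -> 10 degrees
  d <- as.numeric(evaluate_deformation(p, sw))
  th <- 10 * pi / 180
  expect_equal(d, c(1000 * (cos(th) - 1), 1000 * sin(th), 0), tolerance = 1e-9)
})

test_that("sphere rasterization reproduces the analytic volume", {
  vol <- new_volume(array(0, c(24, 24, 24)), voxel_size = 1)
  out <- rasterize_sphere(vol, center = c(12, 12, 12), radius = 5,
                          attenuation = 1, supersampling = 3)
  # coverage fractions sum to the sphere volume (unit voxels, attenuation 1)
  expect_equal(sum(out$data), 4 / 3 * pi * 125, tolerance = 0.02 * 4 / 3 * pi * 125)
})

test_that("a sub-voxel sphere modifies only its own voxel, partially", {
  vol <- new_volume(array(0, c(8, 8, 8)), voxel_size = 1)
  out <- rasterize_sphere(vol, center = c(3.5, 3.5, 3.5), radius = 0.1,
                          attenuation = 1, supersampling = 5)
  touched <- which(out$data != 0)
  expect_length(touched, 1L)
  expect_lt(out$data[touched], 1)
  expect_gt(out$data[touched], 0)
})

test_that("disjoint spheres render independently of order", {
  vol <- new_volume(array(500, c(32, 32, 32)), voxel_size = 1)
  a <- rasterize_sphere(rasterize_sphere(vol, c(8, 8, 8), 3, 100),
                        c(22, 22, 22), 4, 100)
  b <- rasterize_sphere(rasterize_sphere(vol, c(22, 22, 22), 4, 100),
                        c(8, 8, 8), 3, 100)
  expect_identical(a$data, b$data)
})

test_that("a sphere outside the grid warns and leaves the volume unchanged", {
  vol <- new_volume(array(1, c(8, 8, 8)), voxel_size = 1)
  expect_warning(out <- rasterize_sphere(vol, c(100, 100, 100), 2, 0),
                 "outside the grid")
  expect_identical(out$data, vol$data)
})

test_that("rendered bead radiolucency scales with sphere volume", {
  # integrated (composite - value) tracks the analytic sphere volume
  for (r in c(1.25, 1.6, 2.2) * 16) {
    vol <- bead_block(c(256, 256, 256), radius_um = r)
    integrated <- sum(1000 - vol$data) * prod(vol$voxel_size) / 600
    expect_equal(integrated, 4 / 3 * pi * r^3,
                 tolerance = 0.05 * 4 / 3 * pi * r^3)
  }
})

test_that("phantom generation is deterministic and self-consistent", {
  spec <- tiny_spec()
  a <- generate_phantom(spec, deformation_model("none"), rigid_transform(), seed = 5)
  b <- generate_phantom(spec, deformation_model("none"), rigid_transform(), seed = 5)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  expect_identical(a$truth, b$truth)
  # identity pose, zero deformation, no noise: the two scans are the same scan
  expect_identical(a$pre$data, a$post$data)
  # different seed, different phantom
  c2 <- generate_phantom(spec, deformation_model("none"), rigid_transform(), seed = 6)
  expect_false(identical(a$pre$data, c2$pre$data))
})

test_that("phantom truth satisfies its construction invariants", {
  spec <- tiny_spec(bead_count = 50)
  defo <- contraction_of(spec, 0.01)
  ph <- generate_phantom(spec, defo, rigid_transform(), seed = 9)
  tru <- ph$truth
  expect_equal(nrow(tru), 50L)
  expect_false(anyDuplicated(tru$id) > 0)
  # displacement column equals the field evaluated at the pre centre
  u <- evaluate_deformation(as.matrix(tru[, c("x_pre", "y_pre", "z_pre")]), defo)
  expect_lt(max(abs(u - as.matrix(tru[, c("dx", "dy", "dz")]))), 1e-9)
  expect_lt(max(abs(tru$x_post - tru$x_pre - tru$dx)), 1e-9)
  # no two centres closer than the sum of radii
  dmat <- as.matrix(dist(tru[, c("x_pre", "y_pre", "z_pre")]))
  rsum <- outer(tru$radius_um, tru$radius_um, "+")
  diag(dmat) <- Inf
  expect_true(all(dmat >= rsum))
})

test_that("mean true displacement matches the analytic contraction", {
  spec <- tiny_spec(bead_count = 80)
  s <- 0.01
  defo <- contraction_of(spec, s)
  ph <- generate_phantom(spec, defo, rigid_transform(), seed = 3)
  tru <- ph$truth
  dists <- sqrt((tru$x_pre - defo$center[1])^2 + (tru$y_pre - defo$center[2])^2 +
                  (tru$z_pre - defo$center[3])^2)
  mags <- sqrt(tru$dx^2 + tru$dy^2 + tru$dz^2)
  expect_equal(mean(mags), s * mean(dists), tolerance = 1e-6)
})

test_that("an unplaceable bead population raises a budget error", {
  spec <- tiny_spec(bead_count = 5000)
  expect_error(generate_phantom(spec, deformation_model("none"),
                                rigid_transform(), seed = 1),
               "placed [0-9]+ of 5000")
})

test_that("phantom_spec validates its geometry and attenuations", {
  expect_error(phantom_spec(bead_diameter_range = c(0, 40)), "bead_diameter_range")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(grid_shape = c(40, 40, 40)), "grid too small")
  expect_error(
    phantom_spec(layers = list(
      list(label = "a", top_z = 0, bottom_z = 800, attenuation = 1000),
      list(label = "b", top_z = 700, bottom_z = 1280, attenuation = 1400))),
    "overlap")
  # two stacked layers are accepted
  spec <- phantom_spec(layers = list(
    list(label = "flow", top_z = 780, bottom_z = 1280, attenuation = 1000),
    list(label = "bulk", top_z = 0, bottom_z = 780, attenuation = 1400)))
  expect_s3_class(spec, "phantom_spec")
})

test_that("written phantoms round-trip volumes and truth", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(bead_count = 10, noise_sd = 50)
  ph <- generate_phantom(spec, contraction_of(spec, 0.01), rigid_transform(),
                         seed = 2)
  write_phantom(ph, dir)
  pre <- read_volume(file.path(dir, "pre.mha"))
  expect_equal(pre$voxel_size, c(16, 16, 16))
  # float32 storage: relative error ~ 1e-7 of values ~ 1000
  expect_equal(pre$data, ph$pre$data, tolerance = 1e-4)
  tru <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(tru$dx, ph$truth$dx, tolerance = 1e-6)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 2L)
})
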