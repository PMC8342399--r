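test_that("cavity masks match the analytic cylinder volume", {
  vol <- new_volume(array(0, c(80, 80, 80)), voxel_size = 16)
  # cylinder of diameter 50 voxels, depth 40 voxels, fully inside
  mask <- make_cavity_mask(vol, cavity_center = c(640, 640, 320),
                           diameter = 800, depth = 640, margin = 0)
  analytic <- pi * 25^2 * 40
  expect_equal(sum(mask), analytic, tolerance = 0.02 * analytic)
})

test_that("a cylinder covering the whole grid gives an all-true mask", {
  vol <- new_volume(array(0, c(16, 16, 16)), voxel_size = 16)
  mask <- make_cavity_mask(vol, c(128, 128, 0), diameter = 3000, depth = 3000,
                           margin = 0)
  expect_true(all(mask))
})

test_that("margins that erode the cylinder away raise an error", {
  vol <- new_volume(array(0, c(32, 32, 32)), voxel_size = 16)
  expect_error(make_cavity_mask(vol, c(256, 256, 100), diameter = 320,
                                depth = 320, margin = 10), "empty cavity mask")
  expect_error(make_cavity_mask(vol, c(5000, 5000, 5000), diameter = 100,
                                depth = 100, margin = 0), "intersect")
})

test_that("noise-free phantoms are segmented with exact count", {
  spec <- tiny_spec(bead_count = 50)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 31)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss <- segment_spheres(ph$pre, mask)
  expect_equal(nrow(ss), 50L)
  expect_identical(ss$id, seq_len(50L))
  # all centroids within one voxel of a distinct true bead
  expect_equal(truth_hits(data.frame(x_pre = ss$x, y_pre = ss$y, z_pre = ss$z),
                          ph$truth), 50L)
})

test_that("uniform volumes yield an empty sphere set, not an error", {
  vol <- new_volume(array(1000, c(32, 32, 32)), voxel_size = 16)
  mask <- array(TRUE, c(32, 32, 32))
  ss <- segment_spheres(vol, mask)
  expect_s3_class(ss, "sphere_set")
  expect_equal(nrow(ss), 0L)
})

test_that("detection at contrast-to-noise 5 keeps recall and precision high", {
  spec <- tiny_spec(bead_count = 40, noise_sd = 120)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 32)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss <- segment_spheres(ph$pre, mask)
  hits <- truth_hits(data.frame(x_pre = ss$x, y_pre = ss$y, z_pre = ss$z),
                     ph$truth)
  expect_gte(hits / nrow(ph$truth), 0.95)  # recall
  expect_gte(hits / nrow(ss), 0.95)        # precision
})

test_that("estimate_centroid follows the voxel-centre convention", {
  expect_equal(estimate_centroid(cbind(10, 10, 10), weights = 5,
                                 voxel_size = 16),
               c(168, 168, 168))
  # symmetric 3x3x3 component with symmetric weights: exact centre
  vox <- as.matrix(expand.grid(9:11, 9:11, 9:11))
  w <- exp(-rowSums((vox - 10)^2))
  expect_equal(estimate_centroid(vox, w, 16), c(168, 168, 168))
  expect_error(estimate_centroid(vox[0, ], numeric(0), 16), "empty")
  expect_warning(c0 <- estimate_centroid(cbind(c(1, 3), c(2, 2), c(2, 2)),
                                         c(0, 0), 16), "all-zero")
  expect_equal(c0, c((2 + 0.5) * 16, 40, 40))
})

test_that("anti-aliased beads are located to sub-voxel accuracy", {
  set.seed(33)
  errs <- replicate(100, {
    center <- c(256, 256, 256) + runif(3, -8, 8)
    vol <- bead_block(center, radius_um = runif(1, 20, 35))
    mask <- array(TRUE, dim(vol$data))
    ss <- segment_spheres(vol, mask)
    expect_equal(nrow(ss), 1L)
    sqrt(sum((c(ss$x, ss$y, ss$z) - center)^2))
  })
  expect_lt(sqrt(mean(errs^2)), 0.3 * 16)
})

test_that("detection is equivariant under integer-voxel shifts", {
  spec <- tiny_spec(bead_count = 20)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 34)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss0 <- segment_spheres(ph$pre, mask)
  shift <- c(2L, -1L, 3L)
  shifted <- ph$pre
  d <- dim(shifted$data)
  src <- list(seq_len(d[1]) - shift[1], seq_len(d[2]) - shift[2],
              seq_len(d[3]) - shift[3])
  ok <- lapply(src, function(s) s >= 1 & s <= d[1])
  arr <- array(1000, d)
  arr[which(ok[[1]]), which(ok[[2]]), which(ok[[3]])] <-
    ph$pre$data[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  shifted$data <- arr
  mask_s <- array(FALSE, d)
  mask_s[which(ok[[1]]), which(ok[[2]]), which(ok[[3]])] <-
    mask[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  ss1 <- segment_spheres(shifted, mask_s)
  expect_equal(nrow(ss1), nrow(ss0))
  ord0 <- order(ss0$x, ss0$y, ss0$z)
  ord1 <- order(ss1$x - shift[1] * 16, ss1$y, ss1$z)
  expect_equal(ss1$x[ord1] - shift[1] * 16, ss0$x[ord0], tolerance = 1e-9)
  expect_equal(ss1$y[ord1] - shift[2] * 16, ss0$y[ord0], tolerance = 1e-9)
  expect_equal(ss1$z[ord1] - shift[3] * 16, ss0$z[ord0], tolerance = 1e-9)
})

test_that("sphere ids are assigned by lexicographic centroid order", {
  spec <- tiny_spec(bead_count = 15)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 35)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss <- segment_spheres(ph$pre, mask)
  expect_identical(order(ss$x, ss$y, ss$z), seq_len(nrow(ss)))
  # re-running reproduces the identical set
  expect_identical(segment_spheres(ph$pre, mask), ss)
})
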