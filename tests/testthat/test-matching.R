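test_that("identical scans block-match at zero displacement with NCC 1", {
  spec <- tiny_spec(bead_count = 15)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 41)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss <- segment_spheres(ph$pre, mask)
  for (i in seq_len(min(5, nrow(ss)))) {
    bm <- block_match(ph$pre, ph$pre, as.numeric(ss[i, c("x", "y", "z")]))
    expect_identical(bm$disp, c(0L, 0L, 0L))
    expect_equal(bm$ncc, 1, tolerance = 1e-12)
    expect_identical(bm$status, "ok")
  }
})

test_that("a pure integer-voxel shift is recovered for every sphere", {
  spec <- tiny_spec(bead_count = 20)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 42)
  d <- dim(ph$pre$data)
  shift <- c(2L, 0L, -1L)
  arr <- array(1000, d)
  arr[3:d[1], , 1:(d[3] - 1)] <- ph$pre$data[1:(d[1] - 2), , 2:d[3]]
  post <- ph$pre
  post$data <- arr
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss <- segment_spheres(ph$pre, mask)
  for (i in seq_len(min(8, nrow(ss)))) {
    bm <- block_match(ph$pre, post, as.numeric(ss[i, c("x", "y", "z")]))
    expect_identical(bm$disp, shift)
    # the NCC peak is interpolated; finite-block asymmetry leaves a small
    # sub-voxel residual even for exact lattice shifts
    expect_lt(max(abs(bm$subvoxel - shift)), 0.15)
  }
})

test_that("zero-variance blocks give a no-score sentinel", {
  flat <- new_volume(array(7, c(32, 32, 32)), voxel_size = 16)
  bm <- block_match(flat, flat, c(256, 256, 256))
  expect_identical(bm$status, "no_score")
  expect_true(is.na(bm$ncc))
})

test_that("blocks overhanging the volume edge shrink with a warning", {
  spec <- tiny_spec(bead_count = 10, noise_sd = 60)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 43)
  expect_warning(block_match(ph$pre, ph$pre, c(24, 24, 24)), "shrunk")
})

test_that("identical sphere sets pair one-to-one with zero displacement", {
  spec <- tiny_spec(bead_count = 25)
  ph <- generate_phantom(spec, deformation_model("none"), rigid_transform(),
                         seed = 44)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss <- segment_spheres(ph$pre, mask)
  ms <- match_spheres(ph$pre, ph$pre, ss, ss)
  expect_equal(nrow(ms$matches), nrow(ss))
  expect_identical(ms$matches$pre_id, ms$matches$post_id)
  expect_lt(max(abs(as.matrix(ms$matches[, c("dx", "dy", "dz")]))), 1e-9)
  expect_length(ms$unmatched_pre, 0L)
})

test_that("displacements beyond the search radius land in unmatched_pre", {
  spec <- tiny_spec(bead_count = 12)
  # axial drift of 6 voxels with a search radius of 3
  defo <- deformation_model("axial_drift", axial_shift = 96)
  ph <- generate_phantom(spec, defo, rigid_transform(), seed = 45)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss_pre <- segment_spheres(ph$pre, mask)
  ss_post <- segment_spheres(ph$post, mask)
  ms <- match_spheres(ph$pre, ph$post, ss_pre, ss_post,
                      params = match_params(search_radius = 3L))
  expect_gt(length(ms$unmatched_pre), 0.8 * nrow(ss_pre))
})

test_that("pairing conflicts resolve by smallest residual, one-to-one", {
  pre <- data.frame(id = 1:2, x = c(0, 40), y = c(0, 0), z = c(0, 0))
  post <- data.frame(id = 1L, x = 10, y = 0, z = 0)
  coarse <- data.frame(pre_id = 1:2, cdx = 0L, cdy = 0L, cdz = 0L, ncc = 0.9)
  ms <- pair_spheres(pre, post, coarse, params = match_params(gate_distance = 50,
                                                             outlier_mad = Inf))
  expect_equal(nrow(ms$matches), 1L)
  expect_equal(ms$matches$pre_id, 1L)  # residual 10 beats residual 30
  expect_identical(ms$unmatched_pre, 2L)
})

test_that("matching is one-to-one on random perturbed sets", {
  set.seed(46)
  for (rep in 1:10) {
    n <- 30
    pre <- data.frame(id = seq_len(n),
                      x = runif(n, 0, 500), y = runif(n, 0, 500),
                      z = runif(n, 0, 500))
    keep <- sample(n, 24)
    post <- data.frame(id = seq_along(keep),
                       x = pre$x[keep] + rnorm(24, 0, 5),
                       y = pre$y[keep] + rnorm(24, 0, 5),
                       z = pre$z[keep] + rnorm(24, 0, 5))
    coarse <- data.frame(pre_id = pre$id, cdx = 0L, cdy = 0L, cdz = 0L,
                         ncc = 0.9)
    ms <- pair_spheres(pre, post, coarse,
                       params = match_params(outlier_mad = Inf))
    expect_lte(max(table(ms$matches$pre_id)), 1L)
    expect_lte(max(table(ms$matches$post_id)), 1L)
    expect_setequal(c(ms$matches$pre_id, ms$unmatched_pre), pre$id)
    expect_setequal(c(ms$matches$post_id, ms$unmatched_post), post$id)
  }
})

test_that("matching accuracy reaches 99% on a well-spaced contraction phantom", {
  spec <- phantom_spec(grid_shape = c(96, 96, 96), cavity_diameter = 1000,
                       cavity_depth = 768, bead_count = 150)
  defo <- contraction_of(spec, 0.01)
  ph <- generate_phantom(spec, defo, rigid_transform(), seed = 47)
  mask <- tiny_cavity_mask(ph$pre, spec)
  ss_pre <- segment_spheres(ph$pre, mask)
  ss_post <- segment_spheres(ph$post, mask)
  ms <- match_spheres(ph$pre, ph$post, ss_pre, ss_post,
                      params = match_params(block_half_width = 5L,
                                            search_radius = 4L))
  fld <- compute_vectors(ms, ss_pre, ss_post)
  hits <- truth_hits(fld, ph$truth)
  expect_gte(hits / nrow(fld), 0.99)
  expect_gte(nrow(fld) / nrow(ph$truth), 0.95)
  # refined displacement accuracy on a noisy phantom: below half a voxel
  err <- vapply(seq_len(nrow(fld)), function(i) {
    j <- which.min((ph$truth$x_pre - fld$x_pre[i])^2 +
                     (ph$truth$y_pre - fld$y_pre[i])^2 +
                     (ph$truth$z_pre - fld$z_pre[i])^2)
    sqrt((fld$dx[i] - ph$truth$dx[j])^2 + (fld$dy[i] - ph$truth$dy[j])^2 +
           (fld$dz[i] - ph$truth$dz[j])^2)
  }, 0)
  expect_lt(sqrt(mean(err^2)), 0.5 * 16)
})

test_that("gross displacement outliers are demoted to unmatched", {
  set.seed(48)
  n <- 40
  pre <- data.frame(id = seq_len(n), x = runif(n, 0, 800),
                    y = runif(n, 0, 800), z = runif(n, 0, 800))
  post <- pre
  post$x <- post$x + 5
  post$x[1] <- post$x[1] + 120  # one bead pairs to a far-off impostor
  coarse <- data.frame(pre_id = pre$id, cdx = 0L, cdy = 0L, cdz = 0L, ncc = 0.9)
  ms <- pair_spheres(pre, post, coarse,
                     params = match_params(gate_distance = 200))
  expect_false(1L %in% ms$matches$pre_id)
  expect_equal(nrow(ms$matches), n - 1L)
})
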