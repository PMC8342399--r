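make_field <- function(d, pre = NULL) {
  n <- nrow(d)
  if (is.null(pre))
    pre <- data.frame(id = seq_len(n), x = runif(n, 100, 900),
                      y = runif(n, 100, 900), z = runif(n, 100, 900))
  matches <- data.frame(pre_id = pre$id, post_id = pre$id,
                        cdx = 0L, cdy = 0L, cdz = 0L,
                        dx = d[, 1], dy = d[, 2], dz = d[, 3],
                        residual = 0, ncc = 1)
  ms <- shrinkvec:::new_match_set(matches, integer(), integer(), match_params())
  compute_vectors(ms, pre, pre, labels = list(group = "gp1", sample = "s1",
                                              increment = "whole"))
}

test_that("vector records carry magnitude and the axial sign convention", {
  set.seed(51)
  fld <- make_field(rbind(c(0, 0, 0), c(0, 0, 16), c(0, 0, -16), c(48, 64, 0)))
  expect_equal(fld$magnitude, c(0, 16, 16, 80))
  # +z is movement toward the cavity floor; -z toward the light source
  expect_equal(fld$z_component, c(0, 16, -16, 0))
  expect_true(all(fld$magnitude >= abs(fld$z_component)))
  expect_equal(fld$x_post - fld$x_pre, fld$dx)
  expect_equal(attr(fld, "scale_hint"), 10)
})

test_that("a bead moved toward the cavity floor has positive z-component", {
  spec <- tiny_spec(bead_count = 12)
  down <- deformation_model("axial_drift", axial_shift = 16)   # one voxel down
  ph <- generate_phantom(spec, down, rigid_transform(), seed = 52)
  res <- analyze_phantom(ph, register = FALSE,
                         matching = match_params(search_radius = 3L))
  expect_gt(nrow(res$field), 5)
  expect_equal(median(res$field$z_component), 16, tolerance = 0.15 * 16)
  expect_true(all(res$field$z_component > 0))
  up <- deformation_model("axial_drift", axial_shift = -16)
  ph2 <- generate_phantom(spec, up, rigid_transform(), seed = 52)
  res2 <- analyze_phantom(ph2, register = FALSE,
                          matching = match_params(search_radius = 3L))
  expect_true(all(res2$field$z_component < 0))
})

test_that("summaries report n, mean and sample SD per cell", {
  set.seed(53)
  fld <- make_field(rbind(c(3, 0, 0), c(4, 0, 0), c(5, 0, 0)))
  sm <- summarize_field(fld)
  expect_equal(sm$n, 3L)
  expect_equal(sm$mean_magnitude, 4)
  expect_equal(sm$sd_magnitude, 1)
  expect_equal(sm$mean_z, 0)
})

test_that("single-record cells report NA standard deviations", {
  set.seed(54)
  fld <- make_field(rbind(c(1, 2, 2)))
  sm <- summarize_field(fld)
  expect_equal(sm$n, 1L)
  expect_equal(sm$mean_magnitude, 3)
  expect_true(is.na(sm$sd_magnitude))
})

test_that("summaries recover the analytic contraction mean within 5%", {
  spec <- phantom_spec(grid_shape = c(96, 96, 96), cavity_diameter = 1000,
                       cavity_depth = 768, bead_count = 300)
  defo <- contraction_of(spec, 0.005)
  ph <- generate_phantom(spec, defo, rigid_transform(), seed = 55)
  res <- analyze_phantom(ph, register = FALSE,
                         matching = match_params(block_half_width = 5L,
                                                 search_radius = 3L))
  sm <- summarize_field(res$field, debias = TRUE)
  tru <- ph$truth
  analytic <- mean(sqrt(tru$dx^2 + tru$dy^2 + tru$dz^2))
  expect_equal(sm$mean_magnitude_debiased, analytic,
               tolerance = 0.05 * analytic)
})

test_that("glyph export writes one point, vector and scalar per record", {
  set.seed(56)
  d <- cbind(runif(50, -5, 5), runif(50, -5, 5), runif(50, -5, 5))
  d[7, ] <- 0  # zero vectors are kept
  fld <- make_field(d)
  path <- withr::local_tempfile(fileext = ".vtk")
  export_glyphs(fld, path)
  gl <- read_glyphs(path)
  expect_equal(nrow(gl$points), 50L)
  expect_equal(gl$displacement, unname(d), tolerance = 1e-6)
  expect_equal(gl$points[, 1], fld$x_pre, tolerance = 1e-6)
  expect_equal(gl$magnitude, fld$magnitude, tolerance = 1e-6)
  expect_equal(gl$scale, 10)
  expect_equal(gl$displacement[7, ], c(0, 0, 0))
  expect_error(export_glyphs(fld[0, ], tempfile()), "empty")
})

test_that("field noise estimation recovers an injected noise level", {
  set.seed(57)
  n <- 250
  pre <- data.frame(id = seq_len(n), x = runif(n, 0, 1500),
                    y = runif(n, 0, 1500), z = runif(n, 0, 1500))
  # affine field plus isotropic noise of known sd
  sd_true <- 2
  d <- cbind(-0.01 * (pre$x - 750), -0.01 * (pre$y - 750), 0.005 * pre$z) +
    matrix(rnorm(3 * n, 0, sd_true), ncol = 3)
  fld <- make_field(d, pre)
  est <- estimate_field_noise(fld)
  expect_equal(mean(est$sigma_axis_um), sd_true, tolerance = 0.25 * sd_true)
})

test_that("cumulative increments concatenate under one label", {
  set.seed(58)
  f1 <- make_field(rbind(c(1, 0, 0), c(2, 0, 0)))
  f2 <- make_field(rbind(c(3, 0, 0)))
  f2$increment <- "inc2"
  both <- bind_fields(f1, f2, relabel = list(increment = "inc1+inc2"))
  expect_equal(nrow(both), 3L)
  expect_true(all(both$increment == "inc1+inc2"))
  sm <- summarize_field(both)
  expect_equal(sm$mean_magnitude, 2)
})
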