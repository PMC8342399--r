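#' Compare a recovered rigid pose against a known pose
#'
#' Quantifies the residual misalignment `est o inv(true)`: the rotation angle
#' of the residual rotation and the residual displacement evaluated at a
#' reference point (default: the true pose's rotation centre).
#'
#' @param estimated,truth [rigid_transform()] objects.
#' @param at reference point for the translation error, micrometres.
#' @return List: `translation_error_um`, `rotation_error_deg`.
#' @export
pose_error <- function(estimated, truth, at = truth$center) {
  res <- compose_transform(estimated, invert_transform(truth))
  dp <- as.numeric(transform_points(res, at)) - at
  list(translation_error_um = sqrt(sum(dp^2)),
       rotation_error_deg = rotation_angle_deg(res))
}

#' Score recovered shrinkage vectors against phantom ground truth
#'
#' Matches each measured record to the nearest ground-truth sphere (by
#' pre-cure centroid, within `match_radius`) and reports the fraction of
#' truth spheres recovered with a correct correspondence, the per-sphere
#' displacement error RMSE, and the relative error of the mean vector
#' magnitude against the analytic mean computed from the true displacements.
#'
#' @param field a [compute_vectors()] result.
#' @param truth the `truth` data frame of a [generate_phantom()] result.
#' @param match_radius truth-assignment radius, micrometres (default one
#'   16-um voxel).
#' @return List: `n_truth`, `n_measured`, `n_correct`, `recovered_fraction`,
#'   `displacement_rmse_um`, `mean_magnitude_measured_um`,
#'   `mean_magnitude_true_um`, `mean_magnitude_rel_error`.
#' @export
score_against_truth <- function(field, truth, match_radius = 16) {
  if (!nrow(field))
    return(list(n_truth = nrow(truth), n_measured = 0L, n_correct = 0L,
                recovered_fraction = 0, displacement_rmse_um = NA_real_,
                mean_magnitude_measured_um = NA_real_,
                mean_magnitude_true_um = mean(sqrt(truth$dx^2 + truth$dy^2 + truth$dz^2)),
                mean_magnitude_rel_error = NA_real_))
  tid <- integer(nrow(field))
  for (i in seq_len(nrow(field))) {
    d2 <- (truth$x_pre - field$x_pre[i])^2 + (truth$y_pre - field$y_pre[i])^2 +
      (truth$z_pre - field$z_pre[i])^2
    j <- which.min(d2)
    tid[i] <- if (d2[j] <= match_radius^2) truth$id[j] else NA_integer_
  }
  ok <- !is.na(tid) & !duplicated(tid)
  tru <- truth[match(tid[ok], truth$id), , drop = FALSE]
  err2 <- (field$dx[ok] - tru$dx)^2 + (field$dy[ok] - tru$dy)^2 +
    (field$dz[ok] - tru$dz)^2
  mag_true <- mean(sqrt(truth$dx^2 + truth$dy^2 + truth$dz^2))
  mag_meas <- mean(field$magnitude)
  s2 <- if (nrow(field) >= 20)
    tryCatch(2 * mean(estimate_field_noise(field)$sigma_axis_um^2),
             error = function(e) 0)
  else 0
  mag_deb <- mean(sqrt(pmax(field$magnitude^2 - s2, 0)))
  list(n_truth = nrow(truth), n_measured = nrow(field), n_correct = sum(ok),
       recovered_fraction = sum(ok) / nrow(truth),
       displacement_rmse_um = sqrt(mean(err2)),
       mean_magnitude_measured_um = mag_meas,
       mean_magnitude_debiased_um = mag_deb,
       mean_magnitude_true_um = mag_true,
       mean_magnitude_rel_error = abs(mag_meas - mag_true) / mag_true,
       mean_magnitude_debiased_rel_error = abs(mag_deb - mag_true) / mag_true)
}

#' Replicated two-group contraction discrimination study
#'
#' Generates paired phantom groups that differ only in their uniform
#' contraction fraction, runs the segmentation/matching/vector chain on each
#' (identity pose; the registration stage is validated separately), and tests
#' the group difference in vector magnitudes by one-way ANOVA -- one
#' replicate per seed. A method able to quantify shrinkage must separate the
#' two contraction levels in essentially every replicate, with group means
#' ordered by the true contraction.
#'
#' @param s_small,s_large contraction fractions of the two groups.
#' @param n_replicates number of seeded replicates.
#' @param spec phantom specification shared by both groups (default: a
#'   compact 88^3 phantom carrying 300 tracer spheres).
#' @param matching [match_params()] for the chain (default: a tight search
#'   window, since the true displacements are well below 2 voxels).
#' @param seed base seed; replicate `r` uses `seed + 1000 r + {1, 2}`.
#' @param verbose print one line per replicate.
#' @return Data frame: `replicate`, `n_small`, `n_large`, `mean_small`,
#'   `mean_large`, `F`, `p`.
#' @export
contraction_discrimination <- function(s_small = 0.005, s_large = 0.02,
                                       n_replicates = 100,
                                       spec = phantom_spec(
                                         grid_shape = c(88, 88, 88),
                                         cavity_diameter = 992,
                                         cavity_depth = 704),
                                       matching = match_params(
                                         block_half_width = 4L,
                                         search_radius = 3L),
                                       seed = 1, verbose = FALSE) {
  one <- function(s, sd_) {
    defo <- deformation_model("uniform_contraction",
                              center = cavity_floor_center(spec),
                              contraction_fraction = s)
    ph <- generate_phantom(spec, defo, rigid_transform(), seed = sd_)
    analyze_phantom(ph, register = FALSE, matching = matching)$field$magnitude
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    m1 <- one(s_small, seed + 1000 * r + 1)
    m2 <- one(s_large, seed + 1000 * r + 2)
    an <- one_way_anova(list(small = m1, large = m2))
    if (verbose)
      message(sprintf("replicate %d: means %.2f / %.2f um, p = %.3g",
                      r, mean(m1), mean(m2), an$p))
    data.frame(replicate = r, n_small = length(m1), n_large = length(m2),
               mean_small = mean(m1), mean_large = mean(m2),
               F = an$F, p = an$p)
  })
  do.call(rbind, rows)
}

#' Run segmentation, matching and vector computation on a phantom
#'
#' The standard analysis chain for one phantom scan pair: optional rigid
#' registration (or the identity when the phantom was generated without a
#' pose offset), cavity masking, segmentation of both scans, block matching
#' and shrinkage-vector computation.
#'
#' @param phantom a [generate_phantom()] result.
#' @param register run rigid registration (set `FALSE` for identity-pose
#'   phantoms to skip the alignment stage).
#' @param segmentation,matching,registration stage parameter objects
#'   ([segmentation_params()], [match_params()], [register_params()]).
#' @param labels labels attached to the resulting field.
#' @return List: `field`, `transform`, `registration` (or `NULL`),
#'   `pre_set`, `post_set`, `matches`.
#' @export
analyze_phantom <- function(phantom, register = TRUE,
                            segmentation = segmentation_params(),
                            matching = match_params(),
                            registration = register_params(),
                            labels = list(group = "phantom", sample = "s1",
                                          increment = "whole")) {
  spec <- phantom$spec
  g <- cavity_geometry(spec)
  cav_center <- c(g$cx, g$cy, g$z_mouth)
  reg <- NULL
  if (register) {
    mask <- registration_mask(
      phantom$pre, cav_center, spec$cavity_diameter, spec$cavity_depth,
      dilate_voxels = 3,
      intensity_range = c((spec$water_attenuation + spec$dentin_attenuation) / 2, Inf))
    reg <- register_rigid(phantom$pre, phantom$post, mask, registration)
    tf <- reg$transform
  } else {
    tf <- rigid_transform()
  }
  mask_pre <- make_cavity_mask(phantom$pre, cav_center, spec$cavity_diameter,
                               spec$cavity_depth, margin = 2)
  mask_post <- make_cavity_mask(phantom$post, cav_center, spec$cavity_diameter,
                                spec$cavity_depth, margin = 2, transform = tf)
  pre_set <- segment_spheres(phantom$pre, mask_pre, segmentation)
  post_set <- segment_spheres(phantom$post, mask_post, segmentation)
  ms <- match_spheres(phantom$pre, phantom$post, pre_set, post_set, tf,
                      matching)
  field <- compute_vectors(ms, pre_set, post_set, labels,
                           voxel_size = spec$voxel_size)
  list(field = field, transform = tf, registration = reg,
       pre_set = pre_set, post_set = post_set, matches = ms)
}
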