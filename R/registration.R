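#' Registration parameters
#'
#' Controls for [register_rigid()]: a multi-resolution (coarse-to-fine)
#' maximization of masked normalized cross-correlation over the 6 rigid
#' parameters, using a deterministic derivative-free coordinate descent with
#' step halving (no randomness, so equal inputs always give equal results).
#'
#' @param levels integer downsampling factors, coarse to fine.
#' @param strides voxel sampling stride of the NCC metric at each level (the
#'   metric is evaluated on every `stride`-th masked voxel).
#' @param initial a [rigid_transform()] used as the starting point.
#' @param rot_step0,trans_step0 initial search steps (degrees; micrometres are
#'   derived as `trans_step0` voxels at each level's voxel size).
#' @param tol_rot,tol_trans convergence tolerances (degrees; voxels at the
#'   finest level).
#' @param max_eval metric-evaluation cap per level.
#' @param metric_sigma Gaussian smoothing (voxels) applied to both volumes at
#'   the full-resolution level before evaluating the metric; the coarser
#'   pyramid levels are already box-filtered. Raises the signal-to-noise
#'   ratio of the similarity without moving its optimum.
#' @param min_mask_voxels smallest usable mask.
#' @param border_voxels fixed-grid voxels this close to a volume face are
#'   excluded from the metric, so that the NCC sample set does not change with
#'   the candidate pose (a drifting sample set biases the optimum toward
#'   poses that push ill-fitting voxels out of the field of view).
#' @return A list of class `register_params`.
#' @export
register_params <- function(levels = c(4L, 2L, 1L), strides = c(1L, 3L, 8L),
                            initial = rigid_transform(),
                            rot_step0 = 2, trans_step0 = 2,
                            tol_rot = 0.005, tol_trans = 0.02,
                            max_eval = 4000L, metric_sigma = 1,
                            min_mask_voxels = 1000L, border_voxels = 10) {
  structure(list(levels = as.integer(levels), strides = as.integer(strides),
                 initial = initial, rot_step0 = rot_step0,
                 trans_step0 = trans_step0, tol_rot = tol_rot,
                 tol_trans = tol_trans, max_eval = as.integer(max_eval),
                 metric_sigma = metric_sigma,
                 min_mask_voxels = as.integer(min_mask_voxels),
                 border_voxels = border_voxels),
            class = "register_params")
}

#' Rigid registration of a post-cure scan onto a pre-cure scan
#'
#' Finds the rigid transform `T` (fixed world coordinates to moving world
#' coordinates) maximizing the normalized cross-correlation between
#' `fixed(x)` and `moving(T(x))` over the masked voxels of the fixed volume.
#' The mask should select static anatomy only (tooth structure); by default
#' the analysis pipeline excludes the composite region, so that composite
#' shrinkage does not bias the alignment. The returned transform is intended
#' to be applied to sphere coordinates (post-cure centroids are mapped back
#' into the pre-cure frame with its inverse), not to resample image data.
#'
#' @param fixed,moving [new_volume()] objects with equal voxel sizes.
#' @param mask optional logical array on the fixed grid (`NULL` = all voxels).
#' @param params a [register_params()].
#' @return A list of class `registration_result`: `transform`
#'   ([rigid_transform()], rotation centre at the fixed volume centre),
#'   `final_similarity` (NCC in `[-1, 1]`), `iterations` (metric evaluations)
#'   and `converged`.
#' @export
register_rigid <- function(fixed, moving, mask = NULL, params = register_params()) {
  stopifnot(is_volume(fixed), is_volume(moving))
  if (max(abs(fixed$voxel_size - moving$voxel_size)) > 1e-9)
    stop("fixed and moving volumes must share a voxel size")
  if (is.null(mask)) mask <- array(TRUE, dim(fixed$data))
  if (!identical(dim(mask), dim(fixed$data)))
    stop("mask must match the fixed grid")
  if (sum(mask) < params$min_mask_voxels)
    stop(sprintf("degenerate mask: %d voxels (< %d)", sum(mask),
                 params$min_mask_voxels))
  # keep the metric's sample set pose-invariant: stay clear of the faces
  if (params$border_voxels > 0) {
    d0 <- dim(mask)
    b <- ceiling(params$border_voxels)
    if (all(d0 > 2 * b + 4)) {
      trimmed <- mask
      trimmed[c(seq_len(b), d0[1] - seq_len(b) + 1L), , ] <- FALSE
      trimmed[, c(seq_len(b), d0[2] - seq_len(b) + 1L), ] <- FALSE
      trimmed[, , c(seq_len(b), d0[3] - seq_len(b) + 1L)] <- FALSE
      if (sum(trimmed) >= params$min_mask_voxels) mask <- trimmed
    }
  }

  center <- fixed$origin + dim(fixed$data) * fixed$voxel_size / 2
  theta <- c(params$initial$rotation, params$initial$translation)
  total_eval <- 0L
  sim0 <- NA_real_
  sim <- NA_real_

  for (li in seq_along(params$levels)) {
    f <- params$levels[li]
    stride <- params$strides[li]
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    if (f == 1L && params$metric_sigma > 0) {
      fx <- smooth_volume(fx, params$metric_sigma)
      mv <- smooth_volume(mv, params$metric_sigma)
    }
    mk <- if (f == 1L) mask else
      array(cpp_downsample(as.numeric(mask), dim(mask), f) > 0.5,
            dim(fx$data))
    idx <- which(mk)
    if (stride > 1L) idx <- idx[seq(1L, length(idx), by = stride)]
    if (length(idx) < 50L) next
    d <- dim(fx$data)
    i0 <- idx - 1L
    pts <- cbind(i0 %% d[1],
                 (i0 %/% d[1]) %% d[2],
                 i0 %/% (d[1] * d[2]))
    storage.mode(pts) <- "double"
    fvals <- as.numeric(fx$data)[idx]
    mdat <- as.numeric(mv$data)
    mdim <- dim(mv$data)

    # cubic sampling at full resolution (linear interpolation biases NCC
    # toward integer shifts); the box-filtered coarse levels are smooth
    # enough for the cheaper linear metric
    interp <- if (f == 1L) 3L else 1L
    evaluate <- function(th) {
      tf <- rigid_transform(th[1:3], th[4:6], center)
      ab <- transform_to_voxel_affine(tf, fx, mv)
      r <- cpp_ncc_points(fvals, pts, mdat, mdim, ab$A, ab$b, interp)
      total_eval <<- total_eval + 1L
      if (!is.finite(r$ncc) || r$n < 0.25 * length(fvals)) return(-2)
      r$ncc
    }

    best <- evaluate(theta)
    sim0 <- best  # similarity at this level's starting point
    scale <- 4^(li - 1)
    rot_step <- params$rot_step0 / scale
    trans_step <- params$trans_step0 * fx$voxel_size[1] / 2^(li - 1)
    level_eval <- 1L
    repeat {
      improved <- FALSE
      for (j in 1:6) {
        step <- if (j <= 3) rot_step else trans_step
        for (s in c(1, -1)) {
          cand <- theta
          cand[j] <- cand[j] + s * step
          val <- evaluate(cand)
          level_eval <- level_eval + 1L
          if (val > best) {
            best <- val
            theta <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) {
        rot_step <- rot_step / 2
        trans_step <- trans_step / 2
        if (rot_step < params$tol_rot &&
            trans_step < params$tol_trans * fixed$voxel_size[1]) break
      }
      if (level_eval >= params$max_eval) break
    }
    sim <- best
  }

  transform <- rigid_transform(theta[1:3], theta[4:6], center)
  if (!is.finite(sim)) stop("registration similarity is non-finite")
  structure(
    list(transform = transform, final_similarity = sim,
         iterations = total_eval,
         converged = is.finite(sim) && (!is.finite(sim0) || sim >= sim0)),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> NCC %.5f after %d evaluations (%s)\n",
              x$final_similarity, x$iterations,
              if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

#' Registration mask excluding the restoration
#'
#' Builds the default registration mask: all voxels except the cavity cylinder
#' dilated by a safety margin, so that only static tooth anatomy drives the
#' alignment.
#'
#' @param volume fixed-grid [new_volume()].
#' @param cavity_center cavity-mouth centre `(x, y, z)`, micrometres.
#' @param diameter,depth cavity cylinder, micrometres.
#' @param dilate_voxels outward dilation of the excluded cylinder, voxels.
#' @param intensity_range optional `(lo, hi)` window: only fixed-scan voxels
#'   within it are kept, restricting the metric to informative anatomy (e.g. a
#'   dentin/enamel window that drops water-only voxels).
#' @return A logical array on the volume's grid.
#' @export
registration_mask <- function(volume, cavity_center, diameter, depth,
                              dilate_voxels = 3, intensity_range = NULL) {
  pad <- dilate_voxels * mean(volume$voxel_size)
  cyl <- cylinder_mask(volume, cavity_center, diameter / 2 + pad,
                       cavity_center[3] - pad, cavity_center[3] + depth + pad)
  mask <- !cyl
  if (!is.null(intensity_range))
    mask <- mask & volume$data >= intensity_range[1] &
      volume$data <= intensity_range[2]
  mask
}

# Logical array: voxel centres inside a z-aligned cylinder.
cylinder_mask <- function(volume, center_xy, radius, z0, z1) {
  ax <- voxel_axes_world(volume)
  r2 <- outer((ax[[1]] - center_xy[1])^2, (ax[[2]] - center_xy[2])^2, "+")
  inxy <- r2 <= radius^2
  inz <- ax[[3]] >= z0 & ax[[3]] <= z1
  array(outer(as.vector(inxy), inz, "&"), dim(volume$data))
}
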