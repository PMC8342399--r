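#' Cylindrical cavity analysis mask
#'
#' Marks voxels whose centres lie inside the cavity cylinder eroded inward by
#' `margin` voxels. When a rigid `transform` (pre-cure to post-cure frame) is
#' given, the cylinder is defined in the pre-cure frame and the mask is built
#' on the post-cure grid by testing each voxel's back-mapped position, so the
#' same physical region is selected in both scans.
#'
#' @param volume grid-defining [new_volume()].
#' @param cavity_center cavity-mouth centre `(x, y, z)`, micrometres.
#' @param diameter,depth cavity cylinder, micrometres.
#' @param margin inward erosion, voxels.
#' @param transform optional [rigid_transform()] mapping the cylinder's frame
#'   to the volume's frame.
#' @return A logical array; an empty mask is an error.
#' @export
make_cavity_mask <- function(volume, cavity_center, diameter, depth,
                             margin = 0, transform = NULL) {
  pad <- margin * mean(volume$voxel_size)
  radius <- diameter / 2 - pad
  z0 <- cavity_center[3] + pad
  z1 <- cavity_center[3] + depth - pad
  if (radius <= 0 || z0 >= z1)
    stop("empty cavity mask: margin erodes the cylinder away")
  if (is.null(transform) || is_identity_transform(transform)) {
    mask <- cylinder_mask(volume, cavity_center, radius, z0, z1)
  } else {
    d <- dim(volume$data)
    ax <- voxel_axes_world(volume)
    W <- cbind(rep(ax[[1]], times = d[2] * d[3]),
               rep(rep(ax[[2]], each = d[1]), times = d[3]),
               rep(ax[[3]], each = d[1] * d[2]))
    P <- transform_points(invert_transform(transform), W)
    inside <- (P[, 1] - cavity_center[1])^2 + (P[, 2] - cavity_center[2])^2 <=
      radius^2 & P[, 3] >= z0 & P[, 3] <= z1
    mask <- array(inside, d)
  }
  if (!any(mask)) stop("empty cavity mask: cylinder does not intersect the grid")
  mask
}

#' Segmentation parameters
#'
#' Tracer spheres are detected as low-attenuation ("radiolucent") blobs
#' relative to the local composite level; air bubbles are the same detector
#' (they are simply deeper radiolucencies). Components are filtered by size
#' and compactness. Compactness is defined as component volume divided by the
#' volume of the sphere whose radius is the component bounding box's
#' half-diagonal; an ideal sphere scores `3^-1.5` (about 0.19) under this
#' definition and true sphericity is unstable at 2-4-voxel diameters, so the
#' default threshold is permissive (0.1) -- it rejects elongated streaks, not
#' imperfect spheres.
#'
#' @param threshold_mode `"fixed_fraction"` (default: a fraction of the
#'   99.9th-percentile contrast, floored at `noise_floor_sigma` robust
#'   standard deviations of the contrast distribution) or `"otsu_in_mask"`
#'   (Otsu's threshold on the in-mask contrast; suited to low-noise scans --
#'   with a sphere class of well under 1 percent of the voxels and strong
#'   noise, Otsu's criterion collapses into the noise bulk).
#' @param fixed_fraction threshold as a fraction of the 99.9th percentile of
#'   the in-mask contrast.
#' @param noise_floor_sigma lower bound on the threshold in units of the
#'   robust (MAD-based) contrast standard deviation.
#' @param min_volume,max_volume accepted component size, voxels; defaults
#'   bracket sphere diameters of 2-6 voxels (32-96 um at 16 um voxels).
#' @param min_compactness accepted compactness, in (0, 1].
#' @param connectivity `26` (default) or `6`.
#' @param presmooth_sigma Gaussian presmoothing of the contrast image, voxels
#'   (0 disables). Smoothing is symmetric, so sphere centroids are unbiased.
#' @param refine_centroids iteratively re-estimate each centroid as the
#'   Gaussian-weighted centre of mass of the contrast in a window around the
#'   component (weight `contrast * exp(-r^2 / (2 * refine_sigma^2))`,
#'   recentred each iteration). Unlike the threshold-clipped centre of mass,
#'   this uses the full partial-volume tails and approaches the
#'   information-theoretic localization limit on noisy scans.
#' @param refine_sigma weighting sigma of the refinement window, voxels.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_mode = c("fixed_fraction", "otsu_in_mask"),
                                fixed_fraction = 0.4, noise_floor_sigma = 4.5,
                                min_volume = 4L, max_volume = 120L,
                                min_compactness = 0.1,
                                connectivity = 26L, presmooth_sigma = 0.6,
                                refine_centroids = TRUE, refine_sigma = 1.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_volume >= max_volume) stop("min_volume must be < max_volume")
  if (min_compactness <= 0 || min_compactness > 1)
    stop("min_compactness must be in (0, 1]")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(threshold_mode = threshold_mode, fixed_fraction = fixed_fraction,
                 noise_floor_sigma = noise_floor_sigma,
                 min_volume = as.integer(min_volume),
                 max_volume = as.integer(max_volume),
                 min_compactness = min_compactness,
                 connectivity = as.integer(connectivity),
                 presmooth_sigma = presmooth_sigma,
                 refine_centroids = isTRUE(refine_centroids),
                 refine_sigma = refine_sigma),
            class = "segmentation_params")
}

#' Detect radiolucent tracer spheres
#'
#' Builds a contrast image (local composite level minus voxel value, where the
#' local level is the per-slice median of masked voxels, robust to the z-wise
#' layering of the restoration), thresholds it inside the mask, labels
#' connected components and filters them by volume and compactness. Centroids
#' are contrast-weighted centres of mass in world coordinates (sub-voxel).
#' Sphere ids are assigned by lexicographic centroid order, so the output is
#' independent of labelling order and stable under re-runs.
#'
#' @param volume a [new_volume()].
#' @param mask logical array: the analysis region (e.g. [make_cavity_mask()]).
#' @param params a [segmentation_params()].
#' @return A data frame of class `sphere_set`: `id`, `x`, `y`, `z` (um),
#'   `equivalent_radius` (um), `voxel_count`, `compactness`, `mean_contrast`;
#'   detection parameters in attribute `"params"`. A degenerate (uniform)
#'   image yields an empty set, not an error.
#' @export
segment_spheres <- function(volume, mask, params = segmentation_params()) {
  stopifnot(is_volume(volume))
  if (!identical(dim(mask), dim(volume$data))) stop("mask must match the volume grid")
  if (!any(mask)) stop("empty mask")
  if (any(!is.finite(volume$data[mask]))) stop("volume contains non-finite values")

  d <- dim(volume$data)
  work <- if (params$presmooth_sigma > 0)
    smooth_volume(volume, params$presmooth_sigma) else volume

  # local composite level: per-slice median over the mask
  level_z <- rep(NA_real_, d[3])
  msum <- apply(mask, 3, any)
  for (k in which(msum))
    level_z[k] <- median(work$data[, , k][mask[, , k]])
  contrast <- array(0, d)
  for (k in which(msum))
    contrast[, , k] <- (level_z[k] - work$data[, , k]) * mask[, , k]

  cvals <- contrast[mask]
  hi <- quantile(cvals, 0.999, names = FALSE)
  if (!is.finite(hi) || hi <= 0) return(empty_sphere_set(params))
  thr <- switch(params$threshold_mode,
    otsu_in_mask = otsu_threshold(cvals),
    fixed_fraction = max(params$fixed_fraction * hi,
                         params$noise_floor_sigma * stats::mad(cvals))
  )
  if (!is.finite(thr) || thr <= 0) return(empty_sphere_set(params))

  binary <- contrast > thr & mask
  if (!any(binary)) return(empty_sphere_set(params))
  labels <- cpp_label3d(as.vector(binary), d, params$connectivity)
  ncomp <- attr(labels, "n_components")
  if (ncomp == 0L) return(empty_sphere_set(params))

  vox <- which(labels > 0L)
  lab <- labels[vox]
  i0 <- vox - 1L
  xs <- i0 %% d[1]
  ys <- (i0 %/% d[1]) %% d[2]
  zs <- i0 %/% (d[1] * d[2])
  w <- pmax(contrast[vox], 0)

  counts <- tabulate(lab, ncomp)
  wsum <- rowsum_by(w, lab, ncomp)
  keep_w <- wsum > 0
  cx <- rowsum_by(w * xs, lab, ncomp)
  cy <- rowsum_by(w * ys, lab, ncomp)
  cz <- rowsum_by(w * zs, lab, ncomp)
  # fall back to unweighted centroids where all weights vanish
  ux <- rowsum_by(xs, lab, ncomp) / counts
  uy <- rowsum_by(ys, lab, ncomp) / counts
  uz <- rowsum_by(zs, lab, ncomp) / counts
  cxv <- ifelse(keep_w, cx / wsum, ux)
  cyv <- ifelse(keep_w, cy / wsum, uy)
  czv <- ifelse(keep_w, cz / wsum, uz)
  if (any(!keep_w))
    warning(sum(!keep_w), " component(s) had all-zero contrast weights; ",
            "unweighted centroids used")

  bb <- function(v) (rowsum_by_max(v, lab, ncomp) - rowsum_by_min(v, lab, ncomp) + 1)
  half_diag <- sqrt(bb(xs)^2 + bb(ys)^2 + bb(zs)^2) / 2
  compact <- counts / ((4 / 3) * pi * half_diag^3)
  mean_contrast <- rowsum_by(contrast[vox], lab, ncomp) / counts

  sel <- counts >= params$min_volume & counts <= params$max_volume &
    compact >= params$min_compactness
  if (!any(sel)) return(empty_sphere_set(params))

  cent_vox <- cbind(cxv[sel], cyv[sel], czv[sel])
  if (params$refine_centroids)
    cent_vox <- refine_centroids_gw(contrast, d, cent_vox, params$refine_sigma)
  cent <- voxel_to_world(volume, cent_vox)
  voxvol <- prod(volume$voxel_size)
  out <- data.frame(
    id = 0L,
    x = cent[, 1], y = cent[, 2], z = cent[, 3],
    equivalent_radius = (3 * counts[sel] * voxvol / (4 * pi))^(1 / 3),
    voxel_count = counts[sel],
    compactness = compact[sel],
    mean_contrast = mean_contrast[sel]
  )
  out <- out[order(out$x, out$y, out$z), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("sphere_set", "data.frame")
  out
}

# Iterative Gaussian-weighted centre of mass on the contrast image.
# cent_vox: n x 3 starting centroids (0-based continuous voxel indices).
refine_centroids_gw <- function(contrast, d, cent_vox, sigma,
                                window = ceiling(2.5 * sigma), iterations = 6L) {
  out <- cent_vox
  for (i in seq_len(nrow(cent_vox))) {
    c0 <- cent_vox[i, ]
    xs <- max(0, round(c0[1]) - window):min(d[1] - 1, round(c0[1]) + window)
    ys <- max(0, round(c0[2]) - window):min(d[2] - 1, round(c0[2]) + window)
    zs <- max(0, round(c0[3]) - window):min(d[3] - 1, round(c0[3]) + window)
    gr <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    cv <- pmax(contrast[gr + 1L], 0)
    if (sum(cv) <= 0) next
    cc <- c0
    for (it in seq_len(iterations)) {
      r2 <- (gr[, 1] - cc[1])^2 + (gr[, 2] - cc[2])^2 + (gr[, 3] - cc[3])^2
      w <- cv * exp(-r2 / (2 * sigma^2))
      sw <- sum(w)
      if (sw <= 0) break
      cn <- colSums(gr * w) / sw
      if (max(abs(cn - cc)) < 1e-4) { cc <- cn; break }
      cc <- cn
    }
    # a refinement should polish, not jump to a neighbour
    if (sqrt(sum((cc - c0)^2)) <= 1.5) out[i, ] <- cc
  }
  out
}

empty_sphere_set <- function(params) {
  out <- data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
                    equivalent_radius = numeric(), voxel_count = integer(),
                    compactness = numeric(), mean_contrast = numeric())
  attr(out, "params") <- params
  class(out) <- c("sphere_set", "data.frame")
  out
}

# Otsu's threshold via EBImage on the (positive part of the) contrast sample.
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) <= 0) return(NA_real_)
  img <- EBImage::Image(matrix((vals - rng[1]) / diff(rng), ncol = 1))
  t01 <- EBImage::otsu(img, range = c(0, 1), levels = 4096L)
  rng[1] + t01 * diff(rng)
}

# grouped sums / extrema over integer labels 1..n
rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(as.numeric(x), g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
rowsum_by_max <- function(x, g, n) {
  out <- rep(-Inf, n)
  agg <- tapply(x, g, max)
  out[as.integer(names(agg))] <- agg
  out
}
rowsum_by_min <- function(x, g, n) {
  out <- rep(Inf, n)
  agg <- tapply(x, g, min)
  out[as.integer(names(agg))] <- agg
  out
}

#' Sub-voxel centroid of a labelled component
#'
#' Contrast-weighted centre of mass in world coordinates (voxel-centre
#' convention). With all-zero weights the unweighted centroid is returned with
#' a warning.
#'
#' @param voxels n x 3 matrix of 0-based voxel indices.
#' @param weights n non-negative weights (e.g. contrast values).
#' @param voxel_size voxel size, micrometres (scalar or length 3).
#' @param origin grid origin, micrometres.
#' @return Length-3 centroid, micrometres.
#' @export
estimate_centroid <- function(voxels, weights, voxel_size, origin = c(0, 0, 0)) {
  v <- rbind_coords(voxels)
  if (!nrow(v)) stop("empty component")
  w <- as.numeric(weights)
  if (all(w == 0)) {
    warning("all-zero weights; using unweighted centroid")
    w <- rep(1, nrow(v))
  }
  idx <- as.numeric(colSums(v * w) / sum(w))
  origin + (idx + 0.5) * rep_len(as.numeric(voxel_size), 3L)
}
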