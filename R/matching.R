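#' Block-matching parameters
#'
#' @param block_half_width half-width of the image block centred on each
#'   pre-cure sphere, voxels (block edge `2*hw + 1`).
#' @param search_radius exhaustive integer-displacement search radius, voxels;
#'   must be at least the largest expected displacement.
#' @param gate_distance centroid pairing gate, micrometres.
#' @param min_ncc minimum block NCC for a sphere to be matchable.
#' @param smooth_sigma Gaussian smoothing (voxels) applied to both volumes
#'   before block matching in [match_spheres()]. A tracer sphere occupies a
#'   few voxels of a block, so on noisy scans the raw-intensity NCC is
#'   noise-dominated; matched filtering restores it.
#' @param refine `"centroid"` (refined displacement from sub-voxel centroids,
#'   the default) or `"ncc_subvoxel"` (from the parabola-interpolated block
#'   NCC peak).
#' @param outlier_mad robustness gate on the matched displacement field: a
#'   match whose displacement deviates from the component-wise field median
#'   by more than `outlier_mad` MADs (floored at 1 voxel) is demoted to
#'   unmatched. Composite flow is spatially coherent, so isolated gross
#'   deviations are almost always a block that locked onto a neighbouring
#'   sphere. Set to `Inf` to disable.
#' @return A list of class `match_params`.
#' @export
match_params <- function(block_half_width = 7L, search_radius = 10L,
                         gate_distance = 32, min_ncc = 0.3,
                         smooth_sigma = 1,
                         refine = c("centroid", "ncc_subvoxel"),
                         outlier_mad = 8) {
  if (gate_distance <= 0) stop("gate_distance must be > 0")
  refine <- match.arg(refine)
  structure(list(block_half_width = as.integer(block_half_width),
                 search_radius = as.integer(search_radius),
                 gate_distance = gate_distance, min_ncc = min_ncc,
                 smooth_sigma = smooth_sigma, refine = refine,
                 outlier_mad = outlier_mad),
            class = "match_params")
}

#' Coarse displacement of one sphere by block matching
#'
#' Takes the image block centred on the sphere's pre-cure voxel and searches
#' the post-cure volume exhaustively over integer displacements within
#' `search_radius` of the rigidly mapped position, maximizing normalized
#' cross-correlation. Ties are broken by smallest displacement magnitude, then
#' lexicographically on `(dx, dy, dz)`. Blocks overhanging the volume edge are
#' shrunk with a warning; a zero-variance block yields a no-score result
#' (`ncc = NA`), which routes the sphere to the unmatched set downstream.
#'
#' @param pre,post [new_volume()] pair.
#' @param centroid pre-cure sphere centroid, world micrometres.
#' @param transform [rigid_transform()] mapping pre-cure to post-cure world
#'   coordinates (identity if the scans are already aligned).
#' @param params a [match_params()].
#' @return List with `disp` (best integer displacement, post-grid voxels),
#'   `subvoxel` (`disp` refined by a 3-point parabola through the NCC peak),
#'   `scan_disp_vox` (total scan-frame displacement of the sphere in voxels,
#'   including the rigid mapping of the block centre), `ncc`, `status`
#'   (`"ok"`, `"shrunk"` or `"no_score"`).
#' @export
block_match <- function(pre, post, centroid, transform = rigid_transform(),
                        params = match_params()) {
  pc <- round(world_to_voxel(pre, centroid))
  qc <- round(world_to_voxel(post, transform_points(transform, centroid)))
  pc <- pmin(pmax(as.integer(pc), 0L), dim(pre$data) - 1L)
  qc <- pmin(pmax(as.integer(qc), 0L), dim(post$data) - 1L)
  r <- cpp_block_match(as.numeric(pre$data), dim(pre$data),
                       as.numeric(post$data), dim(post$data),
                       pc, qc, params$block_half_width, params$search_radius)
  status <- c("ok", "shrunk", "no_score")[r$status + 1L]
  if (status == "shrunk")
    warning("block shrunk at volume edge for centroid (",
            paste(round(centroid, 1), collapse = ", "), ")")
  scan_disp <- if (status == "no_score") rep(NA_real_, 3) else
    as.numeric(qc - pc) + r$subvoxel
  list(disp = r$disp, subvoxel = r$subvoxel, scan_disp_vox = scan_disp,
       ncc = r$ncc, status = status)
}

#' Pair spheres across scans
#'
#' For each pre-cure sphere, the candidate post-cure position is its rigidly
#' mapped centroid plus the coarse block-matching displacement; post-cure
#' spheres within `gate_distance` of the candidate are potential partners.
#' Conflicts are resolved globally and deterministically by ascending residual
#' distance (greedy on sorted residuals), enforcing a one-to-one match.
#'
#' The refined displacement (in the pre-cure frame, micrometres) comes from
#' the sub-voxel NCC peak of the block match when available (`tdx`..`tdz`
#' columns): correlating the whole block averages the scanner noise over far
#' more voxels than a centroid does, which matters on noisy scans. Without
#' those columns it falls back to
#' `invert(transform)(post centroid) - pre centroid`.
#'
#' @param pre_set,post_set [segment_spheres()] outputs.
#' @param coarse data frame from the block-matching stage: one row per
#'   pre-cure sphere (`pre_id`, `cdx`, `cdy`, `cdz` in post-grid voxels,
#'   `ncc`, optionally `tdx`, `tdy`, `tdz` = total scan-frame displacement in
#'   voxels including the rigid mapping of the block centre).
#' @param transform [rigid_transform()] (pre-cure to post-cure frame).
#' @param post_voxel_size post-scan voxel size, micrometres.
#' @param params a [match_params()].
#' @return A list of class `match_set`: `matches` (data frame `pre_id`,
#'   `post_id`, `cdx`, `cdy`, `cdz`, `dx`, `dy`, `dz` (um, pre frame),
#'   `residual`, `ncc`), `unmatched_pre`, `unmatched_post`, `params`.
#' @export
pair_spheres <- function(pre_set, post_set, coarse,
                         transform = rigid_transform(),
                         post_voxel_size = c(16, 16, 16),
                         params = match_params()) {
  inv <- invert_transform(transform)
  empty <- data.frame(pre_id = integer(), post_id = integer(),
                      cdx = integer(), cdy = integer(), cdz = integer(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      residual = numeric(), ncc = numeric())
  if (!nrow(pre_set) || !nrow(post_set)) {
    return(new_match_set(empty, pre_set$id, post_set$id, params))
  }
  vs <- rep_len(as.numeric(post_voxel_size), 3L)

  cand <- NULL
  usable <- !is.na(coarse$ncc) & coarse$ncc >= params$min_ncc
  pre_xyz <- as.matrix(pre_set[, c("x", "y", "z")])
  post_xyz <- as.matrix(post_set[, c("x", "y", "z")])
  mapped <- transform_points(transform, pre_xyz)  # pre centroids in post frame
  has_t <- all(c("tdx", "tdy", "tdz") %in% names(coarse))
  for (i in which(usable)) {
    row <- coarse[i, ]
    pi_ <- match(row$pre_id, pre_set$id)
    # prefer the sub-voxel total scan displacement for the candidate
    # position (it already includes the rigid mapping of the block centre);
    # integer quantization of the coarse step would eat into the gate budget
    target <- if (has_t && !anyNA(row[c("tdx", "tdy", "tdz")]))
      pre_xyz[pi_, ] + as.numeric(row[c("tdx", "tdy", "tdz")]) * vs
    else
      mapped[pi_, ] + c(row$cdx, row$cdy, row$cdz) * vs
    d2 <- (post_xyz[, 1] - target[1])^2 + (post_xyz[, 2] - target[2])^2 +
      (post_xyz[, 3] - target[3])^2
    near <- which(d2 <= params$gate_distance^2)
    if (length(near))
      cand <- rbind(cand, data.frame(i = i, pre_row = pi_, post_row = near,
                                     residual = sqrt(d2[near])))
  }
  if (is.null(cand)) {
    return(new_match_set(empty, pre_set$id, post_set$id, params))
  }
  cand <- cand[order(cand$residual, pre_set$id[cand$pre_row],
                     post_set$id[cand$post_row]), , drop = FALSE]
  used_pre <- logical(nrow(pre_set))
  used_post <- logical(nrow(post_set))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    a <- cand$pre_row[r]; b <- cand$post_row[r]
    if (!used_pre[a] && !used_post[b]) {
      used_pre[a] <- TRUE
      used_post[b] <- TRUE
      keep[r] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  pre_c <- pre_xyz[cand$pre_row, , drop = FALSE]
  use_subvox <- identical(params$refine, "ncc_subvoxel") &&
    all(c("tdx", "tdy", "tdz") %in% names(coarse)) &&
    !anyNA(coarse[cand$i, c("tdx", "tdy", "tdz")])
  if (use_subvox) {
    scan_post <- pre_c + as.matrix(coarse[cand$i, c("tdx", "tdy", "tdz")]) *
      matrix(vs, nrow(cand), 3, byrow = TRUE)
    disp <- transform_points(inv, scan_post) - pre_c
  } else {
    back <- transform_points(inv, post_xyz[cand$post_row, , drop = FALSE])
    disp <- back - pre_c
  }
  matches <- data.frame(
    pre_id = pre_set$id[cand$pre_row],
    post_id = post_set$id[cand$post_row],
    cdx = coarse$cdx[cand$i], cdy = coarse$cdy[cand$i], cdz = coarse$cdz[cand$i],
    dx = disp[, 1], dy = disp[, 2], dz = disp[, 3],
    residual = cand$residual,
    ncc = coarse$ncc[cand$i]
  )
  # demote gross outliers against the (coherent) displacement field
  if (is.finite(params$outlier_mad) && nrow(matches) >= 8L) {
    floor_um <- mean(vs)
    ok <- rep(TRUE, nrow(matches))
    for (col in c("dx", "dy", "dz")) {
      v <- matches[[col]]
      tol <- max(params$outlier_mad * stats::mad(v), floor_um)
      ok <- ok & abs(v - median(v)) <= tol
    }
    matches <- matches[ok, , drop = FALSE]
  }
  matches <- matches[order(matches$pre_id), , drop = FALSE]
  rownames(matches) <- NULL
  new_match_set(matches,
                setdiff(pre_set$id, matches$pre_id),
                setdiff(post_set$id, matches$post_id),
                params)
}

new_match_set <- function(matches, unmatched_pre, unmatched_post, params) {
  stopifnot(!anyDuplicated(matches$pre_id), !anyDuplicated(matches$post_id))
  structure(list(matches = matches,
                 unmatched_pre = as.integer(unmatched_pre),
                 unmatched_post = as.integer(unmatched_post),
                 params = params),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> %d matches; %d pre / %d post unmatched\n",
              nrow(x$matches), length(x$unmatched_pre), length(x$unmatched_post)))
  invisible(x)
}

#' Match sphere sets between two scans
#'
#' Convenience wrapper running [block_match()] for every pre-cure sphere and
#' then [pair_spheres()].
#'
#' @inheritParams block_match
#' @inheritParams pair_spheres
#' @return A `match_set` (see [pair_spheres()]).
#' @export
match_spheres <- function(pre, post, pre_set, post_set,
                          transform = rigid_transform(),
                          params = match_params()) {
  if (params$smooth_sigma > 0) {
    pre <- smooth_volume(pre, params$smooth_sigma)
    post <- smooth_volume(post, params$smooth_sigma)
  }
  # hoisted out of the per-sphere loop (stripping dim copies the array)
  pre_dat <- as.numeric(pre$data)
  post_dat <- as.numeric(post$data)
  pdim <- dim(pre$data)
  qdim <- dim(post$data)
  coarse <- data.frame(pre_id = pre_set$id, cdx = NA_integer_,
                       cdy = NA_integer_, cdz = NA_integer_,
                       tdx = NA_real_, tdy = NA_real_, tdz = NA_real_,
                       ncc = NA_real_)
  for (i in seq_len(nrow(pre_set))) {
    centroid <- as.numeric(pre_set[i, c("x", "y", "z")])
    pc <- pmin(pmax(as.integer(round(world_to_voxel(pre, centroid))), 0L), pdim - 1L)
    qc <- pmin(pmax(as.integer(round(world_to_voxel(post, transform_points(transform, centroid)))), 0L),
               qdim - 1L)
    r <- cpp_block_match(pre_dat, pdim, post_dat, qdim, pc, qc,
                         params$block_half_width, params$search_radius)
    if (r$status != 2L) {
      coarse[i, c("cdx", "cdy", "cdz")] <- r$disp
      coarse[i, c("tdx", "tdy", "tdz")] <- as.numeric(qc - pc) + r$subvoxel
      coarse$ncc[i] <- r$ncc
    }
  }
  pair_spheres(pre_set, post_set, coarse, transform, post$voxel_size, params)
}
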