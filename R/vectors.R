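#' Compute labelled shrinkage vectors from a match set
#'
#' One record per matched sphere: the displacement `d = (post centroid mapped
#' into the pre-cure frame) - (pre centroid)` in micrometres, its Euclidean
#' magnitude, and the signed axial component `z_component = dz`. The sign
#' convention follows the scan axis: negative values are upward movement
#' toward the light source (occlusal), positive values downward movement
#' toward the cavity floor. Unmatched spheres are excluded and counted in the
#' metadata.
#'
#' @param matchset a [match_spheres()]/[pair_spheres()] result.
#' @param pre_set,post_set the segmented sphere sets.
#' @param labels named list or vector with `group`, `sample`, `increment`.
#' @param voxel_size scan voxel size, micrometres (stored as metadata).
#' @return A data frame of class `shrinkage_field` with the vector-table
#'   columns (see [write_vector_table()]) plus `z_component`; attributes
#'   `labels`, `voxel_size`, `scale_hint` (10, the conventional glyph display
#'   scale) and `n_unmatched`.
#' @export
compute_vectors <- function(matchset, pre_set, post_set,
                            labels = list(group = "group", sample = "sample",
                                          increment = "whole"),
                            voxel_size = 16) {
  stopifnot(inherits(matchset, "match_set"))
  m <- matchset$matches
  pre_rows <- match(m$pre_id, pre_set$id)
  n <- nrow(m)
  out <- data.frame(
    sphere_id = m$pre_id,
    group = rep(as.character(labels$group), n),
    sample = rep(as.character(labels$sample), n),
    increment = rep(as.character(labels$increment), n),
    x_pre = pre_set$x[pre_rows], y_pre = pre_set$y[pre_rows],
    z_pre = pre_set$z[pre_rows],
    x_post = pre_set$x[pre_rows] + m$dx,
    y_post = pre_set$y[pre_rows] + m$dy,
    z_post = pre_set$z[pre_rows] + m$dz,
    dx = m$dx, dy = m$dy, dz = m$dz,
    magnitude = sqrt(m$dx^2 + m$dy^2 + m$dz^2),
    z_component = m$dz,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) out <- out[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  attr(out, "voxel_size") <- voxel_size
  attr(out, "scale_hint") <- 10
  attr(out, "n_unmatched") <- c(pre = length(matchset$unmatched_pre),
                                post = length(matchset$unmatched_post))
  class(out) <- c("shrinkage_field", "data.frame")
  out
}

#' Bind shrinkage fields
#'
#' Concatenates fields (e.g. successive increments of one restoration under a
#' cumulative label, or all samples of a group) into one field.
#'
#' @param ... `shrinkage_field` objects or a single list of them.
#' @param relabel optional named list overriding `group`, `sample` and/or
#'   `increment` in all records.
#' @return A `shrinkage_field`.
#' @export
bind_fields <- function(..., relabel = NULL) {
  fields <- list(...)
  if (length(fields) == 1L && !inherits(fields[[1]], "data.frame"))
    fields <- fields[[1]]
  out <- do.call(rbind, lapply(fields, as.data.frame))
  if (!is.null(relabel))
    for (nm in intersect(names(relabel), c("group", "sample", "increment")))
      out[[nm]] <- as.character(relabel[[nm]])
  attr(out, "voxel_size") <- attr(fields[[1]], "voxel_size")
  attr(out, "scale_hint") <- 10
  class(out) <- c("shrinkage_field", "data.frame")
  out
}

#' Estimate displacement measurement noise from a field's local coherence
#'
#' Composite shrinkage fields are spatially smooth, so the deviation of each
#' vector from a local linear (affine) prediction built on its nearest
#' neighbours is almost entirely measurement noise. For every record, each
#' displacement component is predicted by a leave-one-out linear regression on
#' the `k` nearest matched spheres (exact for affine fields such as uniform
#' contraction or axial drift); the residuals, scaled by their prediction
#' leverage, give a robust (MAD-based) per-axis noise variance.
#'
#' @param field a [compute_vectors()] result with at least `k + 4` records.
#' @param k neighbours used per local fit.
#' @return List: `sigma_axis_um` (per-axis noise SDs), `sigma_tot2_um2` (total
#'   displacement noise variance, the sum of the three squared SDs), `n`.
#' @export
estimate_field_noise <- function(field, k = 12) {
  n <- nrow(field)
  if (n < k + 4) stop("need at least k + 4 records to estimate field noise")
  P <- as.matrix(field[, c("x_pre", "y_pre", "z_pre")])
  D <- as.matrix(field[, c("dx", "dy", "dz")])
  res <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    d2 <- (P[, 1] - P[i, 1])^2 + (P[, 2] - P[i, 2])^2 + (P[, 3] - P[i, 3])^2
    nb <- order(d2)[2:(k + 1)]
    X <- cbind(1, P[nb, , drop = FALSE])
    XtX <- crossprod(X)
    sol <- try(solve(XtX, t(X)), silent = TRUE)
    if (inherits(sol, "try-error")) next
    x0 <- c(1, P[i, ])
    # leverage of the prediction point (residual variance is (1 + h) sigma^2)
    h <- drop(t(x0) %*% solve(XtX, x0))
    pred <- drop(x0 %*% (sol %*% D[nb, , drop = FALSE]))
    res[i, ] <- (D[i, ] - pred) / sqrt(1 + h)
  }
  sig <- apply(res, 2, function(r) stats::mad(r[is.finite(r)]))
  list(sigma_axis_um = sig, sigma_tot2_um2 = sum(sig^2), n = n)
}

#' Summarize shrinkage fields per group and increment
#'
#' Mean and sample standard deviation (n - 1 denominator) of the vector
#' magnitude and of the signed axial component, per `(group, increment)` cell
#' -- the conventional mean +/- SD shrinkage-vector table of such studies
#' (one row per group or cumulative increment). Cells with a single
#' record report `NA` standard deviations; empty cells are omitted with a
#' warning.
#'
#' The magnitude of a noisy vector is biased upward (for isotropic per-axis
#' noise `sigma_a`, roughly `|d| + sigma_a^2 / |d|`: the two transverse
#' components inflate the norm), which matters when displacements are only a
#' few times the measurement noise. With `debias = TRUE` each cell
#' additionally reports `mean_magnitude_debiased`, the mean of the
#' first-moment-matched estimator `sqrt(pmax(magnitude^2 - 2 sigma_a^2, 0))`
#' -- the 3D analogue of the standard Rician magnitude correction -- with the
#' noise variance estimated per cell by [estimate_field_noise()] (falling
#' back to the plain mean where a cell is too small to estimate noise).
#'
#' @param fields a `shrinkage_field` or list of them.
#' @param debias also report noise-debiased mean magnitudes.
#' @return Data frame: `group`, `increment`, `n`, `mean_magnitude`,
#'   `sd_magnitude`, `mean_z`, `sd_z` (+ `mean_magnitude_debiased`,
#'   `sigma_tot_um` with `debias = TRUE`).
#' @export
summarize_field <- function(fields, debias = FALSE) {
  if (inherits(fields, "data.frame")) fields <- list(fields)
  df <- do.call(rbind, lapply(fields, as.data.frame))
  if (is.null(df) || !nrow(df)) {
    warning("no records to summarize")
    return(data.frame(group = character(), increment = character(),
                      n = integer(), mean_magnitude = numeric(),
                      sd_magnitude = numeric(), mean_z = numeric(),
                      sd_z = numeric()))
  }
  key <- interaction(df$group, df$increment, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    out <- data.frame(group = sub$group[1], increment = sub$increment[1],
                      n = nrow(sub),
                      mean_magnitude = mean(sub$magnitude),
                      sd_magnitude = if (nrow(sub) > 1) sd(sub$magnitude) else NA_real_,
                      mean_z = mean(sub$z_component),
                      sd_z = if (nrow(sub) > 1) sd(sub$z_component) else NA_real_)
    if (debias) {
      s2 <- if (nrow(sub) >= 20)
        tryCatch(2 * mean(estimate_field_noise(sub)$sigma_axis_um^2),
                 error = function(e) 0)
      else 0
      out$mean_magnitude_debiased <- mean(sqrt(pmax(sub$magnitude^2 - s2, 0)))
      out$sigma_tot_um <- sqrt(1.5 * s2)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export shrinkage vectors as VTK polydata glyphs
#'
#' Writes a legacy-ASCII VTK polydata file: one point per sphere (the pre-cure
#' centroid, micrometres), a 3-component `displacement` point-data array with
#' the UNSCALED displacement vectors, a `magnitude` scalar array for colour
#' mapping, and a `glyph_scale` field-data entry carrying the display scale
#' factor (conventionally 10) so that renderers can magnify the arrows without
#' the stored data losing quantitative meaning. Zero vectors are written like
#' any other record.
#'
#' @param field a `shrinkage_field` (non-empty).
#' @param path output path (`.vtk`).
#' @param scale display scale hint written as field data (default 10).
#' @return `path`, invisibly.
#' @export
export_glyphs <- function(field, path, scale = 10) {
  if (!nrow(field)) stop("empty shrinkage field")
  n <- nrow(field)
  fmt <- function(m) apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("shrinkage vectors (um); display scale x%g stored as field data", scale),
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", n),
    fmt(as.matrix(field[, c("x_pre", "y_pre", "z_pre")])),
    sprintf("VERTICES %d %d", n, 2L * n),
    paste("1", seq_len(n) - 1L),
    sprintf("POINT_DATA %d", n),
    "VECTORS displacement double",
    fmt(as.matrix(field[, c("dx", "dy", "dz")])),
    "SCALARS magnitude double 1",
    "LOOKUP_TABLE default",
    sprintf("%.10g", field$magnitude),
    "FIELD FieldData 1",
    "glyph_scale 1 1 double",
    sprintf("%.10g", scale)
  ), con)
  invisible(path)
}

#' Read back a glyph file written by [export_glyphs()]
#'
#' @param path a `.vtk` polydata file.
#' @return List with `points` (n x 3), `displacement` (n x 3), `magnitude`
#'   (n), `scale`.
#' @export
read_glyphs <- function(path) {
  lines <- readLines(path)
  grab <- function(pattern) grep(pattern, lines)[1]
  npts <- as.integer(strsplit(lines[grab("^POINTS ")], "\\s+")[[1]][2])
  read_block <- function(start, n) {
    vals <- lapply(lines[start + seq_len(n)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    do.call(rbind, vals)
  }
  pts <- read_block(grab("^POINTS "), npts)
  vec <- read_block(grab("^VECTORS displacement"), npts)
  mag_start <- grab("^LOOKUP_TABLE default")
  mag <- as.numeric(lines[mag_start + seq_len(npts)])
  sc <- as.numeric(lines[grab("^glyph_scale ") + 1L])
  list(points = pts, displacement = vec, magnitude = mag, scale = sc)
}
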