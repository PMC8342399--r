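#' Rigid transforms
#'
#' A rigid transform maps world coordinates (micrometres) of the fixed
#' (pre-cure) frame into the moving (post-cure) frame:
#' `T(x) = R (x - center) + center + translation`, with the rotation `R` built
#' from Euler angles in degrees using the intrinsic z-y-x convention
#' (`R = Rz %*% Ry %*% Rx`). This is the convention written to all transform
#' metadata.
#'
#' @param rotation Euler angles `(rz, ry, rx)` in degrees, intrinsic z-y-x.
#' @param translation translation `(tx, ty, tz)` in micrometres.
#' @param center rotation centre in micrometres.
#' @return An object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(rotation = c(2, 0, 0), translation = c(51.2, -25.6, 12.8))
#' transform_points(tf, cbind(100, 0, 0))
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- rep_len(as.numeric(rotation), 3L)
  translation <- rep_len(as.numeric(translation), 3L)
  center <- rep_len(as.numeric(center), 3L)
  if (any(!is.finite(c(rotation, translation, center))))
    stop("rigid transform parameters must be finite")
  structure(
    list(rotation = rotation, translation = translation, center = center,
         R = euler_zyx_matrix(rotation)),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> rot (z,y,x) = (%s) deg, t = (%s) um, center = (%s) um\n",
    paste(format(x$rotation, digits = 6, trim = TRUE), collapse = ", "),
    paste(format(x$translation, digits = 6, trim = TRUE), collapse = ", "),
    paste(format(x$center, digits = 6, trim = TRUE), collapse = ", ")
  ))
  invisible(x)
}

# Rotation matrix from Euler angles (rz, ry, rx) in degrees, intrinsic z-y-x.
euler_zyx_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# Recover (rz, ry, rx) degrees from a rotation matrix (inverse of
# euler_zyx_matrix); gimbal-locked poses resolve with rz absorbing the spin.
euler_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-10) {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  } else {
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  }
  c(rz, ry, rx) * 180 / pi
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector) of world coordinates, um.
#' @return n x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(transform, points) {
  p <- rbind_coords(points)
  ctr <- matrix(transform$center, nrow(p), 3, byrow = TRUE)
  sweep((p - ctr) %*% t(transform$R) + ctr, 2, transform$translation, "+")
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` returns the transform that applies `b` first and
#' then `a` (`x -> a(b(x))`); `invert_transform(a)` returns the transform that
#' undoes `a`. Both preserve the rigid parameterisation (rotation, translation,
#' centre) exactly.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  Rab <- a$R %*% b$R
  # keep a's centre; translation chosen so the composite agrees at that centre
  t_new <- as.numeric(transform_points(a, transform_points(b, a$center))) - a$center
  tf <- rigid_transform(euler_from_matrix(Rab), t_new, a$center)
  tf$R <- Rab  # exact matrix, not round-tripped through angles
  tf
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  Rt <- t(a$R)
  tf <- rigid_transform(euler_from_matrix(Rt), -as.numeric(Rt %*% a$translation),
                        a$center)
  tf$R <- Rt
  tf
}

is_identity_transform <- function(a, tol = 1e-12) {
  max(abs(a$R - diag(3))) < tol && max(abs(a$translation)) < tol
}

# Rotation angle (degrees) of a transform's rotation part.
rotation_angle_deg <- function(a) {
  ca <- (sum(diag(a$R)) - 1) / 2
  acos(min(1, max(-1, ca))) * 180 / pi
}

# Affine (A, b) mapping output-grid voxel indices to moving-grid voxel indices
# for `out(p) = moving(T(world(p)))`, used by the C++ resampler and NCC metric.
transform_to_voxel_affine <- function(transform, out_volume, moving_volume) {
  vf <- out_volume$voxel_size
  vm <- moving_volume$voxel_size
  A <- transform$R %*% diag(vf) / matrix(vm, 3, 3)
  # world of out voxel p: of + (p + .5) vf ; moving voxel q = (T(w) - om)/vm - .5
  w0 <- out_volume$origin + 0.5 * vf
  q0 <- (as.numeric(transform$R %*% (w0 - transform$center)) + transform$center +
           transform$translation - moving_volume$origin) / vm - 0.5
  list(A = A, b = q0)
}

#' Resample a volume through a rigid transform
#'
#' Produces `out(x) = volume(T(x))` on the grid of `grid` (default: the input's
#' own grid). With the identity transform and `"linear"` interpolation the
#' input is reproduced exactly at lattice points. Mainly intended for QC
#' overlays: the analysis pipeline maps sphere coordinates through transforms
#' instead of resampling image data.
#'
#' @param volume moving [new_volume()] to be resampled.
#' @param transform [rigid_transform()] mapping output-grid world coordinates
#'   into the moving volume's world frame.
#' @param interpolation `"linear"`, `"cubic"` (Catmull-Rom) or `"nearest"`.
#' @param grid volume whose grid defines the output (defaults to `volume`).
#' @param fill value assigned to out-of-field voxels.
#' @return A [new_volume()] on the output grid.
#' @export
resample <- function(volume, transform, interpolation = c("linear", "cubic", "nearest"),
                     grid = volume, fill = 0) {
  interpolation <- match.arg(interpolation)
  method <- c(linear = 1L, cubic = 3L, nearest = 0L)[[interpolation]]
  ab <- transform_to_voxel_affine(transform, grid, volume)
  out <- cpp_resample_affine(as.numeric(volume$data), dim(volume$data),
                             dim(grid$data), ab$A, ab$b, fill, method)
  new_volume(array(out, dim(grid$data)), voxel_size = grid$voxel_size,
             origin = grid$origin, dtype = volume$dtype)
}

#' Read and write rigid transforms as JSON
#'
#' Angles are stored in degrees (intrinsic z-y-x), translations and centres in
#' micrometres, together with any registration metadata supplied.
#'
#' @param transform a [rigid_transform()].
#' @param path file path (`.json`).
#' @param metadata named list stored alongside the parameters.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns a [rigid_transform()] with a `metadata` attribute.
#' @export
write_transform <- function(transform, path, metadata = list()) {
  obj <- list(
    rotation_deg_zyx = transform$rotation,
    translation_um = transform$translation,
    center_um = transform$center,
    euler_convention = "intrinsic z-y-x",
    metadata = metadata
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- rigid_transform(obj$rotation_deg_zyx, obj$translation_um, obj$center_um)
  attr(tf, "metadata") <- obj$metadata
  tf
}
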