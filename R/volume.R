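#' 3D image volume
#'
#' A `volume` is the unit of all image I/O, registration and segmentation in
#' shrinkvec: a 3D scalar grid with explicit physical metadata. The array is
#' stored in `(x, y, z)` order with `z = 0` at the occlusal (light-source) face
#' and increasing toward the cavity floor; all modules inherit this axis
#' convention. Voxel indexing is 0-based and voxel-centred: the world
#' coordinate (micrometres) of voxel `i` along an axis is
#' `origin + (i + 0.5) * voxel_size`.
#'
#' @param data numeric 3D array, `(x, y, z)` order.
#' @param voxel_size voxel edge length(s) in micrometres; scalar or length-3.
#' @param origin world coordinate (micrometres) of the grid corner (the face of
#'   voxel `(0, 0, 0)`), length 3.
#' @param dtype storage type tag used when the volume is written to disk:
#'   `"float32"` or `"int16"`.
#' @return An object of class `volume`.
#' @examples
#' v <- new_volume(array(0, c(8, 8, 8)), voxel_size = 16)
#' voxel_to_world(v, cbind(0, 0, 0))  # centre of the corner voxel: (8, 8, 8)
#' @export
new_volume <- function(data, voxel_size, origin = c(0, 0, 0),
                       dtype = c("float32", "int16")) {
  dtype <- match.arg(dtype)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("grid must be non-empty")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be positive and finite (micrometres)")
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(origin))) stop("`origin` must be finite")
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin, dtype = dtype),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf(
    "<volume> %s voxels @ %s um, origin (%s) um, dtype %s\n",
    paste(dim(x$data), collapse = "x"),
    paste(format(x$voxel_size, trim = TRUE), collapse = "x"),
    paste(format(x$origin, trim = TRUE), collapse = ", "),
    x$dtype
  ))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "volume")

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based continuous coordinates with the centre of voxel
#' `i` at index `i` (voxel-centre convention); world coordinates are in
#' micrometres.
#'
#' @param volume a [new_volume()] object.
#' @param idx,world n x 3 matrices (or length-3 vectors) of voxel indices /
#'   world coordinates.
#' @return An n x 3 numeric matrix.
#' @export
voxel_to_world <- function(volume, idx) {
  idx <- rbind_coords(idx)
  sweep(sweep(idx + 0.5, 2, volume$voxel_size, "*"), 2, volume$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, world) {
  world <- rbind_coords(world)
  sweep(sweep(world, 2, volume$origin, "-"), 2, volume$voxel_size, "/") - 0.5
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3L)
  storage.mode(x) <- "double"
  x
}

# World coordinates of all voxel centres, as three vectors (memory-lean form).
voxel_axes_world <- function(volume) {
  d <- dim(volume$data)
  lapply(1:3, function(a) {
    volume$origin[a] + (seq_len(d[a]) - 0.5) * volume$voxel_size[a]
  })
}

# Gaussian smoothing of a volume, sigma in voxels.
smooth_volume <- function(volume, sigma_voxels) {
  if (sigma_voxels <= 0) return(volume)
  sm <- cpp_gauss3d(as.numeric(volume$data), dim(volume$data), sigma_voxels)
  volume$data <- array(sm, dim(volume$data))
  volume
}

# Block-mean downsampling by an integer factor; voxel size scales, origin is
# preserved (edges truncated when not divisible).
downsample_volume <- function(volume, factor) {
  if (factor == 1L) return(volume)
  out <- cpp_downsample(as.numeric(volume$data), dim(volume$data), as.integer(factor))
  new_volume(array(out, attr(out, "dim")),
             voxel_size = volume$voxel_size * factor,
             origin = volume$origin, dtype = volume$dtype)
}
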