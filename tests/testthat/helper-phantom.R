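# Compact phantom specifications used across test files.

# 64^3 desk phantom, small enough for sub-second generation
tiny_spec <- function(bead_count = 30, noise_sd = 0, ...) {
  phantom_spec(grid_shape = c(64, 64, 64), cavity_diameter = 560,
               cavity_depth = 448, bead_count = bead_count,
               noise_sd = noise_sd, occlusal_margin = 12 * 16, ...)
}

# uniform contraction toward the cavity floor centre
contraction_of <- function(spec, s) {
  deformation_model("uniform_contraction", center = cavity_floor_center(spec),
                    contraction_fraction = s)
}

cavity_args <- function(spec) {
  ext <- spec$grid_shape * spec$voxel_size
  list(center = c(ext[1] / 2, ext[2] / 2, spec$occlusal_margin),
       diameter = spec$cavity_diameter, depth = spec$cavity_depth)
}

tiny_cavity_mask <- function(volume, spec, margin = 2, transform = NULL) {
  ca <- cavity_args(spec)
  make_cavity_mask(volume, ca$center, ca$diameter, ca$depth, margin = margin,
                   transform = transform)
}

# nearest-truth assignment: how many measured records sit within `radius`
# of a distinct true sphere
truth_hits <- function(field, truth, radius = 16) {
  if (!nrow(field)) return(0L)
  taken <- logical(nrow(truth))
  hits <- 0L
  for (i in seq_len(nrow(field))) {
    d2 <- (truth$x_pre - field$x_pre[i])^2 + (truth$y_pre - field$y_pre[i])^2 +
      (truth$z_pre - field$z_pre[i])^2
    j <- which.min(d2)
    if (d2[j] <= radius^2 && !taken[j]) {
      taken[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

# uniform-composite block with one rendered tracer sphere (for centroid tests)
bead_block <- function(center_um, radius_um = 30, dim = c(32, 32, 32),
                       composite = 1000, bead = 400, supersampling = 4) {
  vol <- new_volume(array(composite, dim), voxel_size = 16)
  rasterize_sphere(vol, center_um, radius_um, bead, supersampling)
}
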