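#' Phantom specification
#'
#' Describes a synthetic restored-tooth phantom: a cylindrical class-I cavity
#' (axis along z) cut into a dentin cylinder, filled with one or more composite
#' layers carrying radiolucent tracer spheres, immersed in water, imaged at a
#' given voxel size with additive Gaussian scanner noise. The dentin carries a
#' smooth band-limited intensity texture so that a rigid pose offset between
#' the two scans is fully observable (a featureless cylinder would leave
#' rotation about its own axis undetermined).
#'
#' The default is a desk-scale phantom: a 160^3 grid at 16 um (2.56 mm cube)
#' with a 1.6 mm x 1.28 mm cavity, small enough for routine testing. The
#' `"full"` preset reproduces the full restoration geometry (6 mm diameter,
#' 4 mm deep cavity) on a correspondingly large grid.
#'
#' Attenuations are arbitrary scanner units ordered so that tracer spheres are
#' radiolucent relative to every composite: water 100 < bead 400 < dentin 700
#' < flowable composite 1000 (< hybrid composite 1400 where used).
#'
#' @param grid_shape voxels per axis `(x, y, z)`.
#' @param voxel_size voxel edge length, micrometres.
#' @param cavity_diameter,cavity_depth cavity cylinder, micrometres.
#' @param layers list of composite layers, each
#'   `list(label =, top_z =, bottom_z =, attenuation =)` with depths in
#'   micrometres measured from the cavity mouth downward; default one flowable
#'   layer filling the cavity. Intervals must not overlap and must lie within
#'   the cavity depth.
#' @param bead_count number of tracer spheres.
#' @param bead_diameter_range diameter range, micrometres; diameters are drawn
#'   uniformly from it.
#' @param bead_separation minimum clearance between bead surfaces,
#'   micrometres (centres are kept at least the sum of radii plus this far
#'   apart). Mixing disperses the real tracers; the clearance keeps the
#'   partial-volume footprints of neighbouring spheres separable at the
#'   scan resolution.
#' @param bead_attenuation tracer sphere attenuation (below every layer's).
#' @param water_attenuation,background_attenuation,dentin_attenuation scene
#'   attenuations (water above/around the sample, medium outside the tooth,
#'   dentin).
#' @param noise_sd standard deviation of the additive Gaussian scanner noise
#'   (attenuation units). The default 120 gives a bead contrast-to-noise ratio
#'   of 5 against the default flowable composite.
#' @param psf_sigma scanner/reconstruction point-spread width in voxels:
#'   material boundaries are rendered with a smoothstep profile of this scale
#'   instead of hard steps. Real reconstructions band-limit the image;
#'   point-sampled hard edges would quantize sub-voxel positions to the
#'   lattice.
#' @param occlusal_margin water gap above the occlusal surface, micrometres.
#' @param tooth_diameter dentin cylinder diameter, micrometres (default: grid
#'   width minus a 10-voxel margin each side).
#' @param enamel_thickness,enamel_attenuation occlusal enamel cap (its lower
#'   boundary and the dentin texture give the scans landmarks along z).
#' @param pulp_offset,pulp_semiaxes pulp chamber: a water-attenuation
#'   ellipsoid below the cavity floor, laterally offset from the tooth axis
#'   (`pulp_offset`, micrometres, x/y) with semi-axes `pulp_semiaxes`
#'   (micrometres). The off-axis chamber breaks the rotational symmetry of
#'   the tooth so that pose recovery about the cavity axis is well posed, as
#'   it is for real (asymmetric) molars. Set `pulp_semiaxes = NULL` to omit.
#' @param texture_amplitude,texture_count,texture_wavelength_range dentin
#'   texture: number of random sinusoidal components, their total standard
#'   deviation (attenuation units) and wavelength range (micrometres).
#' @param seed default random seed for [generate_phantom()].
#' @param preset `"desk"` (default) or `"full"`; presets fill geometry fields
#'   that are not given explicitly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = NULL, voxel_size = 16,
                         cavity_diameter = NULL, cavity_depth = NULL,
                         layers = NULL, bead_count = 300,
                         bead_diameter_range = c(40, 70),
                         bead_separation = 32,
                         bead_attenuation = 400,
                         water_attenuation = 100,
                         background_attenuation = 100,
                         dentin_attenuation = 700,
                         noise_sd = 120, psf_sigma = 0.6,
                         occlusal_margin = NULL, tooth_diameter = NULL,
                         enamel_thickness = 300, enamel_attenuation = 1800,
                         pulp_offset = NULL, pulp_semiaxes = NULL,
                         texture_amplitude = 120, texture_count = 8,
                         texture_wavelength_range = c(200, 800),
                         seed = 1, preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    grid_shape <- grid_shape %||% c(160, 160, 160)
    cavity_diameter <- cavity_diameter %||% 1600
    cavity_depth <- cavity_depth %||% 1280
  } else {
    grid_shape <- grid_shape %||% c(512, 512, 480)
    cavity_diameter <- cavity_diameter %||% 6000
    cavity_depth <- cavity_depth %||% 4000
  }
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  occlusal_margin <- occlusal_margin %||% (24 * voxel_size)
  tooth_diameter <- tooth_diameter %||%
    ((min(grid_shape[1:2]) - 20) * voxel_size)
  layers <- layers %||% list(list(label = "composite", top_z = 0,
                                  bottom_z = cavity_depth, attenuation = 1000))
  pulp_offset <- pulp_offset %||% (c(0.15, -0.12) * cavity_diameter)
  if (is.null(pulp_semiaxes) && !identical(pulp_semiaxes, numeric(0)))
    pulp_semiaxes <- c(0.30, 0.24, 0.22) * cavity_diameter

  spec <- structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         cavity_diameter = cavity_diameter, cavity_depth = cavity_depth,
         layers = layers, bead_count = as.integer(bead_count),
         bead_diameter_range = as.numeric(bead_diameter_range),
         bead_separation = bead_separation,
         bead_attenuation = bead_attenuation,
         water_attenuation = water_attenuation,
         background_attenuation = background_attenuation,
         dentin_attenuation = dentin_attenuation,
         noise_sd = noise_sd, psf_sigma = psf_sigma,
         occlusal_margin = occlusal_margin,
         tooth_diameter = tooth_diameter,
         enamel_thickness = enamel_thickness,
         enamel_attenuation = enamel_attenuation,
         pulp_offset = as.numeric(pulp_offset),
         pulp_semiaxes = if (length(pulp_semiaxes)) as.numeric(pulp_semiaxes),
         texture_amplitude = texture_amplitude,
         texture_count = as.integer(texture_count),
         texture_wavelength_range = as.numeric(texture_wavelength_range),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(bead_diameter_range <= 0) || any(bead_diameter_range >= cavity_diameter))
      stop("bead_diameter_range must lie within (0, cavity_diameter)")
    if (bead_diameter_range[1] > bead_diameter_range[2])
      stop("bead_diameter_range must be increasing")
    atts <- c(bead_attenuation, water_attenuation, background_attenuation,
              dentin_attenuation, vapply(layers, `[[`, 0, "attenuation"))
    if (any(atts < 0)) stop("attenuations must be non-negative")
    if (noise_sd < 0) stop("noise_sd must be non-negative")
    ivals <- t(vapply(layers, function(l) c(l$top_z, l$bottom_z), c(0, 0)))
    if (any(ivals[, 1] >= ivals[, 2]))
      stop("each layer must have top_z < bottom_z")
    if (any(ivals < 0) || any(ivals > cavity_depth))
      stop("layer intervals must lie within [0, cavity_depth]")
    o <- order(ivals[, 1])
    if (nrow(ivals) > 1 &&
        any(ivals[o, 1][-1] < ivals[o, 2][-nrow(ivals)] - 1e-9))
      stop("layer intervals must not overlap")
    # cavity plus >= 10 voxel margin must fit in the grid
    need_xy <- cavity_diameter / voxel_size + 20
    need_z <- (occlusal_margin + cavity_depth) / voxel_size + 10
    if (grid_shape[1] < need_xy || grid_shape[2] < need_xy || grid_shape[3] < need_z)
      stop("grid too small: the cavity plus a 10-voxel margin does not fit")
  })
  invisible(spec)
}

# Cavity axis (x, y) and mouth/floor z in world micrometres.
cavity_geometry <- function(spec) {
  ext <- spec$grid_shape * spec$voxel_size
  list(cx = ext[1] / 2, cy = ext[2] / 2,
       z_mouth = spec$occlusal_margin,
       z_floor = spec$occlusal_margin + spec$cavity_depth,
       radius = spec$cavity_diameter / 2,
       tooth_radius = spec$tooth_diameter / 2)
}

#' Cavity-floor centre of a phantom
#'
#' World coordinate (micrometres) of the centre of the cavity floor, the
#' natural centre for contraction-type deformation fields.
#'
#' @param spec a [phantom_spec()].
#' @return Length-3 numeric vector, micrometres.
#' @export
cavity_floor_center <- function(spec) {
  g <- cavity_geometry(spec)
  c(g$cx, g$cy, g$z_floor)
}

#' Analytic deformation fields
#'
#' Simple closed-form displacement fields applied to the composite region of a
#' phantom, standing in for physical polymerization shrinkage:
#' `"uniform_contraction"` pulls every point toward `center` by a fraction
#' `contraction_fraction` of its distance; `"axial_drift"` is a constant shift
#' along z (positive toward the cavity floor); `"swirl"` rotates points about
#' the vertical axis through `center` by `swirl_angle` degrees per millimetre
#' of radius; `"composite_sum"` adds the fields in `parts`; `"none"` is the
#' zero field.
#'
#' @param kind one of `"none"`, `"uniform_contraction"`, `"axial_drift"`,
#'   `"swirl"`, `"composite_sum"`.
#' @param center field centre `(x, y, z)`, micrometres.
#' @param contraction_fraction dimensionless contraction fraction `s`.
#' @param axial_shift signed z shift, micrometres (+ toward the cavity floor).
#' @param swirl_angle degrees of rotation per millimetre of radius.
#' @param parts list of `deformation_model` objects (for `"composite_sum"`).
#' @return An object of class `deformation_model`.
#' @examples
#' m <- deformation_model("uniform_contraction", center = c(0, 0, 0),
#'                        contraction_fraction = 0.01)
#' evaluate_deformation(cbind(100, 0, 0), m)  # (-1, 0, 0)
#' @export
deformation_model <- function(kind = c("none", "uniform_contraction",
                                       "axial_drift", "swirl", "composite_sum"),
                              center = c(0, 0, 0), contraction_fraction = 0,
                              axial_shift = 0, swirl_angle = 0, parts = list()) {
  if (length(kind) != 1L || !kind %in% c("none", "uniform_contraction",
                                         "axial_drift", "swirl", "composite_sum"))
    stop("unknown deformation kind: ", paste(kind, collapse = ", "))
  if (kind == "composite_sum") {
    if (!length(parts) || !all(vapply(parts, inherits, TRUE, "deformation_model")))
      stop("composite_sum requires a non-empty list of deformation models in `parts`")
  }
  structure(
    list(kind = kind, center = rep_len(as.numeric(center), 3L),
         contraction_fraction = contraction_fraction,
         axial_shift = axial_shift, swirl_angle = swirl_angle, parts = parts),
    class = "deformation_model"
  )
}

#' Evaluate a deformation field
#'
#' @param points n x 3 matrix (or length-3 vector) of world coordinates, um.
#' @param model a [deformation_model()].
#' @return n x 3 matrix of displacements `(dx, dy, dz)`, micrometres.
#' @export
evaluate_deformation <- function(points, model) {
  p <- rbind_coords(points)
  n <- nrow(p)
  out <- switch(
    model$kind,
    none = matrix(0, n, 3),
    uniform_contraction = {
      ctr <- matrix(model$center, n, 3, byrow = TRUE)
      -model$contraction_fraction * (p - ctr)
    },
    axial_drift = cbind(rep(0, n), rep(0, n), rep(model$axial_shift, n)),
    swirl = {
      dx <- p[, 1] - model$center[1]
      dy <- p[, 2] - model$center[2]
      r_mm <- sqrt(dx^2 + dy^2) / 1000
      th <- model$swirl_angle * r_mm * pi / 180
      cbind(dx * (cos(th) - 1) - dy * sin(th),
            dx * sin(th) + dy * (cos(th) - 1),
            rep(0, n))
    },
    composite_sum = Reduce(`+`, lapply(model$parts, function(m)
      evaluate_deformation(p, m))),
    stop("unknown deformation kind: ", model$kind)
  )
  if (any(!is.finite(out))) stop("deformation field is non-finite")
  dimnames(out) <- list(NULL, c("dx", "dy", "dz"))
  out
}

# Inverse of the deformation map x -> x + u(x) by fixed-point iteration
# p <- y - u(p); converges geometrically for the small smooth fields used here.
invert_deformation <- function(points, model, iterations = 8L) {
  y <- rbind_coords(points)
  p <- y
  for (i in seq_len(iterations)) p <- y - evaluate_deformation(p, model)
  p
}

#' Render a sphere into a volume
#'
#' Anti-aliased partial-volume rendering: each voxel's value is blended toward
#' `attenuation` by the fraction of the voxel covered by the sphere, estimated
#' by `supersampling`^3 sub-voxel sampling of boundary voxels. Voxels fully
#' outside the sphere are untouched; a sphere entirely outside the grid
#' triggers a warning and leaves the volume unchanged.
#'
#' @param volume a [new_volume()].
#' @param center sphere centre, world coordinates (micrometres).
#' @param radius sphere radius, micrometres (> 0).
#' @param attenuation value blended in where the sphere covers the grid.
#' @param supersampling sub-samples per axis for boundary voxels (>= 1).
#' @return The modified [new_volume()].
#' @export
rasterize_sphere <- function(volume, center, radius, attenuation,
                             supersampling = 3L) {
  if (radius <= 0) stop("radius must be > 0")
  supersampling <- as.integer(supersampling)
  if (supersampling < 1L) stop("supersampling must be >= 1")
  d <- dim(volume$data)
  buf <- volume$data
  dim(buf) <- NULL  # forces a private copy; C++ writes in place
  cv <- world_to_voxel(volume, center)
  touched <- cpp_rasterize_spheres(
    buf, d, cv, radius / mean(volume$voxel_size),
    as.numeric(attenuation), supersampling)
  if (touched == 0L)
    warning("sphere entirely outside the grid; volume unchanged")
  volume$data <- array(buf, d)
  volume
}

#' Generate a pre/post-cure phantom scan pair with ground truth
#'
#' Builds the uncured ("pre") scan of the phantom described by `spec`, then the
#' cured ("post") scan in which every tracer sphere and the composite region
#' have moved by the analytic `deformation` field, the whole scene is rigidly
#' re-posed by `rigid_pose` (emulating sample repositioning between the two
#' physical scans), and an independent scanner-noise realisation is added.
#' Equal `(spec, deformation, rigid_pose, seed)` give bit-identical outputs.
#'
#' Sphere centres are sampled uniformly in the composite region, rejected until
#' no two spheres are closer than the sum of their radii (at most 10,000
#' attempts per sphere). The composite region deforms with the same field as
#' the spheres (to first order in the field's gradient); dentin and water are
#' static, and space vacated by the shrinking composite is filled with water.
#'
#' @param spec a [phantom_spec()].
#' @param deformation a [deformation_model()] applied to the composite.
#' @param rigid_pose a [rigid_transform()] mapping pre-scan (material) world
#'   coordinates to post-scan world coordinates.
#' @param seed integer seed (defaults to `spec$seed`).
#' @param supersampling sphere-rendering anti-aliasing level.
#' @return An object of class `phantom`: a list with elements `pre` and `post`
#'   ([new_volume()] pair), `truth` (data frame: `id`, `x_pre`, `y_pre`,
#'   `z_pre`, `x_post`, `y_post`, `z_post`, `dx`, `dy`, `dz`, `radius_um`;
#'   post centres are in the material frame, before `rigid_pose`), plus
#'   `rigid_pose`, `deformation`, `spec` and `seed`. The truth satisfies
#'   `(dx, dy, dz) = evaluate_deformation(pre centre)` exactly.
#' @export
generate_phantom <- function(spec, deformation = deformation_model("none"),
                             rigid_pose = rigid_transform(), seed = spec$seed,
                             supersampling = 3L) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(deformation, "deformation_model"),
            inherits(rigid_pose, "rigid_transform"))
  local_seed(seed, {
    texture <- draw_texture(spec)
    beads <- place_beads(spec)
    u <- evaluate_deformation(beads$centers, deformation)
    centers_post <- beads$centers + u

    pre_vals <- scene_values(spec, pose = NULL, deformation = NULL,
                             texture = texture)
    post_vals <- scene_values(spec, pose = rigid_pose, deformation = deformation,
                              texture = texture)

    grid <- new_volume(array(0, spec$grid_shape), spec$voxel_size)
    atts <- rep(spec$bead_attenuation, nrow(beads$centers))
    cpp_rasterize_spheres(pre_vals, spec$grid_shape,
                          world_to_voxel(grid, beads$centers),
                          beads$radii / mean(spec$voxel_size), atts,
                          as.integer(supersampling))
    cpp_rasterize_spheres(post_vals, spec$grid_shape,
                          world_to_voxel(grid, transform_points(rigid_pose, centers_post)),
                          beads$radii / mean(spec$voxel_size), atts,
                          as.integer(supersampling))
    if (spec$noise_sd > 0) {
      n <- length(pre_vals)
      pre_vals <- pre_vals + rnorm(n, 0, spec$noise_sd)
      post_vals <- post_vals + rnorm(n, 0, spec$noise_sd)
    }

    truth <- data.frame(
      id = seq_len(nrow(beads$centers)),
      x_pre = beads$centers[, 1], y_pre = beads$centers[, 2],
      z_pre = beads$centers[, 3],
      x_post = centers_post[, 1], y_post = centers_post[, 2],
      z_post = centers_post[, 3],
      dx = u[, 1], dy = u[, 2], dz = u[, 3],
      radius_um = beads$radii
    )
    structure(
      list(pre = new_volume(array(pre_vals, spec$grid_shape), spec$voxel_size),
           post = new_volume(array(post_vals, spec$grid_shape), spec$voxel_size),
           truth = truth, rigid_pose = rigid_pose, deformation = deformation,
           spec = spec, seed = as.integer(seed)),
      class = "phantom"
    )
  })
}

# World centre of the pulp chamber ellipsoid.
pulp_center <- function(spec, g = cavity_geometry(spec)) {
  c(g$cx + spec$pulp_offset[1], g$cy + spec$pulp_offset[2],
    g$z_floor + 0.1 * spec$cavity_depth + spec$pulp_semiaxes[3])
}

# Random band-limited dentin texture parameters.
draw_texture <- function(spec) {
  k <- spec$texture_count
  if (k == 0L || spec$texture_amplitude <= 0)
    return(list(k = matrix(0, 0, 3), phase = numeric(0), amp = numeric(0)))
  # uniform random directions
  z <- runif(k, -1, 1)
  th <- runif(k, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(th), r * sin(th), z)
  wl <- runif(k, spec$texture_wavelength_range[1], spec$texture_wavelength_range[2])
  list(k = dirs * (2 * pi / wl), phase = runif(k, 0, 2 * pi),
       amp = rep(spec$texture_amplitude * sqrt(2 / k), k))
}

texture_values <- function(texture, pts) {
  if (nrow(texture$k) == 0L) return(numeric(nrow(pts)))
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(texture$k))) {
    out <- out + texture$amp[i] *
      sin(pts %*% texture$k[i, ] + texture$phase[i])
  }
  as.numeric(out)
}

# Rejection-sample non-overlapping bead centres and radii inside the composite.
place_beads <- function(spec, max_attempts = 10000L) {
  g <- cavity_geometry(spec)
  n <- spec$bead_count
  radii <- runif(n, spec$bead_diameter_range[1], spec$bead_diameter_range[2]) / 2
  clear <- spec$voxel_size  # wall clearance so spheres stay fully in composite
  centers <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      rmax <- g$radius - radii[i] - clear
      if (rmax <= 0) break
      rr <- rmax * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      z <- runif(1, g$z_mouth + radii[i] + clear, g$z_floor - radii[i] - clear)
      cand <- c(g$cx + rr * cos(th), g$cy + rr * sin(th), z)
      if (i > 1L) {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
          (prev[, 3] - cand[3])^2
        if (any(d2 < (radii[seq_len(i - 1L)] + radii[i] + spec$bead_separation)^2)) next
      }
      centers[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("bead placement budget exhausted: placed %d of %d beads",
                   i - 1L, n))
  }
  list(centers = centers, radii = radii)
}

# Noise-free scene values (numeric vector in column-major (x,y,z) order).
# pose: rigid transform pre -> post frame (NULL for the pre scan);
# deformation applied to the composite region (NULL for none).
#
# Material boundaries are rendered with an analytic smoothstep profile of
# half-width ~ psf_sigma voxels over the signed distance to each surface:
# point-sampling hard indicator functions would quantize sub-voxel edge (and
# hence pose/deformation) positions to the voxel lattice, whereas a real
# reconstruction band-limits the image. Evaluated slice by slice to keep
# temporaries small.
scene_values <- function(spec, pose = NULL, deformation = NULL, texture) {
  d <- spec$grid_shape
  g <- cavity_geometry(spec)
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * spec$voxel_size)
  nxy <- d[1] * d[2]
  Xxy <- rep(ax[[1]], times = d[2])
  Yxy <- rep(ax[[2]], each = d[1])
  has_pose <- !is.null(pose) && !is_identity_transform(pose)
  inv_pose <- if (has_pose) invert_transform(pose) else NULL
  has_def <- !is.null(deformation) && deformation$kind != "none"
  nl <- length(spec$layers)
  H <- 1.5 * spec$psf_sigma * spec$voxel_size  # edge half-width, um
  soft <- if (H > 0) {
    function(dst) {
      s <- pmin(pmax(dst / (2 * H) + 0.5, 0), 1)
      s * s * (3 - 2 * s)
    }
  } else {
    function(dst) as.numeric(dst > 0)
  }
  mix <- function(base, top, wgt) base + (top - base) * wgt
  have_pulp <- !is.null(spec$pulp_semiaxes)
  if (have_pulp) {
    pc <- pulp_center(spec, g)
    pa <- spec$pulp_semiaxes
  }
  val <- numeric(prod(d))
  for (k in seq_len(d[3])) {
    if (has_pose) {
      P <- transform_points(inv_pose, cbind(Xxy, Yxy, ax[[3]][k]))
      X <- P[, 1]; Y <- P[, 2]; Z <- P[, 3]
    } else {
      X <- Xxy; Y <- Yxy; Z <- rep(ax[[3]][k], nxy)
    }
    r <- sqrt((X - g$cx)^2 + (Y - g$cy)^2)
    dz_occ <- Z - g$z_mouth  # depth below the occlusal surface

    # water everywhere, holder medium outside the tooth radius
    sl <- mix(rep(spec$water_attenuation, nxy), spec$background_attenuation,
              soft(r - g$tooth_radius))
    # dentin (textured) inside the tooth
    w_tooth <- soft(pmin(g$tooth_radius - r, dz_occ))
    tex_idx <- which(w_tooth > 0.01)
    dent_val <- rep(spec$dentin_attenuation, nxy)
    if (length(tex_idx))
      dent_val[tex_idx] <- dent_val[tex_idx] +
        texture_values(texture, cbind(X[tex_idx], Y[tex_idx], Z[tex_idx]))
    sl <- mix(sl, dent_val, w_tooth)
    # occlusal enamel cap
    if (spec$enamel_thickness > 0) {
      w_en <- soft(pmin(g$tooth_radius - r, dz_occ,
                        spec$enamel_thickness - dz_occ))
      sl <- mix(sl, spec$enamel_attenuation, w_en)
    }
    # pulp chamber (approximate signed distance to the ellipsoid)
    if (have_pulp) {
      q <- sqrt(((X - pc[1]) / pa[1])^2 + ((Y - pc[2]) / pa[2])^2 +
                  ((Z - pc[3]) / pa[3])^2)
      sl <- mix(sl, spec$water_attenuation, soft((1 - q) * min(pa)))
    }
    # carve the cavity (static hole in the tooth)
    w_cav <- soft(pmin(g$radius - r, dz_occ, g$z_floor - Z))
    sl <- mix(sl, spec$water_attenuation, w_cav)
    # composite layers, rendered at their (deformed) material positions
    cav <- which(w_cav > 0.001)
    if (length(cav)) {
      p <- cbind(X[cav], Y[cav], Z[cav])
      if (has_def) p <- invert_deformation(p, deformation)
      rp <- sqrt((p[, 1] - g$cx)^2 + (p[, 2] - g$cy)^2)
      rel <- p[, 3] - g$z_mouth
      for (li in seq_len(nl)) {
        l <- spec$layers[[li]]
        w_l <- soft(pmin(g$radius - rp, rel - l$top_z, l$bottom_z - rel))
        sl[cav] <- mix(sl[cav], l$attenuation, w_l)
      }
    }
    val[(k - 1) * nxy + seq_len(nxy)] <- sl
  }
  val
}

#' Write a phantom to disk
#'
#' Writes `pre` and `post` volumes (MetaImage by default), the ground-truth
#' table `truth.csv` and a JSON provenance sidecar with the seed, pose,
#' deformation and specification parameters.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @param format volume format passed to [write_volume()].
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("metaimage", "nifti", "tiff_stack")) {
  format <- match.arg(format)
  ext <- c(metaimage = ".mha", nifti = ".nii", tiff_stack = ".tif")[[format]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(phantom$pre, file.path(dir, paste0("pre", ext)), format = format)
  write_volume(phantom$post, file.path(dir, paste0("post", ext)), format = format)
  write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  prov <- list(
    tool = paste0("shrinkvec ", as.character(packageVersion("shrinkvec"))),
    seed = phantom$seed,
    rigid_pose = phantom$rigid_pose[c("rotation", "translation", "center")],
    deformation = phantom$deformation[c("kind", "center", "contraction_fraction",
                                        "axial_shift", "swirl_angle")],
    spec = phantom$spec[setdiff(names(phantom$spec), "layers")],
    layers = phantom$spec$layers
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
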