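#' Read a study configuration
#'
#' YAML configuration driving [run_pipeline()]. Top-level keys:
#' \describe{
#'   \item{voxel_size}{micrometres (required unless volumes carry metadata).}
#'   \item{cavity}{`center: [x, y, z]`, `diameter`, `depth` (micrometres).}
#'   \item{seed}{master seed; per-stage seeds are derived deterministically.}
#'   \item{output_dir}{where results are written.}
#'   \item{groups}{list of `{name, samples}`; each sample is
#'     `{name, increments}` and each increment `{label, pre, post}` with file
#'     paths, or `{label, simulate: {...}}` describing a phantom to generate
#'     (fields of [phantom_spec()] plus `contraction_fraction`, optional
#'     `pose_translation` (um) / `pose_rotation` (deg)).}
#'   \item{registration, segmentation, matching}{optional parameter sections
#'     forwarded to [register_params()], [segmentation_params()],
#'     [match_params()].}
#' }
#' Referenced files must exist; group/sample/increment labels must be unique.
#'
#' @param path YAML file.
#' @return A validated config list of class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_study_config(cfg, base_dir = dirname(path))
}

#' @rdname read_study_config
#' @param config a config list (as from YAML).
#' @param base_dir directory for resolving relative paths.
#' @export
validate_study_config <- function(config, base_dir = ".") {
  if (is.null(config$groups) || !length(config$groups))
    stop("config needs a non-empty `groups` list")
  labels <- character()
  for (g in config$groups) {
    if (is.null(g$name)) stop("every group needs a `name`")
    for (s in g$samples) {
      if (is.null(s$name)) stop("every sample needs a `name`")
      for (inc in s$increments) {
        if (is.null(inc$label)) stop("every increment needs a `label`")
        key <- paste(g$name, s$name, inc$label, sep = "/")
        if (key %in% labels) stop("duplicate label: ", key)
        labels <- c(labels, key)
        if (is.null(inc$simulate)) {
          for (f in c(inc$pre, inc$post)) {
            fp <- if (file.exists(f)) f else file.path(base_dir, f)
            if (!file.exists(fp)) stop("missing scan file: ", f)
          }
        }
      }
    }
  }
  config$base_dir <- base_dir
  class(config) <- c("study_config", "list")
  config
}

# Deterministic per-stage seed derived from the master seed and a stage tag.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full shrinkage-vector pipeline
#'
#' For every scan pair (one per increment of each sample): load or simulate
#' the pre/post volumes, register the post scan rigidly onto the pre scan on
#' static tooth structure, segment tracer spheres in both scans, match them by
#' block matching with centroid gating, and compute labelled shrinkage
#' vectors. Per-pair vector tables and glyph files, per-(group, increment)
#' summaries, group statistics (ANOVA + Tamhane T2 with letters, on both
#' magnitudes and axial components) and a JSON manifest (config hash, seeds,
#' per-stage counts) are written to the output directory. Re-running with an
#' identical config and seed reproduces identical outputs.
#'
#' @param config a `study_config` (list or path to YAML).
#' @param output_dir overrides `config$output_dir`.
#' @param verbose print per-stage progress and sphere counts.
#' @return Invisibly, a list with `fields` (per scan-pair shrinkage fields),
#'   `summary`, `stats` and `manifest`.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- read_study_config(config)
  if (!inherits(config, "study_config"))
    config <- validate_study_config(config)
  out_dir <- output_dir %||% config$output_dir %||% stop("no output_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- config$seed %||% 1L
  say <- function(...) if (verbose) message(sprintf(...))

  seg_par <- do.call(segmentation_params, config$segmentation %||% list())
  mat_par <- do.call(match_params, config$matching %||% list())

  fields <- list()
  counts <- list()
  for (g in config$groups) {
    for (s in g$samples) {
      for (inc in s$increments) {
        tag <- paste(g$name, s$name, inc$label, sep = "/")
        say("[%s] loading scan pair", tag)
        pair <- load_scan_pair(inc, config, derive_seed(master_seed, tag))
        vs <- pair$pre$voxel_size
        cav <- pair$cavity

        say("[%s] rigid registration", tag)
        reg_cfg <- config$registration %||% list()
        irange <- reg_cfg$intensity_range %||% pair$intensity_range
        reg_cfg$intensity_range <- NULL
        reg_mask <- registration_mask(pair$pre, cav$center, cav$diameter,
                                      cav$depth, dilate_voxels = 3,
                                      intensity_range = irange)
        reg <- register_rigid(pair$pre, pair$post, reg_mask,
                              do.call(register_params, reg_cfg))
        tf <- reg$transform

        say("[%s] sphere segmentation", tag)
        mask_pre <- make_cavity_mask(pair$pre, cav$center, cav$diameter,
                                     cav$depth, margin = 2)
        mask_post <- make_cavity_mask(pair$post, cav$center, cav$diameter,
                                      cav$depth, margin = 2, transform = tf)
        pre_set <- segment_spheres(pair$pre, mask_pre, seg_par)
        post_set <- segment_spheres(pair$post, mask_post, seg_par)
        say("[%s] spheres: %d pre, %d post", tag, nrow(pre_set), nrow(post_set))

        say("[%s] block matching", tag)
        ms <- match_spheres(pair$pre, pair$post, pre_set, post_set, tf, mat_par)
        n_un <- length(ms$unmatched_pre)
        if (n_un > 0.2 * max(1L, nrow(pre_set)))
          warning(sprintf("[%s] %d of %d pre spheres unmatched", tag, n_un,
                          nrow(pre_set)))
        say("[%s] matched %d spheres (%d pre unmatched)", tag,
            nrow(ms$matches), n_un)

        fld <- compute_vectors(ms, pre_set, post_set,
                               labels = list(group = g$name, sample = s$name,
                                             increment = inc$label),
                               voxel_size = vs[1])
        safe <- gsub("[^A-Za-z0-9_.-]", "_", tag)
        write_vector_table(as.data.frame(fld)[, vector_table_columns],
                           file.path(out_dir, paste0(safe, "_vectors.csv")))
        if (nrow(fld))
          export_glyphs(fld, file.path(out_dir, paste0(safe, "_glyphs.vtk")))
        fields[[tag]] <- fld
        counts[[tag]] <- list(
          spheres_pre = nrow(pre_set), spheres_post = nrow(post_set),
          matched = nrow(ms$matches), unmatched_pre = n_un,
          unmatched_post = length(ms$unmatched_post),
          registration_similarity = reg$final_similarity)
      }
    }
  }

  summary_df <- summarize_field(fields)
  write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)

  stats_out <- list()
  all_df <- do.call(rbind, lapply(fields, as.data.frame))
  key <- paste(all_df$group, all_df$increment, sep = ":")
  for (measure in c("magnitude", "z_component")) {
    gl <- split(all_df[[measure]], key)
    gl <- gl[vapply(gl, length, 0L) >= 2L]
    if (length(gl) >= 2L) {
      an <- one_way_anova(gl)
      th <- tamhane_t2(gl)
      stats_out[[measure]] <- list(anova = an, tamhane = th)
      write.csv(th$pairs,
                file.path(out_dir, paste0("tamhane_", measure, ".csv")),
                row.names = FALSE)
    }
  }
  writeLines(render_stats_report(summary_df, stats_out),
             file.path(out_dir, "stats_report.txt"))

  manifest <- list(
    tool = paste0("shrinkvec ", as.character(packageVersion("shrinkvec"))),
    seed = master_seed,
    config_hash = config_hash(config),
    pairs = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(fields = fields, summary = summary_df, stats = stats_out,
                 manifest = manifest))
}

config_hash <- function(config) {
  config$base_dir <- NULL
  s <- paste(deparse(config[sort(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997 + 1)) %% 4294967296)
}

load_scan_pair <- function(inc, config, seed) {
  if (!is.null(inc$simulate)) {
    sim <- inc$simulate
    spec_args <- sim[intersect(names(sim), names(formals(phantom_spec)))]
    spec <- do.call(phantom_spec, spec_args)
    defo <- deformation_model("uniform_contraction",
                              center = cavity_floor_center(spec),
                              contraction_fraction = sim$contraction_fraction %||% 0.01)
    pose <- rigid_transform(
      rotation = sim$pose_rotation %||% c(0, 0, 0),
      translation = sim$pose_translation %||% c(0, 0, 0),
      center = spec$grid_shape * spec$voxel_size / 2)
    ph <- generate_phantom(spec, defo, pose, seed = sim$seed %||% seed)
    g <- cavity_geometry(spec)
    list(pre = ph$pre, post = ph$post, truth = ph$truth,
         cavity = list(center = c(g$cx, g$cy, g$z_mouth),
                       diameter = spec$cavity_diameter,
                       depth = spec$cavity_depth),
         intensity_range = c((spec$water_attenuation +
                                spec$dentin_attenuation) / 2, Inf))
  } else {
    resolve <- function(f) if (file.exists(f)) f else file.path(config$base_dir, f)
    vs <- config$voxel_size
    pre <- read_volume(resolve(inc$pre), voxel_size = vs)
    post <- read_volume(resolve(inc$post), voxel_size = vs)
    if (max(abs(pre$voxel_size - post$voxel_size)) > 1e-9)
      stop("pre and post scans disagree on voxel size")
    cav <- config$cavity %||% stop("config needs a `cavity` section for file input")
    list(pre = pre, post = post, truth = NULL,
         cavity = list(center = as.numeric(cav$center), diameter = cav$diameter,
                       depth = cav$depth))
  }
}

render_stats_report <- function(summary_df, stats_out) {
  fmt_cell <- function(m, s, lt) {
    sprintf("%6.1f +/- %5.1f (%s)", m, if (is.na(s)) 0 else s, lt)
  }
  out <- c("Shrinkage vectors (mean +/- SD; um)", "")
  key <- paste(summary_df$group, summary_df$increment, sep = ":")
  get_lt <- function(lts, k) {
    v <- unname(lts[k])
    if (!length(v) || is.na(v)) "-" else v
  }
  lt_mag <- stats_out$magnitude$tamhane$letters
  lt_z <- stats_out$z_component$tamhane$letters
  for (i in seq_len(nrow(summary_df))) {
    k <- key[i]
    out <- c(out, sprintf(
      "%-30s n=%6d  |d| %s   dz %s", k, summary_df$n[i],
      fmt_cell(summary_df$mean_magnitude[i], summary_df$sd_magnitude[i],
               get_lt(lt_mag, k)),
      fmt_cell(summary_df$mean_z[i], summary_df$sd_z[i], get_lt(lt_z, k))))
  }
  for (measure in names(stats_out)) {
    an <- stats_out[[measure]]$anova
    out <- c(out, "", sprintf(
      "one-way ANOVA on %s: F = %.3f; Df = %d,%d; p %s", measure, an$F,
      an$df_between, an$df_within,
      if (an$p < 0.001) "< 0.001" else sprintf("= %.3f", an$p)))
  }
  out
}
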