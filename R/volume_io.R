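#' Read a 3D volume
#'
#' Supported formats: multi-page TIFF stacks (`.tif`/`.tiff`), MetaImage
#' (`.mha` with embedded data, or `.mhd` + raw file) and NIfTI-1
#' (`.nii`/`.nii.gz`). Data are returned in the package's `(x, y, z)` axis
#' order. MetaImage and NIfTI spacings are stored in millimetres on disk and
#' converted to micrometres; TIFF carries no spacing, so `voxel_size` must be
#' given (or be recoverable from a provenance sidecar written by
#' [write_volume()]).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tiff_stack"`, `"metaimage"` or
#'   `"nifti"`.
#' @param voxel_size voxel size override in micrometres (required for TIFF
#'   without a sidecar; overrides file metadata elsewhere).
#' @return A [new_volume()].
#' @export
read_volume <- function(path, format = c("auto", "tiff_stack", "metaimage", "nifti"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file not found: ", path)
  side <- read_sidecar(path)
  vol <- switch(format,
    tiff_stack = read_tiff_stack(path, voxel_size %||% side$voxel_size),
    metaimage = read_metaimage(path),
    nifti = read_nifti_volume(path),
    stop("unknown format: ", format)
  )
  if (!is.null(voxel_size)) vol$voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (!is.null(side$origin) && format == "tiff_stack")
    vol$origin <- as.numeric(side$origin)
  vol
}

#' Write a 3D volume
#'
#' Writes the volume in the chosen format plus a JSON provenance sidecar
#' (`<path>.json`) recording tool version, voxel size, origin, dtype and any
#' extra metadata. `"int16"` volumes are rounded and clamped to `[0, 65535]`
#' for TIFF (stored as unsigned 16-bit) and to signed 16-bit for MetaImage and
#' NIfTI; round-trips are lossless at the declared dtype.
#'
#' @param volume a [new_volume()].
#' @param path output path; extension selects the format under `"auto"`.
#' @param format see [read_volume()].
#' @param metadata named list merged into the provenance sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("auto", "tiff_stack", "metaimage", "nifti"),
                         metadata = list()) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    tiff_stack = write_tiff_stack(volume, path),
    metaimage = write_metaimage(volume, path),
    nifti = write_nifti_volume(volume, path),
    stop("unknown format: ", format)
  )
  write_sidecar(volume, path, metadata)
  invisible(path)
}

guess_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.(tif|tiff)$", low)) return("tiff_stack")
  if (grepl("\\.(mha|mhd)$", low)) return("metaimage")
  if (grepl("\\.(nii|nii\\.gz)$", low)) return("nifti")
  stop("cannot infer volume format from extension: ", path)
}

write_sidecar <- function(volume, path, metadata = list()) {
  obj <- c(list(
    tool = paste0("shrinkvec ", as.character(packageVersion("shrinkvec"))),
    voxel_size = volume$voxel_size,
    origin = volume$origin,
    dtype = volume$dtype,
    dim = dim(volume$data)
  ), metadata)
  jsonlite::write_json(obj, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

# ---- TIFF stacks ----------------------------------------------------------

read_tiff_stack <- function(path, voxel_size) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!length(pages)) stop("empty TIFF stack: ", path)
  dims <- vapply(pages, function(p) dim(p)[1:2], c(0L, 0L))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad))
    stop(sprintf("inconsistent slice shapes in %s: slice %d is %dx%d, expected %dx%d",
                 path, bad[1], dims[1, bad[1]], dims[2, bad[1]],
                 dims[1, 1], dims[2, 1]))
  if (is.null(voxel_size))
    stop("TIFF carries no voxel size; supply `voxel_size` (micrometres)")
  # each page is row-major (row = y, col = x); build (x, y, z)
  nz <- length(pages)
  arr <- array(0, c(dims[2, 1], dims[1, 1], nz))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  # stored as [0,1] fractions of 65535
  arr <- round(arr * 65535)
  new_volume(arr, voxel_size = voxel_size, dtype = "int16")
}

write_tiff_stack <- function(volume, path) {
  vals <- pmin(pmax(round(volume$data), 0), 65535)
  pages <- lapply(seq_len(dim(vals)[3]), function(k) t(vals[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

# ---- MetaImage (.mha / .mhd + .raw) ---------------------------------------
# Minimal MetaImage reader/writer (keyword = value header; little-endian raw
# data, MET_SHORT or MET_FLOAT). No R package on this stack speaks the format.

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  if (ndims != 3L) stop("only 3D MetaImage volumes are supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing_mm <- as.numeric(strsplit(hdr$ElementSpacing %||% hdr$ElementSize %||% "",
                                    "\\s+")[[1]])
  if (!length(spacing_mm) || any(is.na(spacing_mm)))
    stop("MetaImage is missing ElementSpacing: ", path)
  offset_mm <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                                   "\\s+")[[1]])
  et <- hdr$ElementType %||% "MET_SHORT"
  msb <- tolower(hdr$ElementByteOrderMSB %||% hdr$BinaryDataByteOrderMSB %||% "false")
  endian <- if (msb == "true") "big" else "little"
  n <- prod(d)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path)) stop("MetaImage raw file not found: ", raw_path)
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- switch(et,
    MET_SHORT = readBin(raw_con, "integer", n = n, size = 2L, signed = TRUE,
                        endian = endian),
    MET_USHORT = readBin(raw_con, "integer", n = n, size = 2L, signed = FALSE,
                         endian = endian),
    MET_FLOAT = readBin(raw_con, "double", n = n, size = 4L, endian = endian),
    MET_DOUBLE = readBin(raw_con, "double", n = n, size = 8L, endian = endian),
    stop("unsupported MetaImage ElementType: ", et)
  )
  if (length(vals) != n) stop("MetaImage data shorter than DimSize implies: ", path)
  dtype <- if (et %in% c("MET_SHORT", "MET_USHORT")) "int16" else "float32"
  new_volume(array(as.numeric(vals), d), voxel_size = spacing_mm * 1000,
             origin = offset_mm * 1000, dtype = dtype)
}

write_metaimage <- function(volume, path) {
  is_mhd <- grepl("\\.mhd$", tolower(path))
  et <- if (volume$dtype == "int16") "MET_SHORT" else "MET_FLOAT"
  datafile <- if (is_mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
              else "LOCAL"
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(volume$data), collapse = " ")),
    paste("ElementSpacing =", paste(format(volume$voxel_size / 1000, digits = 15,
                                           scientific = FALSE, trim = TRUE),
                                    collapse = " ")),
    paste("Offset =", paste(format(volume$origin / 1000, digits = 15,
                                   scientific = FALSE, trim = TRUE),
                            collapse = " ")),
    paste("ElementType =", et),
    paste("ElementDataFile =", datafile)
  )
  con <- file(path, "wb")
  writeLines(hdr, con)
  write_raw_payload <- function(con2) {
    if (volume$dtype == "int16") {
      vals <- as.integer(pmin(pmax(round(volume$data), -32768), 32767))
      writeBin(vals, con2, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(volume$data), con2, size = 4L, endian = "little")
    }
  }
  if (is_mhd) {
    close(con)
    rcon <- file(file.path(dirname(path), datafile), "wb")
    write_raw_payload(rcon)
    close(rcon)
  } else {
    write_raw_payload(con)
    close(con)
  }
  invisible(path)
}

# ---- NIfTI ----------------------------------------------------------------

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (!length(pd) || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI is missing positive pixel dimensions: ", path)
  code <- RNifti::niftiHeader(img)$datatype
  dtype <- if (code %in% c(4L, 8L, 256L, 512L)) "int16" else "float32"
  new_volume(array(as.numeric(img), dim(img)[1:3]),
             voxel_size = pd[1:3] * 1000, dtype = dtype)
}

write_nifti_volume <- function(volume, path) {
  a <- volume$data
  if (volume$dtype == "int16") {
    a <- array(as.integer(pmin(pmax(round(a), -32768), 32767)), dim(a))
  }
  attr(a, "pixdim") <- volume$voxel_size / 1000
  img <- RNifti::asNifti(a, datatype = if (volume$dtype == "int16") "int16" else "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- Shrinkage-vector tables ----------------------------------------------

vector_table_columns <- c("sphere_id", "group", "sample", "increment",
                          "x_pre", "y_pre", "z_pre", "x_post", "y_post",
                          "z_post", "dx", "dy", "dz", "magnitude")

#' Write and read shrinkage-vector tables
#'
#' CSV with the fixed column set `sphere_id, group, sample, increment, x_pre,
#' y_pre, z_pre, x_post, y_post, z_post, dx, dy, dz, magnitude` (coordinates
#' and displacements in micrometres, post-cure coordinates mapped into the
#' pre-cure frame). Numbers are written at full double precision; a read-back
#' reproduces values to better than 1e-9.
#'
#' @param table a data frame with the columns above (extra columns are
#'   dropped with a warning); an empty table writes a header-only file.
#' @param path file path.
#' @return `write_vector_table` returns `path` invisibly; `read_vector_table`
#'   returns the data frame.
#' @export
write_vector_table <- function(table, path) {
  missing_cols <- setdiff(vector_table_columns, names(table))
  if (length(missing_cols))
    stop("vector table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(table)) {
    bad <- abs(table$magnitude - sqrt(table$dx^2 + table$dy^2 + table$dz^2)) > 1e-9
    if (any(bad)) stop("magnitude column inconsistent with (dx, dy, dz)")
    key <- paste(table$sample, table$increment, table$sphere_id)
    if (anyDuplicated(key)) stop("sphere ids must be unique per (sample, increment)")
  }
  extra <- setdiff(names(table), vector_table_columns)
  if (length(extra)) warning("dropping extra columns: ", paste(extra, collapse = ", "))
  out <- table[, vector_table_columns, drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, quote = which(!num))
  invisible(path)
}

#' @rdname write_vector_table
#' @export
read_vector_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sphere_id = "integer", group = "character",
                                sample = "character", increment = "character"))
  missing_cols <- setdiff(vector_table_columns, names(df))
  if (length(missing_cols))
    stop("not a shrinkage-vector table (missing ", paste(missing_cols, collapse = ", "), ")")
  df
}
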