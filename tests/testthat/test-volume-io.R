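make_int16_volume <- function(dim = c(32, 32, 32), seed = 1) {
  set.seed(seed)
  new_volume(array(sample(0:4095, prod(dim), replace = TRUE), dim),
             voxel_size = 16, dtype = "int16")
}

test_that("int16 volumes round-trip bit-identically through every format", {
  vol <- make_int16_volume()
  for (ext in c(".tif", ".mha", ".mhd", ".nii")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path, voxel_size = if (ext == ".tif") 16 else NULL)
    expect_identical(unname(back$data + 0), unname(vol$data + 0), label = ext)
    # NIfTI stores pixel dimensions in single precision
    expect_equal(back$voxel_size, c(16, 16, 16), tolerance = 1e-6, label = ext)
  }
})

test_that("MetaImage spacing is converted from millimetres", {
  path <- withr::local_tempfile(fileext = ".mha")
  writeLines(c("ObjectType = Image", "NDims = 3", "BinaryData = True",
               "BinaryDataByteOrderMSB = False", "DimSize = 2 2 2",
               "ElementSpacing = 0.016 0.016 0.02",
               "ElementType = MET_SHORT", "ElementDataFile = LOCAL"),
             con <- file(path, "wb"))
  writeBin(1:8, con, size = 2L, endian = "little")
  close(con)
  vol <- read_volume(path)
  expect_equal(vol$voxel_size, c(16, 16, 20))
  expect_equal(as.integer(vol$data), 1:8)
})

test_that("float32 volumes keep sub-integer values through MetaImage and NIfTI", {
  set.seed(2)
  vol <- new_volume(array(runif(27) * 100, c(3, 3, 3)), voxel_size = 16,
                    dtype = "float32")
  for (ext in c(".mha", ".nii")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(unname(back$data + 0), unname(vol$data + 0),
                 tolerance = 1e-6, label = ext)
  }
})

test_that("a TIFF stack with mismatched slice sizes is rejected by name", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.1, 4, 4), matrix(0.1, 5, 4)), path,
                  bits.per.sample = 16L)
  expect_error(read_volume(path, voxel_size = 16), "slice 2")
})

test_that("TIFF without a voxel size errors unless a sidecar provides one", {
  vol <- make_int16_volume(c(8, 8, 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, path)            # sidecar written alongside
  expect_equal(read_volume(path)$voxel_size, c(16, 16, 16))
  file.remove(paste0(path, ".json"))
  expect_error(read_volume(path), "voxel size")
})

test_that("missing and corrupt files produce clear errors", {
  expect_error(read_volume("no-such-file.mha"), "not found")
  path <- withr::local_tempfile(fileext = ".mha")
  writeLines("not a metaimage header", path)
  expect_error(read_volume(path), "MetaImage")
})

test_that("vector tables round-trip at full precision with the fixed header", {
  tab <- data.frame(
    sphere_id = 1:3, group = "gp1", sample = "s1", increment = "whole",
    x_pre = c(1, 2, 3) + 1e-7, y_pre = c(4, 5, 6), z_pre = c(7, 8, 9),
    x_post = c(4, 6, 3), y_post = c(8, 5, 6), z_post = c(7, 8, 9),
    dx = c(3, 4, 0), dy = c(4, 0, 0), dz = c(0, 3, 0),
    magnitude = c(5, 5, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_vector_table(tab, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(gsub("\"", "", hdr),
                   c("sphere_id", "group", "sample", "increment", "x_pre",
                     "y_pre", "z_pre", "x_post", "y_post", "z_post",
                     "dx", "dy", "dz", "magnitude"))
  back <- read_vector_table(path)
  for (cl in names(tab)) expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-12)
})

test_that("an empty vector table writes a header-only file", {
  tab <- data.frame(sphere_id = integer(), group = character(),
                    sample = character(), increment = character(),
                    x_pre = numeric(), y_pre = numeric(), z_pre = numeric(),
                    x_post = numeric(), y_post = numeric(), z_post = numeric(),
                    dx = numeric(), dy = numeric(), dz = numeric(),
                    magnitude = numeric())
  path <- withr::local_tempfile(fileext = ".csv")
  write_vector_table(tab, path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_vector_table(path)), 0L)
})

test_that("inconsistent magnitudes and duplicate ids are rejected", {
  tab <- data.frame(
    sphere_id = 1L, group = "g", sample = "s", increment = "i",
    x_pre = 0, y_pre = 0, z_pre = 0, x_post = 3, y_post = 4, z_post = 0,
    dx = 3, dy = 4, dz = 0, magnitude = 6)
  expect_error(write_vector_table(tab, tempfile()), "magnitude")
  tab$magnitude <- 5
  tab2 <- rbind(tab, tab)
  expect_error(write_vector_table(tab2, tempfile()), "unique")
})

test_that("every written volume carries a provenance sidecar", {
  vol <- make_int16_volume(c(8, 8, 4))
  path <- withr::local_tempfile(fileext = ".mha")
  write_volume(vol, path, metadata = list(seed = 42))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_match(side$tool, "^shrinkvec")
  expect_equal(side$voxel_size, c(16, 16, 16))
  expect_equal(side$seed, 42L)
  expect_equal(side$dtype, "int16")
})
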