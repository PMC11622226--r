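test_that("datacube size formula matches the flat float32 layout", {
  expect_identical(datacube_size_bytes(262144, 310), 325058560)
  expect_identical(datacube_size_bytes(35000, 199), 27860000)
  expect_identical(datacube_size_bytes(1, 1), 4)
})

test_that("write/read round trip is bit-exact for float32 matrices", {
  rc <- rand_cube(37, 9, seed = 5)
  expect_identical(file.size(rc$cube$path), datacube_size_bytes(37, 9))
  back <- read_datacube(rc$cube)
  expect_identical(back, rc$values)

  # 1x1 identity case
  p <- tempfile(fileext = ".bin")
  cube <- write_datacube(matrix(0, 1, 1), p)
  expect_identical(file.size(p), 4)
  expect_identical(read_datacube(cube)[1, 1], 0)
})

test_that("write_datacube rejects bad inputs", {
  meta <- datacube_meta(3, 2)
  expect_error(write_datacube(matrix(1, 2, 2), tempfile(), meta = meta),
               "shape")
  expect_error(write_datacube(matrix(c(1, NA), 1, 2), tempfile()), "finite")
})

test_that("metadata validation enforces the byte-length invariant", {
  rc <- rand_cube(10, 4, seed = 2)
  expect_silent(meta <- load_metadata(rc$path))
  expect_equal(meta$n_spectra, 10L)
  # truncate by one row: 156 bytes instead of 160
  raw <- readBin(rc$path, "raw", n = file.size(rc$path))
  writeBin(raw[1:156], rc$path)
  expect_error(load_metadata(rc$path), "length mismatch")
})

test_that("region layouts must tile [0, n_spectra) without overlap", {
  two <- list(
    list(label = "a", row_offset = 0L, n_pixels = 6L, width = 3L, height = 2L),
    list(label = "b", row_offset = 6L, n_pixels = 4L, width = 2L, height = 2L))
  expect_silent(datacube_meta(10, 4, regions = two))
  overlapping <- list(
    list(label = "a", row_offset = 0L, n_pixels = 6L, width = 6L, height = 1L),
    list(label = "b", row_offset = 5L, n_pixels = 5L, width = 5L, height = 1L))
  expect_error(datacube_meta(10, 4, regions = overlapping), "overlap|tile")
  gap <- list(
    list(label = "a", row_offset = 0L, n_pixels = 4L, width = 4L, height = 1L),
    list(label = "b", row_offset = 6L, n_pixels = 4L, width = 4L, height = 1L))
  expect_error(datacube_meta(10, 4, regions = gap), "overlap|gap|tile")
})

test_that("batch plans partition the rows exactly", {
  p <- batch_plan(5000, 1900)
  expect_equal(p$n_batches, 3L)
  expect_equal(p$offsets, c(0L, 1900L, 3800L))
  expect_equal(p$sizes, c(1900L, 1900L, 1200L))
  expect_equal((p$n_batches - 1L) * p$batch_size + p$last_batch_size, 5000L)

  single <- batch_plan(1900, 1900)
  expect_equal(single$n_batches, 1L)
  expect_equal(single$last_batch_size, 1900L)
})

test_that("iter_batches reproduces the full cube in order, once", {
  rc <- rand_cube(101, 7, seed = 9)
  for (bs in c(7L, 33L, 101L)) {
    it <- iter_batches(rc$cube, batch_plan(101, bs))
    got <- list(); offs <- integer(0)
    while (!is.null(b <- it())) {
      offs <- c(offs, b$row_offset)
      got <- c(got, list(b$data))
    }
    expect_equal(offs, batch_plan(101, bs)$offsets)
    expect_identical(do.call(rbind, got), rc$values)
  }
})

test_that("matrix files round trip and support row windows", {
  x <- float32_round(matrix(rnorm(5000 * 10), 5000, 10))
  mf <- write_matrix(x, tempfile(fileext = ".bin"), role = "scores")
  expect_identical(read_matrix(mf), x)
  windowed <- rbind(read_matrix(mf, 0L, 2500L), read_matrix(mf, 2500L, 2500L))
  expect_identical(windowed, x)
  expect_error(read_matrix(mf, 4000L, 2000L), "window")

  # wrong declared shape is caught on open
  side <- jsonlite::read_json(sub("\\.bin$", ".json", mf$path),
                              simplifyVector = TRUE)
  side$n_rows <- 4999
  jsonlite::write_json(side, sub("\\.bin$", ".json", mf$path),
                       auto_unbox = TRUE)
  expect_error(matrix_file(mf$path), "mismatch")
})
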