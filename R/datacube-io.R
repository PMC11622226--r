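#' Datacube metadata
#'
#' Constructs and validates the metadata sidecar of a flat binary MSI
#' datacube: total spectrum count, peak count, the peak m/z axis, and the
#' region layout (spatial labels with per-region row offsets, mirroring how
#' multi-image datasets are concatenated into one cube).
#'
#' @param n_spectra total number of spectra (pixels) in the cube.
#' @param n_peaks number of mass peaks (features, columns).
#' @param peak_mz numeric vector of peak m/z centres (Da), strictly
#'   increasing, all positive. Defaults to `1:n_peaks` placeholder values.
#' @param regions list of regions, each a list with `label`, `row_offset`
#'   (0-based first spectrum row), `n_pixels`, `width`, `height`. Regions
#'   must be ordered by `row_offset`, non-overlapping, and tile
#'   `[0, n_spectra)`. Defaults to a single region of width `n_spectra`,
#'   height 1.
#' @return a `datacube_meta` object (also a list).
#' @export
datacube_meta <- function(n_spectra, n_peaks, peak_mz = NULL, regions = NULL) {
  n_spectra <- as.integer(n_spectra)
  n_peaks <- as.integer(n_peaks)
  if (is.na(n_spectra) || n_spectra < 1L) stop("n_spectra must be >= 1")
  if (is.na(n_peaks) || n_peaks < 1L) stop("n_peaks must be >= 1")
  if (is.null(peak_mz)) peak_mz <- as.double(seq_len(n_peaks))
  peak_mz <- as.double(peak_mz)
  if (length(peak_mz) != n_peaks) stop("peak_mz length must equal n_peaks")
  if (any(peak_mz <= 0) || any(diff(peak_mz) <= 0))
    stop("peak_mz must be strictly increasing and positive")
  if (is.null(regions)) {
    regions <- list(list(label = "region_0", row_offset = 0L,
                         n_pixels = n_spectra, width = n_spectra, height = 1L))
  }
  meta <- structure(
    list(n_spectra = n_spectra, n_peaks = n_peaks, peak_mz = peak_mz,
         regions = regions,
         value_encoding = "float32 little-endian",
         layout = "row-major, one spectrum per row"),
    class = "datacube_meta")
  validate_meta(meta)
  meta
}

validate_meta <- function(meta) {
  stopifnot(inherits(meta, "datacube_meta") || is.list(meta))
  req <- c("n_spectra", "n_peaks", "peak_mz", "regions")
  missing_fields <- setdiff(req, names(meta))
  if (length(missing_fields))
    stop("metadata missing fields: ", paste(missing_fields, collapse = ", "))
  # regions must tile [0, n_spectra) in order, without overlap
  off <- vapply(meta$regions, function(r) as.integer(r$row_offset), integer(1))
  npx <- vapply(meta$regions, function(r) as.integer(r$n_pixels), integer(1))
  o <- order(off)
  if (!identical(o, seq_along(off)))
    stop("regions must be ordered by row_offset")
  if (off[1] != 0L) stop("first region must start at row 0")
  ends <- off + npx
  if (any(utils::head(ends, -1) != utils::tail(off, -1)))
    stop("regions overlap or leave gaps")
  if (utils::tail(ends, 1) != meta$n_spectra)
    stop("regions do not tile [0, n_spectra)")
  for (r in meta$regions) {
    wh <- as.integer(r$width) * as.integer(r$height)
    if (wh != as.integer(r$n_pixels))
      stop("region '", r$label, "': width x height != n_pixels")
  }
  invisible(meta)
}

#' Expected datacube file size in bytes
#'
#' The flat binary format stores `n_spectra x n_peaks` 32-bit floats, so the
#' file is exactly `n_spectra * n_peaks * 4` bytes. Returned as a double to
#' stay exact beyond the 32-bit integer range (multi-gigabyte cubes).
#'
#' @param n_spectra,n_peaks cube dimensions.
#' @return file size in bytes.
#' @export
#' @examples
#' datacube_size_bytes(262144, 310) / 1e6  # ~325 MB
datacube_size_bytes <- function(n_spectra, n_peaks) {
  as.double(n_spectra) * as.double(n_peaks) * 4
}

cube_bin_path <- function(path) {
  if (grepl("\\.bin$", path)) path else paste0(path, ".bin")
}
cube_json_path <- function(path) sub("\\.bin$", ".json", cube_bin_path(path))

#' Write a datacube to disk
#'
#' Writes an intensity matrix (spectra in rows, peaks in columns) as a flat
#' row-major little-endian float32 binary file plus a JSON metadata sidecar.
#' A write/read round trip reproduces the float32-rounded values bit-exactly.
#'
#' @param values numeric matrix, `n_spectra x n_peaks`, all values finite.
#' @param path output path; `.bin` is appended if absent and the sidecar is
#'   written next to it with extension `.json`.
#' @param meta optional [datacube_meta()]; defaults to one built from the
#'   matrix dimensions. Its declared shape must match `values`.
#' @return a `datacube` handle (list with `path`, `meta`), invisibly usable
#'   by [ipca_fit()], [iter_batches()] etc.
#' @export
write_datacube <- function(values, path, meta = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!all(is.finite(values))) stop("values must all be finite")
  if (is.null(meta)) meta <- datacube_meta(nrow(values), ncol(values))
  validate_meta(meta)
  if (nrow(values) != meta$n_spectra || ncol(values) != meta$n_peaks)
    stop("values shape does not match metadata (",
         nrow(values), "x", ncol(values), " vs ",
         meta$n_spectra, "x", meta$n_peaks, ")")
  bin <- cube_bin_path(path)
  con <- file(bin, "wb")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  # row-major on disk: write the transpose column-wise
  write_f32(con, t(values))
  close(con)
  write_meta_json(meta, cube_json_path(path))
  invisible(datacube(bin))
}

write_meta_json <- function(meta, json_path) {
  payload <- list(
    n_spectra = meta$n_spectra, n_peaks = meta$n_peaks,
    peak_mz = meta$peak_mz,
    regions = lapply(meta$regions, function(r)
      list(label = r$label, row_offset = r$row_offset, n_pixels = r$n_pixels,
           width = r$width, height = r$height)),
    value_encoding = meta$value_encoding, layout = meta$layout)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
}

#' Load and validate a datacube metadata sidecar
#'
#' Parses the JSON sidecar, validates the region layout, and checks the
#' declared shape against the binary file length (`n_spectra * n_peaks * 4`
#' bytes) — a mismatch signals a truncated or corrupt cube.
#'
#' @param path path to the cube (`.bin` or its stem).
#' @return a validated `datacube_meta`.
#' @export
load_metadata <- function(path) {
  json <- cube_json_path(path)
  bin <- cube_bin_path(path)
  if (!file.exists(json)) stop("metadata sidecar not found: ", json)
  raw <- jsonlite::read_json(json, simplifyVector = FALSE)
  for (f in c("n_spectra", "n_peaks", "peak_mz", "regions"))
    if (is.null(raw[[f]])) stop("metadata missing field: ", f)
  meta <- datacube_meta(
    n_spectra = raw$n_spectra, n_peaks = raw$n_peaks,
    peak_mz = unlist(raw$peak_mz),
    regions = raw$regions)
  if (file.exists(bin)) {
    expected <- datacube_size_bytes(meta$n_spectra, meta$n_peaks)
    actual <- file.size(bin)
    if (!isTRUE(actual == expected))
      stop("datacube length mismatch for ", bin, ": expected ", expected,
           " bytes (", meta$n_spectra, "x", meta$n_peaks,
           "x4), found ", actual)
  }
  meta
}

#' Open a datacube handle
#'
#' @param path path to the `.bin` file (or its stem). The sidecar is loaded
#'   and the byte-length invariant enforced.
#' @return a `datacube` object: list with `path` (the .bin) and `meta`.
#' @export
datacube <- function(path) {
  bin <- cube_bin_path(path)
  if (!file.exists(bin)) stop("datacube binary not found: ", bin)
  meta <- load_metadata(path)
  structure(list(path = bin, meta = meta), class = "datacube")
}

#' @export
print.datacube <- function(x, ...) {
  cat("<datacube> ", x$path, "\n  ",
      x$meta$n_spectra, " spectra x ", x$meta$n_peaks, " peaks (",
      format(datacube_size_bytes(x$meta$n_spectra, x$meta$n_peaks) / 1e6,
             digits = 4), " MB), ",
      length(x$meta$regions), " region(s)\n", sep = "")
  invisible(x)
}

#' Read a contiguous block of spectra from a datacube
#'
#' @param cube a `datacube`.
#' @param row_offset 0-based first row.
#' @param n_rows number of rows to read.
#' @return numeric matrix `n_rows x n_peaks` (float32 values as doubles).
#' @export
read_batch <- function(cube, row_offset, n_rows) {
  np <- cube$meta$n_peaks
  if (row_offset < 0 || row_offset + n_rows > cube$meta$n_spectra)
    stop("batch [", row_offset, ", ", row_offset + n_rows,
         ") outside cube rows [0, ", cube$meta$n_spectra, ")")
  con <- file(cube$path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, where = as.double(row_offset) * np * 4, origin = "start")
  x <- read_f32(con, n_rows * np)
  if (length(x) != n_rows * np)
    stop("short read at row offset ", row_offset)
  matrix(x, nrow = n_rows, ncol = np, byrow = TRUE)
}

#' Read a whole datacube into memory
#'
#' Convenience for cubes that fit in RAM (the exact-PCA comparator path).
#' @param cube a `datacube`.
#' @return `n_spectra x n_peaks` matrix.
#' @export
read_datacube <- function(cube) {
  read_batch(cube, 0L, cube$meta$n_spectra)
}

#' Partition cube rows into fixed-size batches
#'
#' @param n_spectra total rows.
#' @param batch_size rows per batch (the last batch may be shorter).
#' @return a `batch_plan`: list with `batch_size`, `n_batches`,
#'   `last_batch_size`, and `offsets`/`sizes` vectors.
#' @export
batch_plan <- function(n_spectra, batch_size) {
  batch_size <- as.integer(batch_size)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  batch_size <- min(batch_size, as.integer(n_spectra))
  n_batches <- as.integer(ceiling(n_spectra / batch_size))
  last <- as.integer(n_spectra - (n_batches - 1L) * batch_size)
  offsets <- as.integer((seq_len(n_batches) - 1L) * batch_size)
  sizes <- c(rep(batch_size, n_batches - 1L), last)
  structure(list(batch_size = batch_size, n_batches = n_batches,
                 last_batch_size = last, offsets = offsets, sizes = sizes),
            class = "batch_plan")
}

#' Iterate over datacube batches
#'
#' Returns a closure yielding one `(row_offset, data)` pair per call and
#' `NULL` when exhausted. Each call opens the file, reads only the current
#' batch, and closes the file again, so the reader's peak resident footprint
#' is one batch (`batch_size x n_peaks` values) regardless of cube size;
#' previously yielded batches hold no reference inside the iterator and are
#' reclaimable as soon as the caller drops them.
#'
#' @param cube a `datacube`.
#' @param plan a [batch_plan()] consistent with the cube.
#' @return function yielding `list(row_offset =, data =)` or `NULL`.
#' @export
iter_batches <- function(cube, plan = NULL) {
  if (is.null(plan))
    plan <- batch_plan(cube$meta$n_spectra,
                       default_batch_size(cube$meta$n_peaks,
                                          cube$meta$n_spectra))
  total <- sum(plan$sizes)
  if (total != cube$meta$n_spectra)
    stop("batch plan covers ", total, " rows, cube has ",
         cube$meta$n_spectra)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > plan$n_batches) return(NULL)
    off <- plan$offsets[i]
    list(row_offset = off, data = read_batch(cube, off, plan$sizes[i]))
  }
}

# ---- generic float32 matrix files (scores / loadings) ----------------------

#' Write a float32 matrix file with a JSON sidecar
#'
#' Scores and loadings share the datacube's raw convention: row-major
#' little-endian float32 plus a sidecar `{n_rows, n_cols, role}`.
#'
#' @param values numeric matrix.
#' @param path output `.bin` path (or stem).
#' @param role `"scores"` or `"loadings"`.
#' @return a `matrix_file` handle.
#' @export
write_matrix <- function(values, path, role = c("scores", "loadings")) {
  role <- match.arg(role)
  if (!is.matrix(values)) values <- as.matrix(values)
  bin <- cube_bin_path(path)
  con <- file(bin, "wb")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  write_f32(con, t(values))
  close(con)
  jsonlite::write_json(
    list(n_rows = nrow(values), n_cols = ncol(values), role = role),
    cube_json_path(path), auto_unbox = TRUE, digits = NA)
  invisible(matrix_file(bin))
}

#' Open a matrix file handle
#' @param path `.bin` path or stem.
#' @return a `matrix_file`: list with `path`, `n_rows`, `n_cols`, `role`.
#' @export
matrix_file <- function(path) {
  bin <- cube_bin_path(path)
  side <- jsonlite::read_json(cube_json_path(path), simplifyVector = TRUE)
  expected <- as.double(side$n_rows) * side$n_cols * 4
  if (!isTRUE(file.size(bin) == expected))
    stop("matrix file length mismatch: expected ", expected, " bytes, found ",
         file.size(bin))
  structure(list(path = bin, n_rows = as.integer(side$n_rows),
                 n_cols = as.integer(side$n_cols), role = side$role),
            class = "matrix_file")
}

#' Read (a row window of) a matrix file
#'
#' @param mf a `matrix_file` (or path).
#' @param row_offset 0-based first row (default 0).
#' @param n_rows rows to read (default all remaining).
#' @return numeric matrix.
#' @export
read_matrix <- function(mf, row_offset = 0L, n_rows = NULL) {
  if (is.character(mf)) mf <- matrix_file(mf)
  if (is.null(n_rows)) n_rows <- mf$n_rows - row_offset
  if (row_offset < 0 || row_offset + n_rows > mf$n_rows)
    stop("row window outside matrix")
  con <- file(mf$path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, where = as.double(row_offset) * mf$n_cols * 4, origin = "start")
  x <- read_f32(con, n_rows * mf$n_cols)
  matrix(x, nrow = n_rows, ncol = mf$n_cols, byrow = TRUE)
}
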