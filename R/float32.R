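#' Round doubles to their nearest float32 representation
#'
#' All on-disk matrices in the datacube format are 32-bit IEEE-754 floats;
#' this helper reproduces, in memory, the value a number takes after a
#' write/read round trip, so tests and callers can reason about bit-exact
#' round trips. Dimensions are preserved.
#'
#' @param x numeric vector or matrix (finite values).
#' @return `x` with every element rounded to float32 precision.
#' @export
#' @examples
#' float32_round(1/3) == 1/3   # FALSE: 1/3 is not float32-representable
float32_round <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L, endian = "little"),
               what = "double", n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

# Low-level float32 block I/O. Offsets are in elements, not bytes.
write_f32 <- function(con, values) {
  writeBin(as.double(values), con, size = 4L, endian = "little")
}

read_f32 <- function(con, n) {
  readBin(con, what = "double", n = n, size = 4L, endian = "little")
}
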