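# Minimal centroided-imzML reader: enough of the imzML/ibd pair (continuous
# or processed mode) to bin centroid intensities against a peak list. Only
# the cvParam accessions needed for that are interpreted.

IMS_X <- "IMS:1000050"; IMS_Y <- "IMS:1000051"
IMS_OFFSET <- "IMS:1000102"; IMS_ARRLEN <- "IMS:1000103"
MS_MZ_ARRAY <- "MS:1000514"; MS_INT_ARRAY <- "MS:1000515"
MS_F32 <- "MS:1000521"; MS_F64 <- "MS:1000523"

#' Read spectra from a centroided imzML/ibd pair
#'
#' Parses the XML part with xml2, then pulls each spectrum's m/z and
#' intensity arrays from the external `.ibd` binary at the declared offsets.
#' Works for continuous mode (shared m/z block) and processed mode
#' (per-spectrum m/z); 32- and 64-bit float arrays are supported.
#'
#' @param imzml_path path to the `.imzML` file; the `.ibd` must sit next to
#'   it (same stem).
#' @return list with `spectra` (list of `list(mz, intensity, x, y)`) in file
#'   order.
#' @export
read_imzml <- function(imzml_path) {
  ibd_path <- sub("\\.imzML$", ".ibd", imzml_path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop(".ibd file not found: ", ibd_path)
  doc <- xml2::read_xml(imzml_path)
  xml2::xml_ns_strip(doc)

  # referenceableParamGroups tell us which array is m/z vs intensity and the
  # binary data type
  groups <- list()
  for (g in xml2::xml_find_all(doc, ".//referenceableParamGroup")) {
    id <- xml2::xml_attr(g, "id")
    acc <- xml2::xml_attr(xml2::xml_find_all(g, ".//cvParam"), "accession")
    groups[[id]] <- acc
  }
  group_kind <- function(acc) {
    kind <- if (MS_MZ_ARRAY %in% acc) "mz"
            else if (MS_INT_ARRAY %in% acc) "intensity" else NA_character_
    size <- if (MS_F64 %in% acc) 8L else if (MS_F32 %in% acc) 4L else NA_integer_
    list(kind = kind, size = size)
  }

  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd), add = TRUE)
  read_array <- function(offset, n, size) {
    seek(ibd, where = offset, origin = "start")
    readBin(ibd, "double", n = n, size = size, endian = "little")
  }

  spectra <- lapply(xml2::xml_find_all(doc, ".//spectrum"), function(sp) {
    cv_val <- function(node, accession) {
      p <- xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", accession))
      if (inherits(p, "xml_missing")) NA_character_ else xml2::xml_attr(p, "value")
    }
    x <- as.integer(cv_val(sp, IMS_X)); y <- as.integer(cv_val(sp, IMS_Y))
    arrays <- list(mz = NULL, intensity = NULL)
    for (bda in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      ref <- xml2::xml_find_first(bda, ".//referenceableParamGroupRef")
      acc <- xml2::xml_attr(xml2::xml_find_all(bda, ".//cvParam"), "accession")
      if (!inherits(ref, "xml_missing"))
        acc <- c(acc, groups[[xml2::xml_attr(ref, "ref")]])
      gk <- group_kind(acc)
      if (is.na(gk$kind) || is.na(gk$size))
        stop("binaryDataArray without array-type / data-type cvParams")
      offset <- as.double(cv_val(bda, IMS_OFFSET))
      n <- as.integer(cv_val(bda, IMS_ARRLEN))
      arrays[[gk$kind]] <- read_array(offset, n, gk$size)
    }
    if (is.null(arrays$mz) || is.null(arrays$intensity))
      stop("spectrum missing m/z or intensity array")
    if (length(arrays$mz) != length(arrays$intensity))
      stop("m/z and intensity arrays differ in length")
    list(mz = arrays$mz, intensity = arrays$intensity, x = x, y = y)
  })
  if (!length(spectra)) stop("imzML file contains no spectra")
  list(spectra = spectra)
}

#' Convert centroided imzML to the binary datacube format
#'
#' Bins each spectrum's centroid intensities onto a fixed peak list: cell
#' `(i, j)` is the sum of centroids of spectrum `i` whose m/z falls within
#' `peak_mz[j] +/- tolerance`. When peak windows overlap, a centroid inside
#' two windows is assigned to the nearer peak centre (ties to the lower
#' index) and a warning reports the overlap. Spectra keep imzML file order;
#' the region grid is derived from the pixel coordinate ranges.
#'
#' @param imzml_path path to the `.imzML` file.
#' @param peak_mz strictly increasing positive m/z centres (Da).
#' @param tolerance half-window width; interpreted in Da
#'   (`tolerance_unit = "Da"`, default) or ppm of each centre.
#' @param path output cube path.
#' @param tolerance_unit `"Da"` or `"ppm"`.
#' @return a `datacube` handle.
#' @export
convert_imzml <- function(imzml_path, peak_mz, tolerance, path,
                          tolerance_unit = c("Da", "ppm")) {
  tolerance_unit <- match.arg(tolerance_unit)
  if (tolerance <= 0) stop("tolerance must be > 0")
  peak_mz <- as.double(peak_mz)
  if (!length(peak_mz) || any(peak_mz <= 0) || any(diff(peak_mz) <= 0))
    stop("peak_mz must be non-empty, positive, strictly increasing")
  half <- if (tolerance_unit == "Da") rep(tolerance, length(peak_mz))
          else peak_mz * tolerance * 1e-6
  lo <- peak_mz - half
  hi <- peak_mz + half
  if (any(utils::head(hi, -1) > utils::tail(lo, -1)))
    warning("overlapping peak windows; centroids assigned to nearest centre")

  parsed <- read_imzml(imzml_path)
  n <- length(parsed$spectra)
  np <- length(peak_mz)
  values <- matrix(0, nrow = n, ncol = np)
  for (i in seq_len(n)) {
    sp <- parsed$spectra[[i]]
    for (ci in seq_along(sp$mz)) {
      inside <- which(sp$mz[ci] >= lo & sp$mz[ci] <= hi)
      if (!length(inside)) next
      # nearest centre wins; which.min ties to the lower index
      j <- inside[which.min(abs(peak_mz[inside] - sp$mz[ci]))]
      values[i, j] <- values[i, j] + sp$intensity[ci]
    }
  }
  xs <- vapply(parsed$spectra, `[[`, integer(1), "x")
  ys <- vapply(parsed$spectra, `[[`, integer(1), "y")
  regions <- NULL
  if (!anyNA(xs) && !anyNA(ys)) {
    w <- max(xs) - min(xs) + 1L
    h <- max(ys) - min(ys) + 1L
    if (w * h == n)
      regions <- list(list(label = "imzml_0", row_offset = 0L, n_pixels = n,
                           width = w, height = h))
  }
  meta <- datacube_meta(n, np, peak_mz = peak_mz, regions = regions)
  write_datacube(values, path, meta = meta)
  datacube(path)
}
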