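#' Specification for a synthetic MSI datacube
#'
#' Describes a planted low-rank cube: `X = b + sum_i lambda_i u_i v_i^T +
#' sigma * eps`, where the `u_i` are unit-norm spatially smooth per-region
#' patterns (orthogonalised low-frequency random fields), the `v_i` are
#' orthonormal loadings, and `eps` is i.i.d. standard normal. The planted
#' singular spectrum decays geometrically: `lambda_i = lambda0 * gamma^(i-1)`.
#'
#' Defaults emulate a strong-contrast peak-picked MSI image: ion-count-scale
#' noise (`noise_sd = 50`), a baseline at three noise SDs so intensities are
#' mostly positive, and a leading component 30 times above the noise
#' singular-value edge `sigma * (sqrt(m) + sqrt(n))`.
#'
#' @param n_spectra,n_peaks cube dimensions.
#' @param rank number of planted components, `<= min(n_spectra, n_peaks)`.
#' @param gamma geometric decay of the planted singular values, in (0, 1).
#' @param lambda0 leading planted singular value; default
#'   `30 * noise_sd * (sqrt(n_spectra) + sqrt(n_peaks))`.
#' @param noise_sd i.i.d. Gaussian noise SD (>= 0).
#' @param baseline constant offset, default `3 * noise_sd`.
#' @param width,height grid dimensions of each region; one region per entry
#'   (recycled pairwise). `sum(width * height)` must equal `n_spectra`.
#'   Default: a single `n_spectra x 1` region.
#' @param seed RNG seed; the cube is bit-reproducible from it.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n_spectra, n_peaks, rank = 3L, gamma = 0.7,
                           lambda0 = NULL, noise_sd = 50, baseline = NULL,
                           width = NULL, height = NULL, seed = 1L) {
  if (rank > min(n_spectra, n_peaks)) stop("rank exceeds min(n_spectra, n_peaks)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)")
  if (is.null(lambda0))
    lambda0 <- 30 * max(noise_sd, 1) * (sqrt(n_spectra) + sqrt(n_peaks))
  if (is.null(baseline)) baseline <- 3 * noise_sd
  if (baseline < 0) stop("baseline must be >= 0")
  if (is.null(width)) { width <- as.integer(n_spectra); height <- 1L }
  if (is.null(height)) height <- rep(1L, length(width))
  if (sum(as.double(width) * height) != n_spectra)
    stop("region grids must tile exactly n_spectra pixels")
  structure(list(n_spectra = as.integer(n_spectra),
                 n_peaks = as.integer(n_peaks), rank = as.integer(rank),
                 gamma = gamma, lambda0 = lambda0, noise_sd = noise_sd,
                 baseline = baseline, width = as.integer(width),
                 height = as.integer(height), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth per-region pattern: a few low-frequency cosine modes with random
# coefficients, evaluated on the region grid (row-major), one column per
# planted component.
region_patterns <- function(width, height, rank) {
  x <- (rep(seq_len(width), times = height) - 0.5) / width
  y <- (rep(seq_len(height), each = width) - 0.5) / height
  n_modes <- 4L
  out <- matrix(0, nrow = width * height, ncol = rank)
  for (i in seq_len(rank)) {
    f <- numeric(width * height)
    for (jx in 0:(n_modes - 1L)) for (jy in 0:(n_modes - 1L)) {
      amp <- rnorm(1) / (1 + jx + jy)   # low frequencies dominate
      ph <- runif(2, 0, 2 * pi)
      f <- f + amp * cos(2 * pi * jx * x + ph[1]) * cos(2 * pi * jy * y + ph[2])
    }
    out[, i] <- f
  }
  out
}

#' Generate a synthetic datacube with known ground truth
#'
#' Draws the planted structure and noise from `spec$seed`, writes the cube in
#' the standard `.bin`/`.json` datacube format (noise generated in fixed-size
#' row blocks so the realisation is identical regardless of cube size), and
#' saves the ground-truth loadings as a float32 matrix file next to it.
#'
#' @param spec a [synthetic_spec()].
#' @param path output cube path (stem or `.bin`).
#' @return list with `cube` (a `datacube`) and `truth` (list: `loadings`
#'   r x n_peaks orthonormal, `patterns` n_spectra x r, `lambda`).
#' @export
generate_datacube <- function(spec, path) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  r <- spec$rank
  np <- spec$n_peaks
  m <- spec$n_spectra
  # orthonormal loadings: QR of a Gaussian matrix, deterministic sign
  V <- qr.Q(qr(matrix(rnorm(np * r), np, r)))
  V <- t(apply_sign_convention(t(V)))          # np x r
  # smooth spatial patterns per region, then global orthonormalisation
  U <- do.call(rbind, mapply(function(w, h) region_patterns(w, h, r),
                             spec$width, spec$height, SIMPLIFY = FALSE))
  # zero-mean patterns: the planted per-feature variance is then exactly
  # sum_i lambda_i^2 v_if^2 / (N - 1) plus the noise variance
  U <- scale(U, center = TRUE, scale = FALSE)
  U <- qr.Q(qr(U))                             # m x r, orthonormal columns
  lambda <- spec$lambda0 * spec$gamma^(seq_len(r) - 1)
  meta <- datacube_meta(
    m, np,
    regions = {
      offs <- cumsum(c(0L, utils::head(spec$width * spec$height, -1L)))
      mapply(function(i, off, w, h)
        list(label = paste0("region_", i - 1L), row_offset = off,
             n_pixels = w * h, width = w, height = h),
        seq_along(spec$width), offs, spec$width, spec$height,
        SIMPLIFY = FALSE)
    })
  bin <- cube_bin_path(path)
  con <- file(bin, "wb")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  block <- 8192L
  offsets <- seq.int(0L, m - 1L, by = block)
  for (off in offsets) {
    rows <- (off + 1L):min(off + block, m)
    x <- U[rows, , drop = FALSE] %*% (lambda * t(V))
    if (spec$noise_sd > 0)
      x <- x + matrix(rnorm(length(rows) * np, sd = spec$noise_sd),
                      nrow = length(rows))
    x <- x + spec$baseline
    write_f32(con, t(x))
  }
  close(con)
  write_meta_json(meta, cube_json_path(path))
  write_matrix(t(V), paste0(sub("\\.bin$", "", bin), "_truth_loadings.bin"),
               role = "loadings")
  list(cube = datacube(bin),
       truth = list(loadings = t(V), patterns = U, lambda = lambda))
}

#' Deterministic fixture suite
#'
#' Named small cubes used across the test and validation workflow, generated
#' into `dir`: `tiny` (100 x 5), `medium` (50,000 x 100, rank 15,
#' gamma = 0.7, seed 42 — the accuracy-validation cube), `rank1` (noiseless
#' rank-1), `zerovar` (constant columns), and `two_region` (two pixel grids).
#' Each entry carries its generating spec as the manifest.
#'
#' @param dir output directory.
#' @param which subset of fixture names (default all).
#' @return named list of `list(cube =, truth =, spec =)`.
#' @export
make_fixture_suite <- function(dir, which = NULL) {
  specs <- list(
    tiny = synthetic_spec(100L, 5L, rank = 2L, seed = 101L),
    medium = synthetic_spec(50000L, 100L, rank = 15L, gamma = 0.7,
                            width = 250L, height = 200L, seed = 42L),
    rank1 = synthetic_spec(60L, 8L, rank = 1L, noise_sd = 0, baseline = 0,
                           seed = 7L),
    two_region = synthetic_spec(200L, 6L, rank = 3L, width = c(10L, 10L),
                                height = c(12L, 8L), seed = 11L))
  if (!is.null(which)) specs <- specs[intersect(names(specs), which)]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- lapply(names(specs), function(nm) {
    res <- generate_datacube(specs[[nm]], file.path(dir, nm))
    res$spec <- specs[[nm]]
    res
  })
  names(out) <- names(specs)
  if (is.null(which) || "zerovar" %in% which) {
    zv <- matrix(5, nrow = 40, ncol = 4)
    cube <- write_datacube(zv, file.path(dir, "zerovar"))
    out$zerovar <- list(cube = cube, truth = NULL, spec = NULL)
  }
  out
}
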