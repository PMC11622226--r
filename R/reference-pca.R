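#' Exact in-memory PCA comparator
#'
#' The deliberately naive baseline: reads the whole cube into RAM, centres it
#' by its column means, and takes one dense SVD. Returns the same model shape
#' and sign convention as [ipca_fit()], so the two are directly comparable.
#'
#' @param cube a `datacube`, path, or in-memory matrix.
#' @param k number of components (default all).
#' @return an `ipca_model` with `method = "exact"`.
#' @export
exact_pca <- function(cube, k = NULL) {
  x <- if (is.matrix(cube)) cube
       else read_datacube(if (is.character(cube)) datacube(cube) else cube)
  np <- ncol(x)
  n <- nrow(x)
  if (is.null(k)) k <- np
  k <- as.integer(k)
  if (k > np) stop("k (", k, ") exceeds number of peaks (", np, ")")
  if (n < k) stop("n_spectra must be >= k")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc, nu = 0L)
  V <- apply_sign_convention(t(sv$v))
  keep <- seq_len(min(k, length(sv$d)))
  state <- structure(list(
    n_seen = n, n_peaks = np, k = k, mean = mu, m2 = colSums(xc^2),
    singular_values = sv$d[keep],
    components = V[keep, , drop = FALSE]), class = "fit_state")
  as_ipca_model(state, method = "exact")
}

#' Pixel-subsampled PCA comparator
#'
#' Draws a uniform sample without replacement of `floor(fraction * n_spectra)`
#' spectra (default 6.5% of the pixels), fits exact PCA on the subsample, and
#' returns that model; centring of all pixels during a subsequent
#' [transform_incremental()] uses the subsample mean. Fast but approximate —
#' its loadings are noisier than the incremental fit's, especially beyond the
#' leading components.
#'
#' @param cube a `datacube` or path.
#' @param fraction sampling fraction in `(0, 1]`, default 0.065.
#' @param seed RNG seed for the pixel sample.
#' @param k number of components (default all).
#' @return an `ipca_model` with `method = "subsampled"`.
#' @export
subsampled_pca <- function(cube, fraction = 0.065, seed = 1L, k = NULL) {
  if (is.character(cube)) cube <- datacube(cube)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- cube$meta$n_spectra
  np <- cube$meta$n_peaks
  if (is.null(k)) k <- np
  n_sample <- floor(fraction * m)
  if (n_sample < k)
    stop("subsample of ", n_sample, " rows is smaller than k = ", k)
  rows <- if (n_sample == m) seq_len(m) else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    sort(sample.int(m, n_sample))
  }
  x <- read_rows(cube, rows)
  model <- exact_pca(x, k = k)
  model$method <- "subsampled"
  model
}

# Gathers an arbitrary (sorted) row subset, reading contiguous runs.
read_rows <- function(cube, rows) {
  np <- cube$meta$n_peaks
  out <- matrix(0, nrow = length(rows), ncol = np)
  runs <- split(rows, cumsum(c(1L, diff(rows) != 1L)))
  pos <- 1L
  for (run in runs) {
    n <- length(run)
    out[pos:(pos + n - 1L), ] <- read_batch(cube, run[1L] - 1L, n)
    pos <- pos + n
  }
  out
}

#' Sign-align one loading matrix to a reference
#'
#' PCA signs are arbitrary; before computing similarity metrics each
#' component of `other` is flipped if its dot product with the matching
#' reference component is negative.
#'
#' @param reference,other loading matrices of equal shape (rows = components).
#' @return `other` with per-component sign flips so every
#'   `dot(reference_i, other_i) >= 0`.
#' @export
align_signs <- function(reference, other) {
  if (!identical(dim(reference), dim(other)))
    stop("loading matrices must have the same shape")
  flips <- ifelse(rowSums(reference * other) < 0, -1, 1)
  other * flips
}

#' Per-component loading similarity metrics
#'
#' For each component pair: mean squared error and squared Pearson
#' correlation (r^2) of the two loading vectors, plus grouped mean r^2 over
#' the component ranges 1-10, 11-20, 21-30 (those present). Inputs must be
#' sign-aligned first ([align_signs()]). A zero-variance loading vector makes
#' r^2 undefined; it is reported as `NA`, not 0.
#'
#' @param a,b loading matrices of equal shape (rows = components).
#' @return a `comparison_report`: list of tibbles `per_component`
#'   (component, mse, r2) and `grouped` (range, mean_r2).
#' @export
loading_metrics <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("loading matrices must have the same shape")
  k <- nrow(a)
  mse <- vapply(seq_len(k), function(i) mean((a[i, ] - b[i, ])^2), numeric(1))
  r2 <- vapply(seq_len(k), function(i) {
    if (stats::sd(a[i, ]) == 0 || stats::sd(b[i, ]) == 0) return(NA_real_)
    stats::cor(a[i, ], b[i, ])^2
  }, numeric(1))
  per_component <- tibble::tibble(component = seq_len(k), mse = mse, r2 = r2)
  grouped <- per_component |>
    dplyr::mutate(range = dplyr::case_when(
      component <= 10 ~ "1-10",
      component <= 20 ~ "11-20",
      component <= 30 ~ "21-30",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(range)) |>
    dplyr::group_by(range) |>
    dplyr::summarise(mean_r2 = mean(r2, na.rm = TRUE),
                     mean_mse = mean(mse), .groups = "drop")
  structure(list(per_component = per_component, grouped = grouped),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$grouped)
  invisible(x)
}

#' Pixelwise score differences as percent of the reference range
#'
#' `100 * (ref - other) / (max(ref) - min(ref))` per pixel for one component,
#' the convention used for difference heatmaps between two PCA results.
#'
#' @param scores_ref,scores_other score matrices (or `matrix_file`s) of equal
#'   shape, sign-aligned.
#' @param component 1-based component index.
#' @return list with `percent` (per-pixel vector), `min_pct`, `max_pct`.
#' @export
score_difference_percent <- function(scores_ref, scores_other, component) {
  if (inherits(scores_ref, "matrix_file")) scores_ref <- read_matrix(scores_ref)
  if (inherits(scores_other, "matrix_file")) scores_other <- read_matrix(scores_other)
  if (!identical(dim(scores_ref), dim(scores_other)))
    stop("score sets must have the same shape")
  if (component < 1 || component > ncol(scores_ref))
    stop("component index out of range")
  ref <- scores_ref[, component]
  oth <- scores_other[, component]
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("reference component has zero range")
  pct <- 100 * (ref - oth) / rng
  list(percent = pct, min_pct = min(pct), max_pct = max(pct))
}

#' Principal angles between two row-orthonormal subspaces
#'
#' Basis-independent subspace distance: the arccosines of the singular values
#' of `A B^T`, clipped to `[0, 1]`, returned nondecreasing (radians).
#'
#' @param a,b row-orthonormal matrices with the same number of columns.
#' @return numeric vector of angles in radians.
#' @export
principal_angles <- function(a, b) {
  check_orthonormal <- function(m, name) {
    g <- m %*% t(m)
    if (max(abs(g - diag(nrow(m)))) > 1e-4)
      stop(name, " is not row-orthonormal")
  }
  if (ncol(a) != ncol(b)) stop("subspaces live in different feature spaces")
  check_orthonormal(a, "a"); check_orthonormal(b, "b")
  s <- svd(a %*% t(b), nu = 0L, nv = 0L)$d
  sort(acos(pmin(pmax(s, 0), 1)))
}

#' Compare two fitted models
#'
#' Sign-aligns `other`'s loadings to `reference`'s and computes
#' [loading_metrics()]; optionally adds percent-of-range score differences
#' when both score sets are supplied.
#'
#' @param reference,other `ipca_model`s over the same peaks.
#' @param scores_ref,scores_other optional score matrices / `matrix_file`s.
#' @param components components for score differences (default 1:3, clipped).
#' @return a `comparison_report`, with a `score_diff` tibble when scores are
#'   given (component, min_pct, max_pct).
#' @export
compare_models <- function(reference, other, scores_ref = NULL,
                           scores_other = NULL, components = 1:3) {
  k <- min(reference$k, other$k)
  ra <- reference$components[seq_len(k), , drop = FALSE]
  rb <- align_signs(ra, other$components[seq_len(k), , drop = FALSE])
  rep <- loading_metrics(ra, rb)
  if (!is.null(scores_ref) && !is.null(scores_other)) {
    if (inherits(scores_ref, "matrix_file")) scores_ref <- read_matrix(scores_ref)
    if (inherits(scores_other, "matrix_file")) scores_other <- read_matrix(scores_other)
    flips <- ifelse(rowSums(reference$components[seq_len(k), , drop = FALSE] *
                              other$components[seq_len(k), , drop = FALSE]) < 0,
                    -1, 1)
    scores_other <- sweep(scores_other[, seq_len(k), drop = FALSE], 2L, flips, `*`)
    components <- components[components <= k]
    rep$score_diff <- dplyr::bind_rows(lapply(components, function(ci) {
      d <- score_difference_percent(scores_ref[, seq_len(k), drop = FALSE],
                                    scores_other, ci)
      tibble::tibble(component = ci, min_pct = d$min_pct, max_pct = d$max_pct)
    }))
  }
  rep
}

#' Serialise a comparison report
#'
#' @param report a `comparison_report`.
#' @param path output `.json` path; a sibling `.csv` of per-component metrics
#'   is written when `csv = TRUE`.
#' @param csv also write the per-component table as CSV.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path, csv = FALSE) {
  payload <- list(per_component = report$per_component,
                  grouped = report$grouped)
  if (!is.null(report$score_diff)) payload$score_diff <- report$score_diff
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (csv)
    utils::write.csv(report$per_component, sub("\\.json$", ".csv", path),
                     row.names = FALSE)
  invisible(path)
}
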