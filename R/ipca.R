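#' Default batch size for incremental PCA
#'
#' Rows per update are set to 19 times the number of mass peaks, a heuristic
#' that balances SVD throughput against resident memory on peak-picked MSI
#' cubes, clipped to the number of spectra (and never below the number of
#' peaks when enough spectra exist, so the first SVD is feasible).
#'
#' @param n_peaks number of mass peaks (features).
#' @param n_spectra total number of spectra.
#' @param factor heuristic multiplier, default 19.
#' @return integer batch size.
#' @export
#' @examples
#' default_batch_size(310, 262144)  # 5890
default_batch_size <- function(n_peaks, n_spectra, factor = 19L) {
  if (n_peaks < 1L || n_spectra < 1L) stop("n_peaks and n_spectra must be >= 1")
  d <- min(as.double(factor) * n_peaks, as.double(n_spectra))
  if (n_spectra >= n_peaks) d <- max(d, n_peaks)
  as.integer(d)
}

#' Initialise an incremental PCA fit state
#'
#' Holds the running sample count, per-feature mean and accumulated squared
#' deviations (kept in double precision), and the current singular values and
#' orthonormal loading rows.
#'
#' @param n_peaks number of features.
#' @param k number of components to retain (default all).
#' @return a `fit_state`.
#' @export
new_fit_state <- function(n_peaks, k = n_peaks) {
  k <- as.integer(k)
  if (k < 1L || k > n_peaks) stop("k must be in [1, n_peaks]")
  structure(list(
    n_seen = 0L, n_peaks = as.integer(n_peaks), k = k,
    mean = numeric(n_peaks), m2 = numeric(n_peaks),
    singular_values = numeric(0), components = NULL), class = "fit_state")
}

#' Incremental mean / squared-deviation update
#'
#' Chan-style pairwise combination of running statistics with a new batch:
#' `mu' = (N mu + d mu_b) / (N + d)` and
#' `m2' = m2 + m2_b + (mu - mu_b)^2 * N d / (N + d)` per feature, which
#' agrees exactly (in exact arithmetic) with one-pass statistics over all
#' rows seen.
#'
#' @param state a `fit_state`.
#' @param batch numeric matrix with `n_peaks` columns.
#' @param batch_mean optional precomputed column means of `batch`.
#' @return the state with `n_seen`, `mean`, `m2` updated.
#' @export
update_mean_var <- function(state, batch, batch_mean = NULL) {
  if (!all(is.finite(batch))) stop("batch contains non-finite values")
  d <- nrow(batch)
  if (d < 1L) stop("batch must have at least one row")
  if (ncol(batch) != state$n_peaks) stop("batch has wrong number of columns")
  mu_b <- if (is.null(batch_mean)) colMeans(batch) else batch_mean
  m2_b <- colSums(sweep(batch, 2L, mu_b)^2)
  n <- state$n_seen
  n_new <- n + d
  if (n == 0L) {
    state$mean <- mu_b
    state$m2 <- m2_b
  } else {
    state$m2 <- state$m2 + m2_b + (state$mean - mu_b)^2 * (n * d / n_new)
    state$mean <- (n * state$mean + d * mu_b) / n_new
  }
  state$n_seen <- n_new
  state
}

# Deterministic sign convention: in each loading row, the entry of largest
# absolute magnitude (ties: lowest feature index) is made positive. Returns
# the per-row sign vector applied.
sign_convention <- function(V) {
  flips <- apply(V, 1L, function(row) {
    j <- which.max(abs(row))
    if (row[j] < 0) -1 else 1
  })
  flips
}

apply_sign_convention <- function(V) {
  V * sign_convention(V)
}

#' One sequential Karhunen-Loeve update
#'
#' Processes a batch: centres it by its own column mean, forms the stacked
#' matrix `[diag(s) V ; X_c ; c]` where
#' `c = sqrt(N d / (N + d)) (mu - mu_b)` carries the running-mean correction,
#' takes a thin SVD, applies the deterministic sign convention, retains the
#' top-k singular values / right singular vectors, and folds the batch into
#' the running mean/variance. On the first call the stack is just the
#' centred batch, which must have at least `k` rows.
#'
#' @param state a `fit_state`.
#' @param batch numeric matrix, `d x n_peaks`, finite.
#' @return the updated `fit_state`.
#' @export
partial_fit <- function(state, batch) {
  if (!is.matrix(batch)) batch <- as.matrix(batch)
  if (!all(is.finite(batch))) stop("batch contains non-finite values")
  d <- nrow(batch)
  if (ncol(batch) != state$n_peaks)
    stop("batch has ", ncol(batch), " columns, expected ", state$n_peaks)
  mu_b <- colMeans(batch)
  Xc <- sweep(batch, 2L, mu_b)
  if (state$n_seen == 0L) {
    if (d < state$k)
      stop("first batch has ", d, " rows but k = ", state$k,
           "; enlarge the first batch")
    A <- Xc
  } else {
    corr <- sqrt(state$n_seen * d / (state$n_seen + d)) *
      (state$mean - mu_b)
    A <- rbind(state$singular_values * state$components, Xc,
               matrix(corr, nrow = 1L))
  }
  sv <- svd(A, nu = 0L)
  V <- t(sv$v)                      # rows = components
  V <- apply_sign_convention(V)
  keep <- seq_len(min(state$k, length(sv$d)))
  state$singular_values <- sv$d[keep]
  state$components <- V[keep, , drop = FALSE]
  update_mean_var(state, batch, batch_mean = mu_b)
}

#' Explained variance from a completed fit state
#'
#' `explained_variance_i = s_i^2 / (N - 1)`; the ratio divides by the total
#' per-feature variance `sum(m2) / (N - 1)`. Ratios are clamped to `[0, 1]`
#' and defined as 0 for an all-zero-variance cube.
#'
#' @param state a `fit_state` with `n_seen >= 2`.
#' @return list with `explained_variance` and `explained_variance_ratio`.
#' @export
finalize_explained_variance <- function(state) {
  if (state$n_seen < 2L) stop("need at least 2 rows to estimate variance")
  ev <- state$singular_values^2 / (state$n_seen - 1L)
  total <- sum(state$m2) / (state$n_seen - 1L)
  ratio <- if (total > 0) pmin(pmax(ev / total, 0), 1) else rep(0, length(ev))
  list(explained_variance = ev, explained_variance_ratio = ratio)
}

as_ipca_model <- function(state, method) {
  fin <- finalize_explained_variance(state)
  structure(list(
    method = method, n_seen = state$n_seen, n_peaks = state$n_peaks,
    k = state$k, mean = state$mean, m2 = state$m2,
    singular_values = state$singular_values, components = state$components,
    explained_variance = fin$explained_variance,
    explained_variance_ratio = fin$explained_variance_ratio),
    class = "ipca_model")
}

#' @export
print.ipca_model <- function(x, ...) {
  cat("<ipca_model> method=", x$method, ", ", x$k, " components over ",
      x$n_peaks, " peaks, fitted on ", x$n_seen, " spectra\n", sep = "")
  r <- x$explained_variance_ratio
  cat("  explained variance ratio (top ", min(5L, length(r)), "): ",
      paste(signif(utils::head(r, 5L), 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fit incremental PCA on a datacube
#'
#' Streams the cube batch by batch through [partial_fit()]; peak additional
#' resident memory is one batch plus the `k x n_peaks` loading matrix,
#' independent of the number of spectra. If the requested batch size is
#' smaller than `k`, the first batch alone is enlarged to `k` rows so the
#' initial SVD is feasible.
#'
#' @param cube a `datacube` (or path to one).
#' @param k number of components (default: all, `n_peaks`).
#' @param batch_size rows per update; default [default_batch_size()].
#' @param verbose log per-stage timings.
#' @return an `ipca_model`.
#' @export
ipca_fit <- function(cube, k = NULL, batch_size = NULL, verbose = FALSE) {
  if (is.character(cube)) cube <- datacube(cube)
  m <- cube$meta$n_spectra
  np <- cube$meta$n_peaks
  if (is.null(k)) k <- np
  k <- as.integer(k)
  if (m < k) stop("n_spectra (", m, ") must be >= k (", k, ")")
  t0 <- proc.time()[["elapsed"]]
  if (is.null(batch_size)) batch_size <- default_batch_size(np, m)
  batch_size <- min(as.integer(batch_size), m)
  if (verbose) log_stage("batch size calculation", proc.time()[["elapsed"]] - t0,
                         detail = paste0("batch_size=", batch_size))
  # first batch enlarged to k rows when needed; later batches keep the plan
  first <- max(batch_size, k)
  offsets <- if (first < m)
    c(0L, seq.int(first, m - 1L, by = batch_size)) else 0L
  sizes <- diff(c(offsets, m))
  t1 <- proc.time()[["elapsed"]]
  state <- new_fit_state(np, k)
  if (verbose) log_stage("reader setup", proc.time()[["elapsed"]] - t1)
  t2 <- proc.time()[["elapsed"]]
  for (i in seq_along(offsets)) {
    batch <- read_batch(cube, offsets[i], sizes[i])
    state <- partial_fit(state, batch)
    batch <- NULL
  }
  model <- as_ipca_model(state, method = "ipca")
  if (verbose) log_stage("fit", proc.time()[["elapsed"]] - t2,
                         detail = paste0(length(offsets), " batches"))
  model
}

#' Incremental transform: project a datacube onto fitted loadings
#'
#' For each batch, scores `= (X - mu) V^T` are computed and written at the
#' matching row offset of an on-disk float32 score matrix. With
#' `concurrency > 1`, groups of that many batches are computed in parallel
#' (forked workers) and written sequentially in row order, so the output is
#' bitwise identical to the sequential run while the resident footprint
#' scales with the concurrency level.
#'
#' @param cube a `datacube` (or path).
#' @param model an `ipca_model` with matching `n_peaks`.
#' @param out_path output path for the score matrix (`.bin` + sidecar).
#' @param batch_size rows per block; default [default_batch_size()].
#' @param concurrency number of batches computed simultaneously.
#' @param verbose log timings.
#' @return a `matrix_file` handle on the scores (`n_spectra x k`).
#' @export
transform_incremental <- function(cube, model, out_path, batch_size = NULL,
                                  concurrency = 1L, verbose = FALSE) {
  if (is.character(cube)) cube <- datacube(cube)
  if (model$n_peaks != cube$meta$n_peaks)
    stop("model has ", model$n_peaks, " peaks, cube has ", cube$meta$n_peaks)
  m <- cube$meta$n_spectra
  if (is.null(batch_size))
    batch_size <- default_batch_size(cube$meta$n_peaks, m)
  plan <- batch_plan(m, batch_size)
  Vt <- t(model$components)          # n_peaks x k
  mu <- model$mean
  t0 <- proc.time()[["elapsed"]]
  bin <- cube_bin_path(out_path)
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  score_block <- function(i) {
    x <- read_batch(cube, plan$offsets[i], plan$sizes[i])
    sweep(x, 2L, mu) %*% Vt
  }
  idx <- seq_len(plan$n_batches)
  groups <- split(idx, ceiling(idx / max(1L, as.integer(concurrency))))
  for (g in groups) {
    blocks <- if (length(g) > 1L && concurrency > 1L)
      parallel::mclapply(g, score_block, mc.cores = length(g))
    else lapply(g, score_block)
    for (b in blocks) write_f32(con, t(b))
  }
  close(con); on.exit(NULL)
  jsonlite::write_json(list(n_rows = m, n_cols = model$k, role = "scores"),
                       cube_json_path(out_path), auto_unbox = TRUE,
                       digits = NA)
  if (verbose) log_stage("transform", proc.time()[["elapsed"]] - t0,
                         detail = paste0(plan$n_batches, " batches"))
  matrix_file(bin)
}

# ---- model persistence -----------------------------------------------------

#' Save / load a fitted model
#'
#' Loadings go to a float32 matrix file (`<stem>_loadings.bin` + sidecar);
#' the scalar state (sample count, full-precision mean, singular values,
#' explained variance) goes to `<stem>.json`.
#'
#' @param model an `ipca_model`.
#' @param stem file stem (no extension).
#' @return `save_model`: the stem, invisibly. `load_model`: an `ipca_model`.
#' @export
save_model <- function(model, stem) {
  write_matrix(model$components, paste0(stem, "_loadings.bin"),
               role = "loadings")
  jsonlite::write_json(
    list(method = model$method, n_seen = model$n_seen,
         n_peaks = model$n_peaks, k = model$k,
         mean = model$mean, m2 = model$m2,
         singular_values = model$singular_values,
         explained_variance = model$explained_variance,
         explained_variance_ratio = model$explained_variance_ratio),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname save_model
#' @export
load_model <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  comp <- read_matrix(paste0(stem, "_loadings.bin"))
  structure(list(
    method = meta$method, n_seen = as.integer(meta$n_seen),
    n_peaks = as.integer(meta$n_peaks), k = as.integer(meta$k),
    mean = meta$mean, m2 = meta$m2,
    singular_values = meta$singular_values, components = comp,
    explained_variance = meta$explained_variance,
    explained_variance_ratio = meta$explained_variance_ratio),
    class = "ipca_model")
}

log_stage <- function(stage, seconds, detail = NULL) {
  msg <- sprintf("[%s] %s: %.3f s%s",
                 format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seconds,
                 if (is.null(detail)) "" else paste0(" (", detail, ")"))
  message(msg)
}
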