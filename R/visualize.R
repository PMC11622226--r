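# Hyperspectral rendering: PCs 1-3 as red/green/blue, min-max scaled per
# component over the whole dataset (one colourbar per figure, not per
# region), pixels placed on each region's row-major grid.

round_half_up <- function(x) floor(x + 0.5)

#' RGB composite of three principal components
#'
#' Maps three score columns to red, green and blue channels. Each channel is
#' `(score - min) / (max - min)` scaled to 0..255 (round half-up), with the
#' min/max taken per component over all spectra; a zero-range component
#' yields an all-zero channel. Pixels are placed on each region's
#' `width x height` grid in row-major order.
#'
#' @param scores score matrix or `matrix_file` (`n_spectra x k`).
#' @param meta the cube's `datacube_meta` (for the region grids).
#' @param components three 1-based component indices, default `c(1, 2, 3)`.
#' @param clip_quantile optional two-sided percentile (e.g. 0.01) clipped
#'   from each component before normalisation; default none.
#' @return named list, one `height x width x 3` integer array (0-255) per
#'   region.
#' @export
rgb_composite <- function(scores, meta, components = c(1, 2, 3),
                          clip_quantile = NULL) {
  if (inherits(scores, "matrix_file")) scores <- read_matrix(scores)
  if (any(components < 1) || any(components > ncol(scores)))
    stop("component indices out of range")
  if (length(components) != 3L) stop("exactly three components required")
  channels <- sapply(components, function(ci) {
    s <- scores[, ci]
    if (!is.null(clip_quantile)) {
      q <- stats::quantile(s, c(clip_quantile, 1 - clip_quantile))
      s <- pmin(pmax(s, q[1]), q[2])
    }
    rng <- max(s) - min(s)
    if (rng == 0) return(rep(0L, length(s)))
    as.integer(round_half_up((s - min(s)) / rng * 255))
  })
  out <- lapply(meta$regions, function(r) {
    if (as.integer(r$width) * as.integer(r$height) != as.integer(r$n_pixels))
      stop("region '", r$label, "' is not grid-shaped")
    rows <- (r$row_offset + 1L):(r$row_offset + r$n_pixels)
    arr <- array(0L, dim = c(r$height, r$width, 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(channels[rows, ch], nrow = r$height,
                            ncol = r$width, byrow = TRUE)
    arr
  })
  names(out) <- vapply(meta$regions, `[[`, character(1), "label")
  out
}

#' Write a composite (or any 0-255 raster array) to PNG
#'
#' @param raster `h x w x 3` array of 0-255 values.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path) {
  png::writePNG(raster / 255, target = path)
  invisible(path)
}

#' Difference heatmap between two score sets
#'
#' Renders [score_difference_percent()] on the region grids as a signed
#' percent map; the reported colourbar limits are the min/max percent
#' differences over all pixels.
#'
#' @param scores_a,scores_b score matrices or `matrix_file`s, sign-aligned.
#' @param component 1-based component index.
#' @param meta the cube's `datacube_meta`.
#' @return list with `rasters` (one `height x width` percent matrix per
#'   region) and `limits` `c(min_pct, max_pct)`.
#' @export
difference_heatmap <- function(scores_a, scores_b, component, meta) {
  d <- score_difference_percent(scores_a, scores_b, component)
  rasters <- lapply(meta$regions, function(r) {
    rows <- (r$row_offset + 1L):(r$row_offset + r$n_pixels)
    matrix(d$percent[rows], nrow = r$height, ncol = r$width, byrow = TRUE)
  })
  names(rasters) <- vapply(meta$regions, `[[`, character(1), "label")
  list(rasters = rasters, limits = c(d$min_pct, d$max_pct))
}

#' ggplot of an RGB composite region
#'
#' @param composite output of [rgb_composite()].
#' @param region region name or index (default first).
#' @return a ggplot object (geom_raster, identity fill).
#' @export
plot_rgb_composite <- function(composite, region = 1L) {
  arr <- composite[[region]]
  h <- dim(arr)[1]; w <- dim(arr)[2]
  df <- tibble::tibble(
    x = rep(seq_len(w), each = h), y = rep(seq_len(h), times = w),
    hex = grDevices::rgb(arr[, , 1] / 255, arr[, , 2] / 255, arr[, , 3] / 255))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$hex)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' ggplot of a difference heatmap region
#'
#' @param heatmap output of [difference_heatmap()].
#' @param region region name or index (default first).
#' @return a ggplot object with a diverging fill scale centred at 0%.
#' @export
plot_difference_heatmap <- function(heatmap, region = 1L) {
  mat <- heatmap$rasters[[region]]
  h <- nrow(mat); w <- ncol(mat)
  df <- tibble::tibble(
    x = rep(seq_len(w), each = h), y = rep(seq_len(h), times = w),
    pct = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$pct)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = heatmap$limits,
                                  name = "% of range") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
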