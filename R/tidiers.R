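#' Tidy a fitted PCA model
#'
#' One row per retained component: singular value, explained variance and
#' its ratio, plus the cumulative ratio.
#'
#' @param x an `ipca_model`.
#' @param ... unused.
#' @return a tibble with columns `component`, `singular_value`,
#'   `explained_variance`, `explained_variance_ratio`, `cumulative_ratio`.
#' @export
tidy.ipca_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    singular_value = x$singular_values,
    explained_variance = x$explained_variance,
    explained_variance_ratio = x$explained_variance_ratio,
    cumulative_ratio = cumsum(x$explained_variance_ratio))
}

#' One-row model summary
#'
#' @param x an `ipca_model`.
#' @param ... unused.
#' @return a one-row tibble: method, spectra seen, peaks, components, total
#'   per-feature variance, and variance fraction captured.
#' @export
glance.ipca_model <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_seen = x$n_seen, n_peaks = x$n_peaks, k = x$k,
    total_variance = sum(x$m2) / max(x$n_seen - 1L, 1L),
    captured_ratio = sum(x$explained_variance_ratio))
}

#' Tidy a comparison report
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return the per-component metrics tibble (`component`, `mse`, `r2`).
#' @export
tidy.comparison_report <- function(x, ...) x$per_component

#' Grouped-range summary of a comparison report
#'
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return tibble of mean r-squared / MSE per component range.
#' @export
glance.comparison_report <- function(x, ...) x$grouped

#' Scree plot of a fitted model
#'
#' @param object an `ipca_model`.
#' @param n_components how many leading components to show.
#' @param ... unused.
#' @return a ggplot: explained-variance ratio per component (log scale).
#' @export
autoplot.ipca_model <- function(object, n_components = min(object$k, 30L),
                                ...) {
  df <- utils::head(tidy.ipca_model(object), n_components)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained_variance_ratio)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_ratio),
                       colour = "steelblue") +
    ggplot2::labs(x = "principal component",
                  y = "explained variance ratio",
                  title = paste0("Scree (", object$method, ", ",
                                 object$n_seen, " spectra)")) +
    ggplot2::theme_minimal()
}

#' Per-component r-squared plot of a comparison report
#'
#' @param object a `comparison_report`.
#' @param ... unused.
#' @return a ggplot of r-squared against component index.
#' @export
autoplot.comparison_report <- function(object, ...) {
  ggplot2::ggplot(object$per_component,
                  ggplot2::aes(x = .data$component, y = .data$r2)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "principal component", y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
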