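#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a REML fit
#'
#' @param x A [reml_fit()] or [gblup()] object.
#' @param ... Ignored.
#' @return A tibble with one row per variance component: `term`,
#'   `estimate`, `std.error`, `proportion` (of the summed components)
#'   and `at_bound`.
#' @method tidy reml_fit
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta),
                 estimate = as.numeric(x$theta),
                 std.error = as.numeric(x$se),
                 proportion = as.numeric(x$theta) / sum(x$theta),
                 at_bound = as.logical(x$pinned))
}

#' @rdname tidy.reml_fit
#' @method glance reml_fit
#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(minus2logL = x$minus2logL, converged = x$converged,
                 iterations = max(x$trace$iteration),
                 n = x$n, n_terms = x$n_terms)
}

#' Tidy a fitted model family
#'
#' @param x A `gblup_family` from [fit_model_family()].
#' @param ... Ignored.
#' @return `tidy()`: component estimates stacked over models (columns
#'   `model`, `term`, `estimate`, `std.error`, `proportion`);
#'   `glance()`: one row per model.
#' @method tidy gblup_family
#' @export
tidy.gblup_family <- function(x, ...) {
  purrr::imap_dfr(x, function(f, nm)
    dplyr::mutate(tidy(f), model = nm, .before = 1L))
}

#' @rdname tidy.gblup_family
#' @method glance gblup_family
#' @export
glance.gblup_family <- function(x, ...) {
  purrr::imap_dfr(x, function(f, nm)
    dplyr::mutate(glance(f), model = nm, .before = 1L))
}

#' Diagnostic plots
#'
#' `autoplot.reml_fit()` shows the `-2logL` iteration trace;
#' `autoplot.grm()` a relationship-matrix heatmap;
#' `autoplot.validation_report()` per-model validation accuracy.
#'
#' @param object The object to plot.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$minus2logL)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$step)) +
    ggplot2::labs(x = "iteration", y = "-2 log restricted likelihood",
                  colour = "update") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.reml_fit
#' @method autoplot grm
#' @export
autoplot.grm <- function(object, ...) {
  df <- as.data.frame(as.table(object$K))
  names(df) <- c("row", "col", "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = object$kind,
                  title = paste0("Genomic relationship matrix (",
                                 object$recipe, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @rdname autoplot.reml_fit
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$accuracy,
                            cols = c("cor_gtv", "cor_gbv"),
                            names_to = "measure", values_to = "correlation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$correlation,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "cor(prediction, test phenotype)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
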