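#' Plot a 96-context mutation spectrum
#'
#' Standard signature-style bar chart: one bar per trinucleotide class,
#' facetted by substitution, one panel row per sample.
#'
#' @param catalog A catalog tibble.
#' @param relative Plot class fractions instead of counts?
#' @return A ggplot object.
#' @export
plot_spectrum <- function(catalog, relative = FALSE) {
  validate_catalog(catalog)
  df <- catalog |>
    dplyr::mutate(
      substitution = sub("^.\\[(.+)\\].$", "\\1", .data$context),
      trinucleotide = paste0(substr(.data$context, 1, 1),
                             substr(.data$context, 3, 3),
                             substr(.data$context, 7, 7))
    )
  if (relative) {
    df <- df |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(count = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trinucleotide, y = .data$count,
                                   fill = .data$substitution)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(sample_id ~ substitution, scales = "free_x") +
    ggplot2::labs(x = NULL, y = if (relative) "fraction" else "mutations") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5,
                                                       vjust = 0.5))
}

#' Plot per-sample signature exposures
#'
#' Stacked bars of attributed mutation counts, the display used to compare
#' AA-driven and AA-free samples.
#'
#' @param fit A `signature_fit` (raw or merged) or tidy exposure tibble.
#' @param order Optional sample ordering (e.g. the `"dendrogram_order"`
#'   attribute of [cluster_subtypes()] output).
#' @return A ggplot object.
#' @export
plot_exposures <- function(fit, order = NULL) {
  exposures <- if (inherits(fit, "signature_fit")) fit$exposures else fit
  if (!is.null(order)) {
    exposures <- dplyr::mutate(exposures,
                               sample_id = factor(.data$sample_id, levels = order))
  }
  ggplot2::ggplot(exposures,
                  ggplot2::aes(x = .data$sample_id, y = .data$exposure,
                               fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "attributed SNVs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn plot_exposures `autoplot` method for fitted exposures.
#' @param object A `signature_fit`.
#' @param ... Passed to [plot_exposures()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.signature_fit <- function(object, ...) {
  plot_exposures(object, ...)
}

#' Plot Kaplan-Meier curves
#'
#' Step curves of the product-limit estimate per group, with censoring marks.
#'
#' @param km Output of [km_estimate()], or raw survival records (in which
#'   case the estimate is computed first).
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  if (!"survival" %in% names(km)) km <- km_estimate(km)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(km, .data$n_censor > 0),
                        shape = 3, size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
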