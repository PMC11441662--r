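# ggplot2 visualizations for the main result types.

#' Plot a nodal overlap profile
#'
#' Histogram of normalized nodal entropies, with overlapping regions
#' (2+ involved modules) highlighted.
#'
#' @param object A `node_overlap` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot node_overlap
#' @export
autoplot.node_overlap <- function(object, ...) {
  d <- dplyr::filter(object, !.data$missing)
  d$overlapping <- d$n_involved >= 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$entropy, fill = .data$overlapping)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2166AC"),
                               name = ">= 2 modules") +
    ggplot2::labs(x = "normalized nodal entropy", y = "nodes",
                  title = "Module overlap across nodes") +
    ggplot2::theme_minimal()
}

#' Plot an instance ensemble
#'
#' Bar chart of the module-number frequencies across Louvain instances,
#' with the modal count marked.
#'
#' @param object An `instance_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot instance_ensemble
#' @export
autoplot.instance_ensemble <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$n_modules))) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::geom_vline(xintercept = factor(object$modal_n), linetype = 2) +
    ggplot2::labs(x = "module number", y = "instances",
                  title = sprintf("Modal module number = %d", object$modal_n)) +
    ggplot2::theme_minimal()
}

#' Plot a prediction result
#'
#' Predicted vs actual scatter of pooled out-of-fold predictions, with the
#' identity line and the accuracy annotation.
#'
#' @param object A `prediction_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_result
#' @export
autoplot.prediction_result <- function(object, ...) {
  d <- object$predictions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "actual", y = "predicted (out of fold)",
                  subtitle = sprintf("r = %.3f%s", object$r,
                                     if (!is.null(object[["p"]]))
                                       sprintf(", permutation p = %.3g", object[["p"]])
                                     else "")) +
    ggplot2::theme_minimal()
}

#' Plot a node-wise age-effect map
#'
#' Per-node t values of the selected age term, FDR-significant nodes
#' highlighted.
#'
#' @param object An `age_effect_map` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot age_effect_map
#' @export
autoplot.age_effect_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$idx <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$t,
                                  colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B"),
                                 name = "FDR significant") +
    ggplot2::labs(x = "node", y = "age-effect t value") +
    ggplot2::theme_minimal()
}
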