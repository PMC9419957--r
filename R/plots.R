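#' Plot posterior model probabilities of a model comparison
#'
#' Bar chart of the 18 posterior model probabilities, grouped by model
#' family (single timespan, adjacent pair, sinusoid, null).
#'
#' @param object A `bmc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bmc_result <- function(object, ...) {
  df <- tidy(object)
  df$family <- cut(df$model_id, c(0, 6, 11, 17, 18),
                   labels = c("single timespan", "adjacent pair",
                              "sinusoid", "null"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$model_id),
                                   y = .data$posterior_prob,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "model", y = "posterior probability",
                  fill = "family") +
    ggplot2::theme_minimal()
}

#' Plot per-timespan parameter means of a model average
#'
#' Time course of the averaged per-timespan group means for selected
#' parameters (e.g. decay and the CSD amplitude).
#'
#' @param object A `bma_result`.
#' @param parameters Character vector of parameter names (default: all
#'   significant time effects, or the first two parameters).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bma_result <- function(object, parameters = NULL, ...) {
  pn <- object$parameter_names
  if (is.null(parameters)) {
    sig <- sub("^time:", "",
               names(object$significant)[object$significant &
                                           startsWith(names(object$significant),
                                                      "time:")])
    parameters <- if (length(sig)) sig else pn[seq_len(min(2, length(pn)))]
  }
  df <- tibble::as_tibble(object$per_timespan_means, rownames = "timespan")
  df <- tidyr::pivot_longer(df, -"timespan", names_to = "parameter",
                            values_to = "mean")
  df <- dplyr::filter(df, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timespan, y = .data$mean,
                                   group = .data$parameter,
                                   colour = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "timespan", y = "posterior group mean") +
    ggplot2::theme_minimal()
}

#' Heatmap of the averaged connectivity effects
#'
#' @param bma_conn A `bma_result` over the A-matrix block.
#' @param roi_names Optional ROI names.
#' @param threshold Blank entries below this posterior probability.
#' @return A ggplot object.
#' @export
plot_connectivity <- function(bma_conn, roi_names = NULL, threshold = NULL) {
  M <- render_connectivity_matrix(bma_conn, threshold = threshold,
                                  roi_names = roi_names)
  df <- tibble::as_tibble(as.table(M), .name_repair = "minimal")
  names(df) <- c("to", "from", "value")
  df$value <- suppressWarnings(as.numeric(df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(na.value = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "from", y = "to", fill = "effect (Hz)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
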