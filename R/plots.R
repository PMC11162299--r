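#' Plot the training-loss trace of a fitted autoencoder
#'
#' @param object an `hgvae_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hgvae_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "variational loss",
                  title = "HGVAE training trace") +
    ggplot2::theme_minimal()
}

#' Plot resampled classifier metrics
#'
#' @param object a `classifier_eval` from [evaluate_classifier()].
#' @param ... unused.
#' @return a ggplot (boxplots of AUROC and AUPRC over resamples).
#' @export
autoplot.classifier_eval <- function(object, ...) {
  df <- tidyr_longer(object$resamples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::labs(y = "area under curve", x = NULL,
                  title = "Classifier performance over negative resamples") +
    ggplot2::theme_minimal()
}

# minimal long-format pivot (auroc/auprc columns)
tidyr_longer <- function(resamples) {
  dplyr::bind_rows(
    tibble::tibble(metric = "auroc", value = resamples$auroc),
    tibble::tibble(metric = "auprc", value = resamples$auprc))
}

#' Plot the size distribution of one or more complex sets
#'
#' Log-log frequency of complex sizes, the standard view of the power-law
#' shape of curated complex catalogs.
#'
#' @param ... named [complex_set()] objects.
#' @return a ggplot.
#' @export
plot_size_distribution <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  df <- purrr::map_dfr(names(sets), function(nm) {
    tb <- table(complex_sizes(sets[[nm]]))
    tibble::tibble(set = nm, size = as.integer(names(tb)),
                   count = as.integer(tb))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$count,
                                   color = .data$set)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "complex size (subunits)", y = "number of complexes") +
    ggplot2::theme_minimal()
}
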