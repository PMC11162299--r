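#' Tidy the training trace of a fitted autoencoder
#'
#' @param x an `hgvae_fit`.
#' @param ... unused.
#' @return a tibble with columns `epoch`, `loss`.
#' @export
tidy.hgvae_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a fitted autoencoder
#'
#' @param x an `hgvae_fit`.
#' @param ... unused.
#' @return a one-row tibble: n_nodes, latent_dim, mode, epochs,
#'   initial_loss, final_loss.
#' @export
glance.hgvae_fit <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes),
                 latent_dim = x$config$latent_dim,
                 mode = x$config$mode,
                 epochs = length(x$loss_trace),
                 initial_loss = x$loss_trace[1],
                 final_loss = x$loss_trace[length(x$loss_trace)])
}

#' Tidy the training trace of a complex classifier
#'
#' @param x a `complex_classifier`.
#' @param ... unused.
#' @return a tibble with columns `epoch`, `loss`.
#' @export
tidy.complex_classifier <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a complex classifier
#'
#' @param x a `complex_classifier`.
#' @param ... unused.
#' @return a one-row tibble: input_dim, layers, epochs, final_loss.
#' @export
glance.complex_classifier <- function(x, ...) {
  tibble::tibble(input_dim = x$dims[1],
                 layers = paste(x$dims[-1], collapse = "-"),
                 epochs = length(x$loss_trace),
                 final_loss = x$loss_trace[length(x$loss_trace)])
}

#' Per-resample metrics of a classifier evaluation
#'
#' @param x a `classifier_eval` from [evaluate_classifier()].
#' @param ... unused.
#' @return the resamples tibble (resample, auroc, auprc).
#' @export
tidy.classifier_eval <- function(x, ...) x$resamples

#' Mean and standard error of a classifier evaluation
#'
#' @param x a `classifier_eval` from [evaluate_classifier()].
#' @param ... unused.
#' @return the summary tibble (metric, mean, se).
#' @export
glance.classifier_eval <- function(x, ...) x$summary
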