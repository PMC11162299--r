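#' End-to-end complex prediction pipeline
#'
#' Wires the full workflow: encode sequences (conjoint triads), build the
#' clique hypergraph, train the hypergraph variational autoencoder, sample
#' negatives and train the classifier on the gold-standard complexes, then
#' mine the network for complexes.
#'
#' @param network a [ppi_network()].
#' @param catalog protein catalog covering the network nodes.
#' @param positives gold-standard [complex_set()] for classifier training.
#' @param hgvae an [hgvae_config()].
#' @param classifier a [classifier_config()].
#' @param detection a [detection_config()].
#' @param clique_min_size smallest clique used as a hyperedge.
#' @param feature_mode `"ct"` (default) or `"identity"` for the
#'   sequence-free ablation.
#' @param seed master seed; module seeds are derived from it.
#' @return list with `hypergraph`, `fit` (`hgvae_fit`), `embeddings`,
#'   `classifier`, `predicted` ([complex_set()]).
#' @export
complex_prediction_pipeline <- function(network, catalog, positives,
                                        hgvae = hgvae_config(),
                                        classifier = classifier_config(),
                                        detection = detection_config(),
                                        clique_min_size = 3,
                                        feature_mode = c("ct", "identity"),
                                        seed = 1) {
  feature_mode <- match.arg(feature_mode)
  X <- if (feature_mode == "ct") encode_catalog(catalog)
       else identity_features(network)
  if (feature_mode == "identity") hgvae$input_dim <- ncol(X)
  hgvae$seed <- seed
  classifier$seed <- seed + 1
  hg <- build_hypergraph(network, X, min_size = clique_min_size)
  fit <- train_hgvae(hg, hgvae, network = network)
  emb <- latent_embeddings(fit)
  negs <- sample_negative_complexes(positives, network,
                                    classifier$negative_ratio, seed = seed + 2)
  cls <- train_classifier(emb, positives, negs, classifier)
  pred <- detect_complexes(network, cls, emb, detection)
  list(hypergraph = hg, fit = fit, embeddings = emb,
       classifier = cls, predicted = pred)
}
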