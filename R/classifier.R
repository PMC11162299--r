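#' Embed a candidate complex by averaging member embeddings
#'
#' The complex embedding is the column-wise mean of its members' latent
#' vectors, giving a size-independent input for the classifier.
#'
#' @param embeddings node embedding matrix with protein-id rownames
#'   (e.g. from [latent_embeddings()]).
#' @param members character vector of protein identifiers.
#' @return a numeric vector of length `ncol(embeddings)`.
#' @export
complex_embedding <- function(embeddings, members) {
  members <- unique(as.character(members))
  missing <- setdiff(members, rownames(embeddings))
  if (length(missing) > 0)
    stop("members absent from embedding table: ", paste(missing, collapse = ", "))
  colMeans(embeddings[members, , drop = FALSE])
}

# embeddings for a list of member sets, one row each
embed_member_sets <- function(embeddings, sets) {
  t(vapply(sets, function(m) complex_embedding(embeddings, m),
           numeric(ncol(embeddings))))
}

#' Sample non-complexes matching the positive size distribution
#'
#' Draws `round(ratio * n_positives)` random protein sets from the network
#' nodes. Each set's size is drawn with replacement from the empirical size
#' distribution of the positives (so the non-complex sizes follow the same
#' power-law shape), and its members uniformly without replacement. A draw
#' identical (as a set) to any positive is rejected and redrawn.
#'
#' @param positives a [complex_set()] of gold-standard complexes.
#' @param network a [ppi_network()] supplying the node universe.
#' @param ratio negatives per positive (default 5).
#' @param seed RNG seed.
#' @return a [complex_set()] of non-complexes (score `NA`).
#' @export
sample_negative_complexes <- function(positives, network, ratio = 5, seed = 1) {
  stopifnot(nrow(positives) > 0, ratio > 0)
  nodes <- network$nodes
  sizes <- complex_sizes(positives)
  if (max(sizes) > length(nodes))
    stop("positive complex larger than the node universe")
  pos_keys <- vapply(positives$members, paste, character(1), collapse = "\r")
  n_out <- round(ratio * nrow(positives))
  set.seed(seed)
  out <- vector("list", n_out)
  for (i in seq_len(n_out)) {
    repeat {
      k <- sample(sizes, 1)
      mem <- sort(sample(nodes, k))
      if (!(paste(mem, collapse = "\r") %in% pos_keys)) break
    }
    out[[i]] <- mem
  }
  complex_set(out, ids = sprintf("N%04d", seq_len(n_out)))
}

#' Configuration for the complex classifier
#'
#' A feed-forward network with four weight layers: the input complex
#' embedding passes through three hidden layers (`layer_sizes`), each
#' followed by batch normalization, ReLU and dropout, and a final linear
#' layer with a sigmoid output. Trained with binary cross-entropy and Adam.
#'
#' @param layer_sizes widths of the three hidden layers.
#' @param dropout_rate dropout probability between layers.
#' @param batch_norm use batch normalization?
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size (capped at the number of examples).
#' @param negative_ratio negatives drawn per positive (default 5).
#' @param seed RNG seed.
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(layer_sizes = c(64, 32, 16), dropout_rate = 0.2,
                              batch_norm = TRUE, learning_rate = 1e-3,
                              epochs = 150, batch_size = 64,
                              negative_ratio = 5, seed = 1) {
  stopifnot(length(layer_sizes) == 3, negative_ratio > 0)
  structure(list(layer_sizes = layer_sizes, dropout_rate = dropout_rate,
                 batch_norm = batch_norm, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size,
                 negative_ratio = negative_ratio, seed = seed),
            class = "classifier_config")
}

#' Train the complex classifier
#'
#' Positives and negatives are embedded with [complex_embedding()] and fed
#' to the 4-layer network. Reproducible under `config$seed`.
#'
#' @param embeddings node embedding matrix with protein-id rownames.
#' @param positives,negatives [complex_set()] objects.
#' @param config a [classifier_config()].
#' @return an object of class `complex_classifier` holding the trained
#'   parameters, batch-norm running statistics, config and loss trace.
#' @export
train_classifier <- function(embeddings, positives, negatives,
                             config = classifier_config()) {
  if (nrow(positives) == 0 || nrow(negatives) == 0)
    stop("both classes need at least one example")
  X <- rbind(embed_member_sets(embeddings, positives$members),
             embed_member_sets(embeddings, negatives$members))
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negatives)))
  fit_mlp(X, y, config)
}

# ---- internal MLP ----------------------------------------------------------

fit_mlp <- function(X, y, config) {
  set.seed(config$seed)
  # standardize inputs; complex embeddings can live on a very small scale
  f_mean <- colMeans(X)
  f_sd <- pmax(apply(X, 2, stats::sd), 1e-8)
  X <- sweep(sweep(X, 2, f_mean), 2, f_sd, `/`)
  dims <- c(ncol(X), config$layer_sizes, 1L)
  L <- length(dims) - 1L          # 4 weight layers
  params <- list()
  for (l in seq_len(L)) {
    params[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- numeric(dims[l + 1])
    if (config$batch_norm && l < L) {
      params[[paste0("g", l)]] <- rep(1, dims[l + 1])
      params[[paste0("be", l)]] <- numeric(dims[l + 1])
    }
  }
  running <- lapply(seq_len(L - 1), function(l)
    list(mean = numeric(dims[l + 1]), var = rep(1, dims[l + 1])))
  st <- adam_init(params)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  trace <- numeric(config$epochs)
  tstep <- 0
  momentum <- 0.9
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_seen <- 0
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1, n)]
      if (length(idx) < 2 && config$batch_norm) next  # BN needs >= 2 rows
      fb <- mlp_batch(params, running, X[idx, , drop = FALSE], y[idx],
                      config, train = TRUE)
      if (config$batch_norm) {
        running <- lapply(seq_len(L - 1), function(l) {
          list(mean = momentum * running[[l]]$mean + (1 - momentum) * fb$bn_mean[[l]],
               var = momentum * running[[l]]$var + (1 - momentum) * fb$bn_var[[l]])
        })
      }
      tstep <- tstep + 1
      upd <- adam_step(params, fb$grads, st, config$learning_rate, tstep)
      params <- upd$params
      st <- upd$state
      ep_loss <- ep_loss + fb$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    trace[ep] <- ep_loss / max(n_seen, 1)
  }
  if (config$batch_norm) {
    # re-estimate batch-norm population statistics on the full training set
    # (running averages lag the final weights, which matters when the
    # per-feature scale is tiny)
    cfg0 <- config
    cfg0$dropout_rate <- 0
    pop <- mlp_batch(params, running, X, y, cfg0, train = TRUE)
    running <- lapply(seq_len(L - 1), function(l)
      list(mean = pop$bn_mean[[l]], var = pop$bn_var[[l]]))
  }
  structure(list(params = params, running = running, config = config,
                 dims = dims, loss_trace = trace,
                 feature_mean = f_mean, feature_sd = f_sd),
            class = "complex_classifier")
}

# forward (and optional backward) pass over one batch
mlp_batch <- function(params, running, Xb, yb = NULL, config, train = FALSE) {
  L <- length(config$layer_sizes) + 1L
  slopeB <- nrow(Xb)
  act <- Xb
  cache <- list()
  bn_mean <- bn_var <- vector("list", L - 1)
  bneps <- 1e-5
  for (l in seq_len(L - 1)) {
    U <- sweep(act %*% params[[paste0("W", l)]], 2, params[[paste0("b", l)]], `+`)
    if (config$batch_norm) {
      if (train) {
        mu <- colMeans(U)
        va <- colMeans(sweep(U, 2, mu)^2)
      } else {
        mu <- running[[l]]$mean
        va <- running[[l]]$var
      }
      bn_mean[[l]] <- mu
      bn_var[[l]] <- va
      Uc <- sweep(U, 2, mu)
      inv <- 1 / sqrt(va + bneps)
      xhat <- sweep(Uc, 2, inv, `*`)
      Bn <- sweep(sweep(xhat, 2, params[[paste0("g", l)]], `*`), 2,
                  params[[paste0("be", l)]], `+`)
    } else {
      Bn <- U
      xhat <- Uc <- inv <- NULL
    }
    Hl <- pmax(Bn, 0)
    if (train && config$dropout_rate > 0) {
      mk <- matrix(rbinom(length(Hl), 1, 1 - config$dropout_rate),
                   nrow(Hl), ncol(Hl)) / (1 - config$dropout_rate)
      Hl <- Hl * mk
    } else mk <- NULL
    cache[[l]] <- list(input = act, U = U, Uc = Uc, inv = inv, xhat = xhat,
                       Bn = Bn, mask = mk)
    act <- Hl
  }
  logits <- as.numeric(sweep(act %*% params[[paste0("W", L)]], 2,
                             params[[paste0("b", L)]], `+`))
  prob <- sigmoid(logits)
  if (!train)
    return(list(prob = prob))
  loss <- mean(yb * softplus(-logits) + (1 - yb) * softplus(logits))
  # backward
  grads <- list()
  dlogits <- (prob - yb) / slopeB
  grads[[paste0("W", L)]] <- crossprod(act, matrix(dlogits))
  grads[[paste0("b", L)]] <- sum(dlogits)
  dact <- matrix(dlogits) %*% t(params[[paste0("W", L)]])
  for (l in rev(seq_len(L - 1))) {
    cc <- cache[[l]]
    if (!is.null(cc$mask)) dact <- dact * cc$mask
    dBn <- dact * (cc$Bn > 0)
    if (config$batch_norm) {
      g <- params[[paste0("g", l)]]
      grads[[paste0("g", l)]] <- colSums(dBn * cc$xhat)
      grads[[paste0("be", l)]] <- colSums(dBn)
      dxhat <- sweep(dBn, 2, g, `*`)
      B <- nrow(dBn)
      # standard batch-norm backward, fused form
      dU <- sweep(dxhat -
                    matrix(colMeans(dxhat), B, ncol(dxhat), byrow = TRUE) -
                    sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), `*`),
                  2, cc$inv, `*`)
    } else {
      dU <- dBn
    }
    grads[[paste0("W", l)]] <- crossprod(cc$input, dU)
    grads[[paste0("b", l)]] <- colSums(dU)
    dact <- dU %*% t(params[[paste0("W", l)]])
  }
  list(loss = loss, grads = grads, bn_mean = bn_mean, bn_var = bn_var)
}

# ---- scoring ---------------------------------------------------------------

# batch inference over rows of an embedding matrix
score_embedding_matrix <- function(classifier, Xb) {
  Xb <- sweep(sweep(Xb, 2, classifier$feature_mean), 2,
              classifier$feature_sd, `/`)
  mlp_batch(classifier$params, classifier$running, Xb,
            config = classifier$config, train = FALSE)$prob
}

#' Score member sets with a classifier
#'
#' Generic used throughout detection and evaluation; methods exist for
#' trained classifiers ([train_classifier()]) and for the subset oracle
#' ([make_subset_oracle()]). Inference is deterministic: dropout off,
#' batch normalization using running statistics.
#'
#' @param classifier a scoring object.
#' @param embeddings node embedding matrix.
#' @param sets list of character vectors of protein identifiers.
#' @return numeric vector of probabilities, one per set.
#' @export
score_member_sets <- function(classifier, embeddings, sets) {
  UseMethod("score_member_sets")
}

#' @export
score_member_sets.complex_classifier <- function(classifier, embeddings, sets) {
  if (length(sets) == 0) return(numeric(0))
  score_embedding_matrix(classifier, embed_member_sets(embeddings, sets))
}

#' Score one candidate complex
#'
#' @inheritParams score_member_sets
#' @param members character vector of protein identifiers.
#' @return probability in (0, 1) that the set forms a complex.
#' @export
score_complex <- function(classifier, embeddings, members) {
  score_member_sets(classifier, embeddings, list(unique(as.character(members))))[1]
}

#' An oracle classifier for planted-complex benchmarks
#'
#' Scores a set `high` when it is a subset of (or equal to) some reference
#' complex and `low` otherwise. Used to validate the detection algorithm
#' independently of any learned model.
#'
#' @param reference a [complex_set()] of planted complexes.
#' @param high,low scores for subset / non-subset sets.
#' @return an object of class `subset_oracle` usable wherever a classifier
#'   is accepted.
#' @export
make_subset_oracle <- function(reference, high = 1, low = 0) {
  structure(list(reference = lapply(reference$members, as.character),
                 high = high, low = low),
            class = "subset_oracle")
}

#' @export
score_member_sets.subset_oracle <- function(classifier, embeddings, sets) {
  vapply(sets, function(mem) {
    hit <- any(vapply(classifier$reference,
                      function(r) all(mem %in% r), logical(1)))
    if (hit) classifier$high else classifier$low
  }, numeric(1))
}

# ---- evaluation ------------------------------------------------------------

#' Area under the precision-recall curve
#'
#' Step-function integral of precision over recall, sweeping the score
#' threshold over the observed scores (ties handled jointly).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUPRC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  keep <- c(diff(sc) != 0, TRUE)   # threshold at each distinct score
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1 - lab)[keep]
  n_pos <- sum(lab)
  if (n_pos == 0 || n_pos == length(lab)) stop("need both classes")
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Resampled evaluation of the complex classifier
#'
#' For each resample a fresh negative set (same 5:1 protocol as training)
#' is drawn, all complexes are scored, and AUROC/AUPRC are computed.
#'
#' @param classifier a trained classifier (or oracle).
#' @param embeddings node embedding matrix.
#' @param positives gold-standard [complex_set()].
#' @param network a [ppi_network()] for negative sampling.
#' @param n_resamples number of fresh negative draws (default 30).
#' @param ratio negatives per positive.
#' @param seed RNG seed.
#' @return an object of class `classifier_eval`: list with `resamples`
#'   (tibble: resample, auroc, auprc) and `summary` (tibble: metric, mean,
#'   se). `tidy()` returns the resamples, `glance()` the summary.
#' @export
evaluate_classifier <- function(classifier, embeddings, positives, network,
                                n_resamples = 30, ratio = 5, seed = 1) {
  stopifnot(n_resamples >= 1)
  pos_scores <- score_member_sets(classifier, embeddings, positives$members)
  rows <- purrr::map_dfr(seq_len(n_resamples), function(r) {
    negs <- sample_negative_complexes(positives, network, ratio,
                                      seed = seed + r)
    neg_scores <- score_member_sets(classifier, embeddings, negs$members)
    scores <- c(pos_scores, neg_scores)
    labels <- c(rep(1, length(pos_scores)), rep(0, length(neg_scores)))
    tibble::tibble(resample = r,
                   auroc = roc_auc(scores, labels),
                   auprc = pr_auc(scores, labels))
  })
  summ <- tibble::tibble(
    metric = c("auroc", "auprc"),
    mean = c(mean(rows$auroc), mean(rows$auprc)),
    se = c(stats::sd(rows$auroc), stats::sd(rows$auprc)) / sqrt(n_resamples))
  structure(list(resamples = rows, summary = summ), class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat("<classifier_eval> ", nrow(x$resamples), " resamples\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' K-fold cross-validated classifier evaluation
#'
#' Splits positives and a fresh negative draw into `k` folds; for each fold
#' a classifier is trained on the remaining folds and AUROC/AUPRC computed
#' on the held-out fold. Folds where the held-out part has a single class
#' are skipped with a warning.
#'
#' @param embeddings node embedding matrix.
#' @param positives gold-standard [complex_set()].
#' @param network a [ppi_network()].
#' @param config a [classifier_config()].
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return a tibble with one row per evaluated fold: fold, auroc, auprc.
#' @export
cross_validate_classifier <- function(embeddings, positives, network,
                                      config = classifier_config(), k = 5,
                                      seed = 1) {
  negs <- sample_negative_complexes(positives, network,
                                    config$negative_ratio, seed = seed)
  sets <- c(positives$members, negs$members)
  y <- c(rep(1, nrow(positives)), rep(0, nrow(negs)))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = length(y)))
  out <- list()
  for (f in seq_len(k)) {
    te <- fold == f
    if (length(unique(y[te])) < 2 || length(unique(y[!te])) < 2) {
      warning("fold ", f, " degenerate; skipped")
      next
    }
    cfg <- config
    cfg$seed <- seed + f
    cls <- fit_mlp(embed_member_sets(embeddings, sets[!te]), y[!te], cfg)
    sc <- score_member_sets(cls, embeddings, sets[te])
    out[[length(out) + 1]] <- tibble::tibble(
      fold = f, auroc = roc_auc(sc, y[te]), auprc = pr_auc(sc, y[te]))
  }
  dplyr::bind_rows(out)
}
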