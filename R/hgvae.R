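#' Configuration for the hypergraph variational autoencoder
#'
#' The encoder stacks two hypergraph-convolution layers: the first maps the
#' node features (343-dim conjoint-triad vectors by default) to
#' `hidden_dim` with a ReLU; the second forks into two linear heads
#' producing the per-node Gaussian mean and log-variance of dimension
#' `latent_dim`. Hyperedge embeddings are attention-pooled from member
#' latents through a two-layer LeakyReLU projection of width `proj_dim`,
#' and an inner-product decoder reconstructs the incidence matrix.
#'
#' @param input_dim dimension of the node feature matrix (343 for CT).
#' @param hidden_dim width of the first convolution layer.
#' @param latent_dim dimension `d` of the latent embedding.
#' @param proj_dim width of the attention projection.
#' @param learning_rate Adam learning rate.
#' @param epochs number of full-batch gradient steps.
#' @param dropout_rate dropout on the hidden layer during training.
#' @param leaky_slope negative slope of every LeakyReLU.
#' @param pos_weight_mode `"auto"` weights the positive (1) entries of the
#'   incidence matrix by `#zeros/#ones` in the reconstruction loss so that a
#'   sparse `H` cannot be fit by predicting all zeros; `"none"` disables it.
#' @param mode `"hypergraph"` (default), `"no_pin"` (identity propagation:
#'   topology ablation, sequence features only), or `"vgae"` (pairwise
#'   graph autoencoder on the plain adjacency, the conventional-GCN
#'   ablation).
#' @param seed RNG seed controlling initialization and sampling.
#' @return a list of class `hgvae_config`.
#' @export
hgvae_config <- function(input_dim = 343, hidden_dim = 256, latent_dim = 100,
                         proj_dim = 64, learning_rate = 1e-3, epochs = 200,
                         dropout_rate = 0, leaky_slope = 0.01,
                         pos_weight_mode = c("auto", "none"),
                         mode = c("hypergraph", "no_pin", "vgae"),
                         seed = 1) {
  stopifnot(latent_dim >= 1, epochs >= 1, learning_rate > 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_dim = input_dim, hidden_dim = hidden_dim,
                 latent_dim = latent_dim, proj_dim = proj_dim,
                 learning_rate = learning_rate, epochs = epochs,
                 dropout_rate = dropout_rate, leaky_slope = leaky_slope,
                 pos_weight_mode = match.arg(pos_weight_mode),
                 mode = match.arg(mode), seed = seed),
            class = "hgvae_config")
}

#' One hypergraph-convolution layer
#'
#' Computes `ReLU(A %*% X_in %*% theta)` where `A` is the normalized
#' propagation operator from [propagation_operator()]. The final encoder
#' layer emitting the Gaussian parameters omits the ReLU
#' (`activation = FALSE`).
#'
#' @param X_in input node matrix (`n x d_l`).
#' @param A propagation operator (`n x n`).
#' @param theta parameter matrix (`d_l x d_{l+1}`).
#' @param activation apply the ReLU?
#' @return an `n x d_{l+1}` matrix.
#' @export
hgnn_layer <- function(X_in, A, theta, activation = TRUE) {
  if (ncol(A) != nrow(X_in) || ncol(X_in) != nrow(theta))
    stop("shape mismatch in hgnn_layer")
  out <- A %*% X_in %*% theta
  if (activation) out <- pmax(out, 0)
  out
}

#' Draw a latent sample by reparameterization
#'
#' `z = mu + exp(log_var / 2) * eps` with `eps` i.i.d. standard normal, so
#' the sampling is differentiable in `(mu, log_var)`.
#'
#' @param mu,log_var matrices of equal shape.
#' @param seed optional seed for the draw; `NULL` uses the current RNG
#'   state.
#' @return a matrix shaped like `mu`.
#' @export
reparameterize <- function(mu, log_var, seed = NULL) {
  stopifnot(all(dim(mu) == dim(log_var)))
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(log_var / 2) * eps
}

#' Attention-pool node latents into hyperedge embeddings
#'
#' Each member latent is scored by a two-layer LeakyReLU projection down to
#' a scalar; a softmax over the members of each hyperedge gives attention
#' weights, and the hyperedge embedding is the LeakyReLU of the
#' attention-weighted sum of member latents.
#'
#' @param z node latent matrix (`|V| x d`), rows aligned with `hg$nodes`.
#' @param hg a `protein_hypergraph`.
#' @param proj_params list with `W1` (`p x d`), `b1` (length `p`), `w2`
#'   (length `p`), `b2` (scalar).
#' @param slope LeakyReLU negative slope.
#' @return list with `hyperedge_embed` (`|E| x d`) and `attention` (list of
#'   per-hyperedge weight vectors, each non-negative and summing to 1).
#' @export
hyperedge_pool <- function(z, hg, proj_params, slope = 0.01) {
  he <- hg$hyperedges
  if (any(lengths(he) == 0)) stop("empty hyperedge")
  d <- ncol(z)
  s <- node_attention_scores(z, proj_params, slope)$s
  m <- length(he)
  E <- matrix(0, m, d)
  att <- vector("list", m)
  for (k in seq_len(m)) {
    mem <- he[[k]]
    a <- softmax_vec(s[mem])
    u <- as.numeric(crossprod(z[mem, , drop = FALSE], a))
    E[k, ] <- leaky_relu(u, slope)
    att[[k]] <- a
  }
  list(hyperedge_embed = E, attention = att)
}

# scalar attention score per node plus the intermediates needed for backprop
node_attention_scores <- function(z, pp, slope) {
  P1 <- sweep(z %*% t(pp$W1), 2, pp$b1, `+`)
  P1a <- leaky_relu(P1, slope)
  Sc <- as.numeric(P1a %*% pp$w2) + pp$b2
  list(P1 = P1, P1a = P1a, Sc = Sc, s = leaky_relu(Sc, slope))
}

#' Inner-product decoder for the incidence matrix
#'
#' `H_hat[i, j] = sigmoid(z_i . e_j)`: the probability that node `i`
#' belongs to hyperedge `j`.
#'
#' @param z node latent matrix (`|V| x d`).
#' @param hyperedge_embed hyperedge embedding matrix (`|E| x d`).
#' @return a `|V| x |E|` matrix of probabilities.
#' @export
hgvae_decode <- function(z, hyperedge_embed) {
  if (ncol(z) != ncol(hyperedge_embed)) stop("latent dimensions differ")
  sigmoid(z %*% t(hyperedge_embed))
}

#' Variational loss: reconstruction + KL
#'
#' The minimized objective is the mean (optionally positive-weighted)
#' binary cross-entropy of the reconstructed incidence probabilities
#' against `H`, plus the closed-form KL divergence of the per-node Gaussian
#' posterior from the standard-normal prior,
#' `KL = sum(mu^2 + sigma^2 - 1 - log sigma^2) / (2 n)`.
#'
#' @param H observed binary incidence matrix.
#' @param H_hat reconstructed probabilities (same shape).
#' @param mu,log_var Gaussian posterior parameters.
#' @param pos_weight multiplier on the positive-entry term of the BCE.
#' @return a scalar loss.
#' @export
elbo_loss <- function(H, H_hat, mu, log_var, pos_weight = 1) {
  H <- as.matrix(H)
  H_hat <- as.matrix(H_hat)
  stopifnot(all(dim(H) == dim(H_hat)))
  eps <- 1e-7
  if (any(H_hat <= 0 | H_hat >= 1)) {
    message("clamping reconstruction probabilities to [", eps, ", 1-", eps, "]")
    H_hat <- pmin(pmax(H_hat, eps), 1 - eps)
  }
  rec <- -mean(pos_weight * H * log(H_hat) + (1 - H) * log(1 - H_hat))
  kl <- sum(mu^2 + exp(log_var) - 1 - log_var) / (2 * nrow(mu))
  rec + kl
}

#' Encode a hypergraph with given parameters
#'
#' Deterministic forward pass of the two-layer encoder; no latent sampling.
#'
#' @param hg a `protein_hypergraph`.
#' @param params parameter list as in an [train_hgvae()] fit.
#' @param config the `hgvae_config` used at training time.
#' @param network the PPI network; required for `mode = "vgae"`.
#' @return list with `mu` and `log_var` (`|V| x latent_dim`, protein-id
#'   rownames).
#' @export
hgvae_encode <- function(hg, params, config, network = NULL) {
  A <- encoder_operator(hg, config, network)
  H1 <- pmax(A %*% hg$X %*% params$W0, 0)
  AH1 <- A %*% H1
  mu <- AH1 %*% params$Wmu
  lv <- AH1 %*% params$Wlv
  rownames(mu) <- rownames(lv) <- hg$nodes
  list(mu = mu, log_var = lv)
}

encoder_operator <- function(hg, config, network = NULL) {
  n <- length(hg$nodes)
  switch(config$mode,
    hypergraph = propagation_operator(hg),
    no_pin = diag(n),
    vgae = {
      if (is.null(network)) stop("mode 'vgae' needs the PPI network")
      Adj <- adjacency_with_loops(network, hg$nodes)
      dg <- rowSums(Adj)
      di <- 1 / sqrt(dg)
      di * sweep(Adj, 2, di, `*`)
    })
}

adjacency_with_loops <- function(network, nodes) {
  n <- length(nodes)
  Adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges) > 0) {
    i <- match(network$edges$from, nodes)
    j <- match(network$edges$to, nodes)
    Adj[cbind(i, j)] <- 1
    Adj[cbind(j, i)] <- 1
  }
  diag(Adj) <- 1
  Adj
}

#' One-hot identity features for the sequence-free ablation
#'
#' Replaces the conjoint-triad feature matrix with an `n x n` identity so
#' the model sees only network topology.
#'
#' @param network a [ppi_network()].
#' @return an identity matrix with protein-id dimnames.
#' @export
identity_features <- function(network) {
  n <- length(network$nodes)
  diag(1, n, n) |> `dimnames<-`(list(network$nodes, network$nodes))
}

#' Train the hypergraph variational autoencoder
#'
#' Full-batch gradient optimization (Adam) of the variational objective:
#' weighted binary cross-entropy of the reconstructed incidence matrix plus
#' the KL penalty toward the standard-normal prior. One reparameterized
#' latent sample is drawn per epoch. Gradients are computed analytically;
#' the run is fully reproducible under `config$seed`.
#'
#' The canonical downstream node embedding is the posterior mean `mu`.
#'
#' @param hg a `protein_hypergraph` from [build_hypergraph()].
#' @param config an [hgvae_config()].
#' @param network the PPI network (only needed for `mode = "vgae"`).
#' @return an object of class `hgvae_fit`: list with `params`, `config`,
#'   `loss_trace`, `latent` (the `mu` matrix with protein-id rownames), and
#'   `latent_state` (`mu`, `log_var`, `z`, `hyperedge_embed`, `attention`
#'   from a final deterministic pass).
#' @export
train_hgvae <- function(hg, config = hgvae_config(), network = NULL) {
  stopifnot(inherits(hg, "protein_hypergraph"))
  if (ncol(hg$X) != config$input_dim)
    stop("config$input_dim (", config$input_dim, ") != ncol(X) (", ncol(hg$X), ")")
  set.seed(config$seed)
  slope <- config$leaky_slope
  n <- length(hg$nodes)
  d <- config$latent_dim
  A <- encoder_operator(hg, config, network)
  vgae <- config$mode == "vgae"
  target <- if (vgae) adjacency_with_loops(network, hg$nodes) else as.matrix(hg$H)
  m <- ncol(target)
  n_pos <- sum(target)
  pw <- if (config$pos_weight_mode == "auto") (length(target) - n_pos) / n_pos else 1

  X <- hg$X
  AX <- A %*% X
  params <- list(W0 = glorot(config$input_dim, config$hidden_dim),
                 Wmu = glorot(config$hidden_dim, d),
                 Wlv = glorot(config$hidden_dim, d))
  if (!vgae) {
    params$P_W1 <- glorot(config$proj_dim, d)
    params$P_b1 <- numeric(config$proj_dim)
    params$P_w2 <- as.numeric(glorot(config$proj_dim, 1))
    params$P_b2 <- 0
  }
  st <- adam_init(params)
  he <- hg$hyperedges
  trace <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    if (config$dropout_rate > 0) {
      mask <- matrix(rbinom(n * config$hidden_dim, 1, 1 - config$dropout_rate),
                     n, config$hidden_dim) / (1 - config$dropout_rate)
    } else mask <- NULL
    Eps <- matrix(rnorm(n * d), n, d)
    fb <- hgvae_grad_step(params, AX, A, target, pw, he, Eps, slope,
                          vgae = vgae, mask = mask)
    if (!is.finite(fb$loss))
      stop("non-finite loss at epoch ", ep)
    trace[ep] <- fb$loss
    upd <- adam_step(params, fb$grads, st, config$learning_rate, ep)
    params <- upd$params
    st <- upd$state
  }

  enc <- hgvae_encode(hg, params, config, network)
  z_final <- reparameterize(enc$mu, enc$log_var, seed = config$seed)
  rownames(z_final) <- hg$nodes
  if (!vgae) {
    pool <- hyperedge_pool(z_final, hg,
                           list(W1 = params$P_W1, b1 = params$P_b1,
                                w2 = params$P_w2, b2 = params$P_b2), slope)
  } else {
    pool <- list(hyperedge_embed = NULL, attention = NULL)
  }
  structure(list(params = params, config = config, loss_trace = trace,
                 latent = enc$mu,
                 latent_state = list(mu = enc$mu, log_var = enc$log_var,
                                     z = z_final,
                                     hyperedge_embed = pool$hyperedge_embed,
                                     attention = pool$attention),
                 nodes = hg$nodes),
            class = "hgvae_fit")
}

# One full forward + analytic-backward pass of the variational objective.
# `Eps` is the reparameterization noise (supplied so the pass is a pure,
# finite-difference-checkable function of `params`). Returns the loss, its
# gradients wrt every parameter, and the forward intermediates.
hgvae_grad_step <- function(params, AX, A, target, pw, he, Eps, slope,
                            vgae = FALSE, mask = NULL) {
  n <- nrow(AX)
  # ---- forward ----
  H1pre <- AX %*% params$W0
  H1 <- pmax(H1pre, 0)
  if (!is.null(mask)) H1 <- H1 * mask
  AH1 <- A %*% H1
  Mu <- AH1 %*% params$Wmu
  Lv <- AH1 %*% params$Wlv
  Sig <- exp(Lv / 2)
  Z <- Mu + Sig * Eps
  if (vgae) {
    Logits <- Z %*% t(Z)
  } else {
    m <- length(he)
    d <- ncol(Z)
    pp <- list(W1 = params$P_W1, b1 = params$P_b1,
               w2 = params$P_w2, b2 = params$P_b2)
    sc <- node_attention_scores(Z, pp, slope)
    U <- matrix(0, m, d)
    att <- vector("list", m)
    for (k in seq_len(m)) {
      mem <- he[[k]]
      a <- softmax_vec(sc$s[mem])
      U[k, ] <- as.numeric(crossprod(Z[mem, , drop = FALSE], a))
      att[[k]] <- a
    }
    E <- leaky_relu(U, slope)
    Logits <- Z %*% t(E)
  }
  rec <- mean(pw * target * softplus(-Logits) + (1 - target) * softplus(Logits))
  kl <- sum(Mu^2 + exp(Lv) - 1 - Lv) / (2 * n)
  loss <- rec + kl

  # ---- backward ----
  dLogits <- (sigmoid(Logits) * ((1 - target) + pw * target) - pw * target) /
    length(target)
  if (vgae) {
    dZ <- (dLogits + t(dLogits)) %*% Z
    grads <- list()
  } else {
    dZ <- dLogits %*% E
    GE <- crossprod(dLogits, Z)          # m x d, gradient wrt E
    dU <- GE * leaky_relu_grad(U, slope)
    ds <- numeric(n)
    for (k in seq_len(m)) {
      mem <- he[[k]]
      a <- att[[k]]
      du <- dU[k, ]
      if (length(mem) == 1L) {
        dZ[mem, ] <- dZ[mem, ] + du
      } else {
        da <- as.numeric(Z[mem, , drop = FALSE] %*% du)
        dZ[mem, ] <- dZ[mem, ] + outer(a, du)
        ds[mem] <- ds[mem] + a * (da - sum(a * da))
      }
    }
    dSc <- ds * leaky_relu_grad(sc$Sc, slope)
    dP1a <- outer(dSc, pp$w2)
    dP1 <- dP1a * leaky_relu_grad(sc$P1, slope)
    grads <- list(P_W1 = crossprod(dP1, Z),
                  P_b1 = colSums(dP1),
                  P_w2 = as.numeric(crossprod(sc$P1a, dSc)),
                  P_b2 = sum(dSc))
    dZ <- dZ + dP1 %*% pp$W1
  }
  dMu <- dZ + Mu / n
  dLv <- dZ * Eps * 0.5 * Sig + (exp(Lv) - 1) / (2 * n)
  grads$Wmu <- crossprod(AH1, dMu)
  grads$Wlv <- crossprod(AH1, dLv)
  dAH1 <- dMu %*% t(params$Wmu) + dLv %*% t(params$Wlv)
  dH1 <- A %*% dAH1                      # A is symmetric
  if (!is.null(mask)) dH1 <- dH1 * mask
  dH1pre <- dH1 * (H1pre > 0)
  grads$W0 <- crossprod(AX, dH1pre)
  list(loss = loss, rec = rec, kl = kl, grads = grads, Z = Z)
}

#' @export
print.hgvae_fit <- function(x, ...) {
  cat("<hgvae_fit> ", length(x$nodes), " nodes, latent dim ",
      x$config$latent_dim, ", mode '", x$config$mode, "'\n",
      "final loss: ", format(x$loss_trace[length(x$loss_trace)], digits = 6),
      " after ", length(x$loss_trace), " epochs\n", sep = "")
  invisible(x)
}

#' Extract the node embedding table from a fitted autoencoder
#'
#' @param fit an `hgvae_fit`.
#' @return the posterior-mean matrix (`|V| x d`) with protein-id rownames.
#' @export
latent_embeddings <- function(fit) {
  stopifnot(inherits(fit, "hgvae_fit"))
  fit$latent
}

#' Write / read a node embedding table as TSV
#'
#' @param embeddings a numeric matrix with protein-id rownames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_embeddings <- function(embeddings, path) {
  df <- data.frame(protein_id = rownames(embeddings), embeddings,
                   check.names = FALSE)
  colnames(df)[-1] <- paste0("d", seq_len(ncol(embeddings)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
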