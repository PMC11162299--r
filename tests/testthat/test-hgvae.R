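make_toy_hg <- function(seed = 1, n = 10, p = 0.4) {
  net <- random_network(n, p, seed)
  X <- matrix(abs(rnorm(n * 6)), n, 6, dimnames = list(net$nodes, NULL))
  build_hypergraph(net, X, min_size = 2)
}

test_that("hgnn_layer reduces to its matrix-product definition", {
  X <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(hgnn_layer(X, diag(4), diag(3)), X)
  expect_equal(hgnn_layer(X, diag(4), matrix(0, 3, 2)), matrix(0, 4, 2))

  set.seed(8)
  hg <- make_toy_hg(3)
  A <- propagation_operator(hg)
  theta <- matrix(rnorm(6 * 2), 6, 2)
  out <- hgnn_layer(hg$X, A, theta)
  # explicit step-by-step oracle
  manual <- A %*% (hg$X %*% theta)
  manual[manual < 0] <- 0
  expect_equal(out, manual, tolerance = 1e-12)
  expect_error(hgnn_layer(X, diag(3), diag(3)), "shape")
})

test_that("encoding with zero parameters gives the standard-normal posterior", {
  hg <- make_toy_hg(4)
  params <- list(W0 = matrix(0, 6, 5), Wmu = matrix(0, 5, 2),
                 Wlv = matrix(0, 5, 2))
  enc <- hgvae_encode(hg, params, hgvae_config(input_dim = 6, hidden_dim = 5,
                                               latent_dim = 2))
  expect_equal(unname(enc$mu), matrix(0, 10, 2))
  expect_equal(unname(enc$log_var), matrix(0, 10, 2))
  # deterministic: repeat call agrees exactly
  set.seed(11)
  params2 <- list(W0 = matrix(rnorm(30), 6, 5), Wmu = matrix(rnorm(10), 5, 2),
                  Wlv = matrix(rnorm(10), 5, 2))
  cfg <- hgvae_config(input_dim = 6, hidden_dim = 5, latent_dim = 2)
  expect_identical(hgvae_encode(hg, params2, cfg), hgvae_encode(hg, params2, cfg))
})

test_that("reparameterization has the right limits, determinism and mean", {
  mu <- matrix(c(1, -2, 0.5, 3), 2, 2)
  lv0 <- matrix(-60, 2, 2)    # sigma ~ 0
  expect_equal(reparameterize(mu, lv0, seed = 1), mu, tolerance = 1e-10)
  lv <- matrix(c(0.2, -0.3, 0.1, 0), 2, 2)
  expect_identical(reparameterize(mu, lv, seed = 42),
                   reparameterize(mu, lv, seed = 42))
  # Monte-Carlo mean within 4 standard errors
  m1 <- matrix(0.7, 1, 1); l1 <- matrix(0.4, 1, 1)
  set.seed(5)
  draws <- replicate(1e5, reparameterize(m1, l1)[1, 1])
  se <- exp(0.2) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 0.7), 4 * se)
})

test_that("attention pooling matches a hand-unrolled computation", {
  hg <- make_toy_hg(6)
  d <- 3
  set.seed(2)
  z <- matrix(rnorm(length(hg$nodes) * d), length(hg$nodes), d)
  pp <- list(W1 = matrix(rnorm(4 * d, sd = 0.5), 4, d), b1 = rnorm(4, sd = 0.1),
             w2 = rnorm(4, sd = 0.5), b2 = 0.2)
  pool <- hyperedge_pool(z, hg, pp, slope = 0.01)
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  for (k in seq_along(hg$hyperedges)) {
    mem <- hg$hyperedges[[k]]
    s <- vapply(mem, function(i)
      lrelu(sum(pp$w2 * lrelu(pp$W1 %*% z[i, ] + pp$b1)) + pp$b2), numeric(1))
    a <- exp(s - max(s)); a <- a / sum(a)
    e <- lrelu(colSums(a * z[mem, , drop = FALSE]))
    expect_equal(pool$attention[[k]], unname(a), tolerance = 1e-12)
    expect_equal(pool$hyperedge_embed[k, ], unname(e), tolerance = 1e-12)
  }
})

test_that("attention weights are a proper softmax on every hyperedge", {
  hg <- make_toy_hg(9, n = 12, p = 0.5)
  z <- matrix(rnorm(12 * 4), 12, 4)
  set.seed(3)
  pp <- list(W1 = matrix(rnorm(8), 2, 4), b1 = rnorm(2), w2 = rnorm(2), b2 = 0)
  pool <- hyperedge_pool(z, hg, pp)
  for (a in pool$attention) {
    expect_true(all(a >= 0))
    expect_lt(abs(sum(a) - 1), 1e-6)
  }
  # singleton hyperedge: attention 1, embedding = leaky relu of the latent
  single <- which(lengths(hg$hyperedges) == 1)
  if (length(single) == 0) {
    hg2 <- build_hypergraph(toy_network(),
                            matrix(rnorm(5 * 4), 5, 4,
                                   dimnames = list(toy_network()$nodes, NULL)),
                            min_size = 3)
    zz <- matrix(rnorm(5 * 4), 5, 4)
    pool2 <- hyperedge_pool(zz, hg2, pp)
    sk <- which(lengths(hg2$hyperedges) == 1)[1]
    expect_equal(pool2$attention[[sk]], 1)
    expect_equal(pool2$hyperedge_embed[sk, ],
                 ifelse(zz[hg2$hyperedges[[sk]], ] > 0,
                        zz[hg2$hyperedges[[sk]], ],
                        0.01 * zz[hg2$hyperedges[[sk]], ]))
  }
  # identical member latents give uniform attention
  z_same <- matrix(1.3, 12, 4)
  pool3 <- hyperedge_pool(z_same, hg, pp)
  for (k in seq_along(hg$hyperedges)) {
    nk <- length(hg$hyperedges[[k]])
    expect_equal(pool3$attention[[k]], rep(1 / nk, nk))
  }
})

test_that("the decoder is an element-wise sigmoid of inner products", {
  set.seed(4)
  z <- matrix(rnorm(5 * 3), 5, 3)
  E <- matrix(rnorm(4 * 3), 4, 3)
  Hh <- hgvae_decode(z, E)
  for (i in 1:5) for (j in 1:4)
    expect_equal(Hh[i, j], 1 / (1 + exp(-sum(z[i, ] * E[j, ]))),
                 tolerance = 1e-12)
  # orthogonal latent and hyperedge embedding give probability 1/2
  expect_equal(hgvae_decode(matrix(c(1, 0), 1, 2),
                            matrix(c(0, 1), 1, 2))[1, 1], 0.5)
})

test_that("the variational loss matches an element-wise oracle", {
  set.seed(6)
  H <- matrix(rbinom(12, 1, 0.5), 3, 4)
  Hh <- matrix(runif(12, 0.05, 0.95), 3, 4)
  mu <- matrix(rnorm(6), 3, 2)
  lv <- matrix(rnorm(6, sd = 0.3), 3, 2)
  pw <- 2.5
  rec <- 0
  for (i in 1:3) for (j in 1:4)
    rec <- rec - (pw * H[i, j] * log(Hh[i, j]) +
                    (1 - H[i, j]) * log(1 - Hh[i, j])) / 12
  kl <- 0
  for (i in 1:3) for (j in 1:2)
    kl <- kl + (mu[i, j]^2 + exp(lv[i, j]) - 1 - lv[i, j]) / 6
  expect_equal(elbo_loss(H, Hh, mu, lv, pos_weight = pw), rec + kl,
               tolerance = 1e-8)
  # prior == posterior: KL term vanishes
  expect_equal(elbo_loss(H, Hh, matrix(0, 3, 2), matrix(0, 3, 2), pw), rec,
               tolerance = 1e-8)
  # near-perfect reconstruction: tiny loss
  eps <- 1e-9
  Hp <- H * (1 - 2 * eps) + eps
  expect_lt(elbo_loss(H, Hp, matrix(0, 3, 2), matrix(0, 3, 2)), 1e-6)
  expect_message(elbo_loss(H, H, mu, lv), "clamp")
})

test_that("closed-form KL agrees with a Monte-Carlo estimate", {
  set.seed(77)
  mu <- matrix(rnorm(4, sd = 0.8), 2, 2)
  lv <- matrix(rnorm(4, sd = 0.4), 2, 2)
  closed <- sum(mu^2 + exp(lv) - 1 - lv) / 2
  # KL = E_q[log q - log p], estimated by sampling from q
  nmc <- 2e5
  samp <- numeric(nmc)
  for (r in seq_len(nmc)) {
    z <- rnorm(4, mean = as.numeric(mu), sd = as.numeric(exp(lv / 2)))
    samp[r] <- sum(stats::dnorm(z, as.numeric(mu), as.numeric(exp(lv / 2)),
                                log = TRUE) -
                     stats::dnorm(z, 0, 1, log = TRUE))
  }
  se <- stats::sd(samp) / sqrt(nmc)
  expect_lt(abs(mean(samp) - closed), 3 * se)
})

test_that("analytic gradients match finite differences", {
  hg <- make_toy_hg(12, n = 8, p = 0.45)
  A <- propagation_operator(hg)
  AX <- A %*% hg$X
  target <- as.matrix(hg$H)
  pw <- (length(target) - sum(target)) / sum(target)
  d <- 3
  set.seed(9)
  params <- list(W0 = matrix(rnorm(6 * 4, sd = 0.4), 6, 4),
                 Wmu = matrix(rnorm(4 * d, sd = 0.4), 4, d),
                 Wlv = matrix(rnorm(4 * d, sd = 0.4), 4, d),
                 P_W1 = matrix(rnorm(3 * d, sd = 0.4), 3, d),
                 P_b1 = rnorm(3, sd = 0.1),
                 P_w2 = rnorm(3, sd = 0.4), P_b2 = 0.05)
  Eps <- matrix(rnorm(8 * d), 8, d)
  fb <- hgcomplex:::hgvae_grad_step(params, AX, A, target, pw,
                                    hg$hyperedges, Eps, 0.01)
  h <- 1e-6
  for (nm in names(params)) {
    idx <- if (length(params[[nm]]) > 4) sample(length(params[[nm]]), 4)
           else seq_along(params[[nm]])
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      lp <- hgcomplex:::hgvae_grad_step(pp, AX, A, target, pw,
                                        hg$hyperedges, Eps, 0.01)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      lm <- hgcomplex:::hgvae_grad_step(pp, AX, A, target, pw,
                                        hg$hyperedges, Eps, 0.01)$loss
      num <- (lp - lm) / (2 * h)
      ana <- fb$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-3)
    }
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  net <- random_network(12, 0.4, seed = 21)
  set.seed(21)
  X <- matrix(abs(rnorm(12 * 6)), 12, 6, dimnames = list(net$nodes, NULL))
  hg <- build_hypergraph(net, X, min_size = 2)
  cfg <- hgvae_config(input_dim = 6, hidden_dim = 8, latent_dim = 4,
                      proj_dim = 4, epochs = 200, learning_rate = 5e-3,
                      seed = 7)
  fit1 <- train_hgvae(hg, cfg)
  fit2 <- train_hgvae(hg, cfg)
  expect_identical(fit1$loss_trace, fit2$loss_trace)
  expect_lt(fit1$loss_trace[200], fit1$loss_trace[1])
  expect_equal(dim(fit1$latent), c(12, 4))
  expect_true(all(is.finite(fit1$latent)))
})

test_that("two planted blocks separate in latent space", {
  bm <- generate_benchmark(n_nodes = 40, n_complexes = 2, max_size = 8,
                           background_edge_prob = 0.02, seed = 9)
  X <- encode_catalog(bm$catalog)
  hg <- build_hypergraph(bm$network, X, min_size = 3)
  fit <- train_hgvae(hg, hgvae_config(hidden_dim = 64, latent_dim = 16,
                                      proj_dim = 16, epochs = 200,
                                      learning_rate = 5e-3, seed = 4))
  emb <- latent_embeddings(fit)
  b1 <- bm$planted$members[[1]]; b2 <- bm$planted$members[[2]]
  cs <- emb / sqrt(rowSums(emb^2))
  C <- cs %*% t(cs)
  within <- mean(c(C[b1, b1][upper.tri(C[b1, b1])],
                   C[b2, b2][upper.tri(C[b2, b2])]))
  between <- mean(C[b1, b2])
  expect_gt(within, between)
})

test_that("topology-free and pairwise-graph ablation modes train", {
  net <- random_network(14, 0.35, seed = 31)
  set.seed(31)
  X <- matrix(abs(rnorm(14 * 6)), 14, 6, dimnames = list(net$nodes, NULL))
  hg <- build_hypergraph(net, X, min_size = 2)
  f_nopin <- train_hgvae(hg, hgvae_config(input_dim = 6, hidden_dim = 8,
                                          latent_dim = 4, proj_dim = 4,
                                          epochs = 30, mode = "no_pin"))
  expect_equal(dim(f_nopin$latent), c(14, 4))
  f_vgae <- train_hgvae(hg, hgvae_config(input_dim = 6, hidden_dim = 8,
                                         latent_dim = 4, proj_dim = 4,
                                         epochs = 30, mode = "vgae"),
                        network = net)
  expect_equal(dim(f_vgae$latent), c(14, 4))
  # sequence-free ablation uses one-hot features through the same path
  I <- identity_features(net)
  hgI <- build_hypergraph(net, I, min_size = 2)
  f_noct <- train_hgvae(hgI, hgvae_config(input_dim = 14, hidden_dim = 8,
                                          latent_dim = 4, proj_dim = 4,
                                          epochs = 30))
  expect_equal(dim(f_noct$latent), c(14, 4))
})
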