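# Shared neural-network primitives: activations, stable binary
# cross-entropy on logits, Glorot initialization and Adam updates.
# All state lives in plain R lists; determinism comes from seeding the
# session RNG before any draw.

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow
softplus <- function(x) {
  out <- x
  neg <- x < 0
  out[neg] <- log1p(exp(x[neg]))
  out[!neg] <- x[!neg] + log1p(exp(-x[!neg]))
  out
}

leaky_relu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -r, r), n_in, n_out)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# one Adam update over a named list of parameters; returns list(params, state)
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
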