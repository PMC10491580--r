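# Minimal multilayer perceptron with ReLU hidden layers, a linear embedding
# layer, and an Adam optimiser. Written directly on base matrix algebra:
# the networks involved are small (a few hundred inputs, two layers) and
# train in seconds, and keeping the forward/backward pass explicit makes the
# triplet-gradient wiring auditable.

mlp_init <- function(input_dim, layers, seed = 1L) {
  dims <- c(input_dim, layers)
  with_seed(seed, {
    W <- vector("list", length(layers))
    b <- vector("list", length(layers))
    for (i in seq_along(layers)) {
      fan_in <- dims[i]
      # He initialisation, suited to the ReLU hidden activations
      W[[i]] <- matrix(stats::rnorm(fan_in * dims[i + 1], sd = sqrt(2 / fan_in)),
                       nrow = fan_in, ncol = dims[i + 1])
      b[[i]] <- numeric(dims[i + 1])
    }
    list(W = W, b = b)
  })
}

# Forward pass; returns the embedding and, when cache = TRUE, the
# per-layer activations needed for backprop. ReLU after every layer except
# the last (linear embedding output).
mlp_forward <- function(params, X, cache = FALSE) {
  L <- length(params$W)
  H <- X
  Hs <- if (cache) vector("list", L + 1) else NULL
  if (cache) Hs[[1]] <- H
  for (i in seq_len(L)) {
    Z <- sweep(H %*% params$W[[i]], 2, params$b[[i]], "+")
    H <- if (i < L) pmax(Z, 0) else Z
    if (cache) Hs[[i + 1]] <- H
  }
  if (cache) list(out = H, activations = Hs) else H
}

# Backward pass for dL/d(out); returns gradients with the same shapes as
# params. ReLU derivative read off the cached post-activation values.
mlp_backward <- function(params, fwd, dOut) {
  L <- length(params$W)
  Hs <- fwd$activations
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (i in rev(seq_len(L))) {
    gW[[i]] <- crossprod(Hs[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- tcrossprod(delta, params$W[[i]])
      delta <- delta * (Hs[[i]] > 0)
    }
  }
  list(W = gW, b = gb)
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(params$W), vW = zero_like(params$W),
       mb = zero_like(params$b), vb = zero_like(params$b), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$W[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$W[[i]]^2
    params$W[[i]] <- params$W[[i]] -
      lr * (state$mW[[i]] / bc1) / (sqrt(state$vW[[i]] / bc2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$b[[i]]^2
    params$b[[i]] <- params$b[[i]] -
      lr * (state$mb[[i]] / bc1) / (sqrt(state$vb[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

rowwise_euclidean <- function(A, B) {
  sqrt(pmax(rowSums((A - B)^2), 0))
}

# One gradient step on a batch of triplets (anchor / positive / negative
# rows aligned). Hinge-active rows contribute the standard Euclidean triplet
# gradient; the mean is taken over ALL triplets in the batch.
triplet_batch_step <- function(params, A, P, N, margin) {
  fa <- mlp_forward(params, A, cache = TRUE)
  fp <- mlp_forward(params, P, cache = TRUE)
  fn <- mlp_forward(params, N, cache = TRUE)
  eps <- 1e-12
  d_ap <- rowwise_euclidean(fa$out, fp$out)
  d_an <- rowwise_euclidean(fa$out, fn$out)
  loss_vec <- pmax(d_ap - d_an + margin, 0)
  active <- loss_vec > 0
  n <- nrow(A)
  dA <- matrix(0, n, ncol(fa$out))
  dP <- dA
  dN <- dA
  if (any(active)) {
    u_ap <- (fa$out - fp$out) / pmax(d_ap, eps)  # unit vector a - p
    u_an <- (fa$out - fn$out) / pmax(d_an, eps)
    dA[active, ] <- (u_ap - u_an)[active, , drop = FALSE] / n
    dP[active, ] <- -u_ap[active, , drop = FALSE] / n
    dN[active, ] <- u_an[active, , drop = FALSE] / n
  }
  gA <- mlp_backward(params, fa, dA)
  gP <- mlp_backward(params, fp, dP)
  gN <- mlp_backward(params, fn, dN)
  grads <- list(
    W = Map(function(x, y, z) x + y + z, gA$W, gP$W, gN$W),
    b = Map(function(x, y, z) x + y + z, gA$b, gP$b, gN$b)
  )
  list(grads = grads, loss = mean(loss_vec))
}
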