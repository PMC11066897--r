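# Minimal dense-network engine: stacks of fully connected layers with
# ReLU hidden activations, manual backpropagation and Adam updates.
# Kept deliberately small — the package only needs fixed MLP stacks —
# so that the whole training path stays dependency-free and exactly
# reproducible from seeds on one thread.

.nn_init_stack <- function(dims) {
  # He-normal init; consumes RNG in a fixed order.
  lapply(seq_len(length(dims) - 1L), function(i) {
    fin <- dims[i]; fout <- dims[i + 1L]
    list(W = matrix(stats::rnorm(fin * fout, sd = sqrt(2 / fin)), fin, fout),
         b = rep(0, fout))
  })
}

# Forward pass. X is samples x features. Hidden layers ReLU (+ inverted
# dropout when train=TRUE and rate>0); the last layer stays linear.
# Returns the linear output plus the caches backprop needs.
.nn_forward <- function(layers, X, dropout = 0, train = FALSE) {
  n <- length(layers)
  A <- vector("list", n + 1L); A[[1L]] <- X
  relu <- vector("list", n); masks <- vector("list", n)
  for (i in seq_len(n)) {
    Z <- A[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    if (i < n) {
      relu[[i]] <- Z > 0
      H <- Z * relu[[i]]
      if (train && dropout > 0) {
        m <- (matrix(stats::runif(length(H)), nrow(H)) >= dropout) /
          (1 - dropout)
        masks[[i]] <- m
        H <- H * m
      }
      A[[i + 1L]] <- H
    } else {
      A[[i + 1L]] <- Z
    }
  }
  list(out = A[[n + 1L]], A = A, relu = relu, masks = masks)
}

# Backward pass from dZ = d(loss)/d(final linear output).
# Returns per-layer gradients and the gradient wrt the input.
.nn_backward <- function(layers, fw, dZ) {
  n <- length(layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    grads[[i]] <- list(W = crossprod(fw$A[[i]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[i]]$W)
    if (i > 1L) {
      if (!is.null(fw$masks[[i - 1L]])) dA <- dA * fw$masks[[i - 1L]]
      dZ <- dA * fw$relu[[i - 1L]]
    } else {
      dX <- dA
    }
  }
  list(grads = grads, dX = dX)
}

.nn_zero_grads <- function(layers)
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))

.nn_add_grads <- function(g1, g2)
  Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), g1, g2)

.adam_init <- function(layers)
  lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))

.adam_step <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    st <- state[[i]]; g <- grads[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / bc1) /
      (sqrt(st$vW / bc2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / bc1) /
      (sqrt(st$vb / bc2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

# Adam on a plain numeric vector (used for per-gene log-dispersions).
.adam_vec_step <- function(x, g, state, lr, t,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  x <- x - lr * (state$m / (1 - beta1^t)) /
    (sqrt(state$v / (1 - beta2^t)) + eps)
  list(x = x, state = state)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))
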