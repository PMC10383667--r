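# A compact multilayer perceptron for the depth-sweep baseline: gamma hidden
# layers of a fixed width (30 by default), ReLU activations, sigmoid output,
# binary cross-entropy loss, full-batch Adam. Written in plain matrix code;
# at the subset sizes the pipeline feeds it (tens of genes, a few hundred
# samples) this trains in well under a second per configuration.

mlp_fit <- function(X, y, layers, width = 30L, epochs = 150L,
                    learn_rate = 0.01) {
  layers <- as.integer(layers)
  if (layers < 1L) {
    stop_ibdsig("an MLP needs at least 1 hidden layer", "ibdsig_value_error")
  }
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.numeric(y)
  sizes <- c(ncol(X), rep(as.integer(width), layers), 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialisation keeps activations stable through deep ReLU stacks
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- vW <- lapply(W, function(w) w * 0)
  mb <- vb <- lapply(b, function(v) v * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(as.integer(epochs))) {
    a <- vector("list", L + 1L)
    a[[1L]] <- X
    for (l in seq_len(L)) {
      z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+")
      a[[l + 1L]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
    }
    delta <- (a[[L + 1L]] - y) / n  # dLoss/dz for sigmoid + cross-entropy
    for (l in rev(seq_len(L))) {
      gW <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
      W[[l]] <- W[[l]] - learn_rate * (mW[[l]] / corr1) /
        (sqrt(vW[[l]] / corr2) + eps)
      b[[l]] <- b[[l]] - learn_rate * (mb[[l]] / corr1) /
        (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  list(W = W, b = b, L = L)
}

mlp_predict <- function(fit, X) {
  a <- as.matrix(X)
  for (l in seq_len(fit$L)) {
    z <- sweep(a %*% fit$W[[l]], 2L, fit$b[[l]], "+")
    a <- if (l < fit$L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  as.integer(drop(a) > 0.5)
}
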