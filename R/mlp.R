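# A small dense feed-forward binary classifier: ReLU hidden layers, sigmoid
# output, binary cross-entropy, Adam, inverted dropout. Written with plain
# (BLAS-backed) matrix ops; deterministic given the seed.

mlp_init <- function(n_in, hidden) {
  dims <- c(n_in, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    # He initialisation for the ReLU layers
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(W = W, b = b, dims = dims)
}

mlp_forward <- function(par, X, dropout = 0, training = FALSE) {
  L <- length(par$W)
  A <- list(X)
  masks <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    if (l < L) {
      Z <- pmax(Z, 0)
      if (training && dropout > 0) {
        keep <- matrix(runif(length(Z)) >= dropout, nrow(Z), ncol(Z))
        Z <- Z * keep / (1 - dropout)
        masks[[l]] <- keep
      }
    } else {
      Z <- 1 / (1 + exp(-Z))
    }
    A[[l + 1]] <- Z
  }
  list(A = A, masks = masks)
}

mlp_fit <- function(X, y, hidden = 32, dropout = 0, learning_rate = 1e-3,
                    epochs = 50, batch_size = 32, seed = 1) {
  stopifnot(nrow(X) == length(y))
  X <- as.matrix(X)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    par <- mlp_init(ncol(X), hidden)
    L <- length(par$W)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0
    history <- numeric(max(epochs, 0))
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1, n)]
        Xb <- X[rows, , drop = FALSE]
        yb <- y[rows]
        fw <- mlp_forward(par, Xb, dropout, training = TRUE)
        p <- fw$A[[L + 1]][, 1]
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        losses <- c(losses, -mean(yb * log(p) + (1 - yb) * log(1 - p)))
        # backprop: sigmoid + BCE collapse to (p - y)
        delta <- matrix((p - yb) / length(yb), ncol = 1)
        step <- step + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(par$W[[l]])
            act <- fw$A[[l]]
            delta <- delta * (act > 0)
            if (!is.null(fw$masks[[l - 1]])) {
              delta <- delta * fw$masks[[l - 1]] / (1 - dropout)
            }
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
          mhb <- mb[[l]] / (1 - beta1^step); vhb <- vb[[l]] / (1 - beta2^step)
          par$W[[l]] <- par$W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
          par$b[[l]] <- par$b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      history[ep] <- mean(losses)
    }
    list(par = par, loss_history = history, n_features = ncol(X))
  })
}

mlp_predict <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != fit$n_features) {
    abort(sprintf("Feature width %d does not match the model's %d.",
                  ncol(X), fit$n_features),
          class = "amidescreen_incompatible_features")
  }
  p <- mlp_forward(fit$par, X)$A[[length(fit$par$W) + 1]][, 1]
  pmin(pmax(p, 0), 1)
}

mlp_param_count <- function(n_in, hidden) {
  dims <- c(n_in, hidden, 1L)
  sum(dims[-length(dims)] * dims[-1] + dims[-1])
}
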