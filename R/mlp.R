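# Native multilayer perceptron for binary classification, trained with Adam.
# Fixed architecture (default 3 hidden layers x 300 ReLU units, 2-unit
# softmax output) with early stopping on a held-out validation split
# (patience in epochs, metric = validation cross-entropy loss).

mlp_init <- function(sizes) {
  # He initialization for ReLU layers
  weights <- list()
  for (i in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[i]
    weights[[i]] <- list(
      w = matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[i + 1]),
      b = rep(0, sizes[i + 1])
    )
  }
  weights
}

mlp_forward <- function(weights, x) {
  acts <- list(x)
  a <- x
  n_layers <- length(weights)
  for (i in seq_len(n_layers)) {
    z <- a %*% weights[[i]]$w
    z <- sweep(z, 2, weights[[i]]$b, "+")
    a <- if (i < n_layers) pmax(z, 0) else z
    acts[[i + 1]] <- a
  }
  # softmax over the 2 output units
  z <- acts[[n_layers + 1]]
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(acts = acts, probs = probs)
}

mlp_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y + 1)], 1e-12)))
}

# One Adam step on a minibatch; returns updated weights and moments.
mlp_backward <- function(weights, acts, probs, y, lr, state, t_step,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- length(y)
  n_layers <- length(weights)
  target <- matrix(0, n, 2)
  target[cbind(seq_len(n), y + 1)] <- 1
  delta <- (probs - target) / n
  for (i in rev(seq_len(n_layers))) {
    gw <- t(acts[[i]]) %*% delta
    gb <- colSums(delta)
    if (i > 1) {
      delta <- (delta %*% t(weights[[i]]$w)) * (acts[[i]] > 0)
    }
    state$m[[i]]$w <- beta1 * state$m[[i]]$w + (1 - beta1) * gw
    state$v[[i]]$w <- beta2 * state$v[[i]]$w + (1 - beta2) * gw^2
    state$m[[i]]$b <- beta1 * state$m[[i]]$b + (1 - beta1) * gb
    state$v[[i]]$b <- beta2 * state$v[[i]]$b + (1 - beta2) * gb^2
    mhat_w <- state$m[[i]]$w / (1 - beta1^t_step)
    vhat_w <- state$v[[i]]$w / (1 - beta2^t_step)
    mhat_b <- state$m[[i]]$b / (1 - beta1^t_step)
    vhat_b <- state$v[[i]]$b / (1 - beta2^t_step)
    weights[[i]]$w <- weights[[i]]$w - lr * mhat_w / (sqrt(vhat_w) + eps)
    weights[[i]]$b <- weights[[i]]$b - lr * mhat_b / (sqrt(vhat_b) + eps)
  }
  list(weights = weights, state = state)
}

mlp_train <- function(x, y, hidden = c(300, 300, 300), lr = 1e-3,
                      batch_size = 32, epochs = 50, patience = 3,
                      val_fraction = 0.1, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  with_seed(seed, {
    n <- nrow(x)
    n_val <- max(1L, round(n * val_fraction))
    val_idx <- sample.int(n, n_val)
    xtr <- x[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
    xva <- x[val_idx, , drop = FALSE];  yva <- y[val_idx]
    sizes <- c(ncol(x), hidden, 2)
    weights <- mlp_init(sizes)
    zero_like <- lapply(weights, function(l) list(w = l$w * 0, b = l$b * 0))
    state <- list(m = zero_like, v = zero_like)
    best <- list(loss = Inf, weights = weights)
    wait <- 0L
    t_step <- 0L
    bs <- max(1L, min(batch_size, nrow(xtr)))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(xtr))
      for (start in seq(1, nrow(xtr), by = bs)) {
        idx <- ord[start:min(start + bs - 1, nrow(xtr))]
        fw <- mlp_forward(weights, xtr[idx, , drop = FALSE])
        t_step <- t_step + 1L
        upd <- mlp_backward(weights, fw$acts, fw$probs, ytr[idx], lr, state, t_step)
        weights <- upd$weights
        state <- upd$state
      }
      val_loss <- mlp_loss(mlp_forward(weights, xva)$probs, yva)
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, weights = weights)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    list(weights = best$weights, val_loss = best$loss, sizes = sizes)
  })
}

mlp_predict_proba <- function(model, x) {
  mlp_forward(model$weights, as.matrix(x))$probs[, 2]
}
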