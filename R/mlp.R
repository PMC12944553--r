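# Internal multilayer perceptron: ReLU hidden layers, softmax output,
# cross-entropy loss, Adam optimizer, early stopping on a stratified
# validation split. Deterministic given a seed.

mlp_init <- function(dims, seed) {
  with_seed(seed, lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L],
                                 sd = sqrt(2 / dims[i])),
                    dims[i], dims[i + 1L]),
         b = rep(0, dims[i + 1L]))
  }))
}

# Forward pass. `drop_masks` (training only) holds one inverted-dropout
# mask per hidden layer; NULL disables dropout.
mlp_forward <- function(x, weights, drop_masks = NULL) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1L]] <- x
  n <- length(weights)
  for (i in seq_len(n)) {
    z <- sweep(acts[[i]] %*% weights[[i]]$W, 2, -weights[[i]]$b)
    if (i < n) {
      h <- pmax(z, 0)
      if (!is.null(drop_masks)) h <- h * drop_masks[[i]]
      acts[[i + 1L]] <- h
    } else acts[[i + 1L]] <- z
  }
  z <- acts[[n + 1L]]
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  list(acts = acts, probs = ez / rowSums(ez))
}

mlp_loss <- function(probs, y_onehot) {
  -mean(rowSums(y_onehot * log(probs + 1e-12)))
}

# One Adam step on a minibatch (decoupled weight decay on W, not biases);
# returns updated weights and moments.
mlp_step <- function(weights, mom, x, y_onehot, lr, t, weight_decay = 0,
                     drop_masks = NULL,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  fw <- mlp_forward(x, weights, drop_masks = drop_masks)
  n <- length(weights)
  m <- nrow(x)
  delta <- (fw$probs - y_onehot) / m
  for (i in rev(seq_len(n))) {
    a <- fw$acts[[i]]
    gW <- crossprod(a, delta)
    gb <- colSums(delta)
    if (i > 1) delta <- (delta %*% t(weights[[i]]$W)) * (fw$acts[[i]] > 0)
    for (nm in c("W", "b")) {
      g <- if (nm == "W") gW else gb
      mom[[i]][[nm]]$m <- beta1 * mom[[i]][[nm]]$m + (1 - beta1) * g
      mom[[i]][[nm]]$v <- beta2 * mom[[i]][[nm]]$v + (1 - beta2) * g^2
      mhat <- mom[[i]][[nm]]$m / (1 - beta1^t)
      vhat <- mom[[i]][[nm]]$v / (1 - beta2^t)
      upd <- mhat / (sqrt(vhat) + eps)
      if (nm == "W" && weight_decay > 0)
        upd <- upd + weight_decay * weights[[i]][[nm]]
      weights[[i]][[nm]] <- weights[[i]][[nm]] - lr * upd
    }
  }
  list(weights = weights, mom = mom)
}

mlp_train <- function(x, y, hidden, lr, epochs, batch_size, val_frac,
                      patience, seed, weight_decay = 0, dropout = 0,
                      input_noise_sd = 0, input_dropout = 0,
                      input_l1 = 0, label_smoothing = 0,
                      lr_decay = c("none", "cosine"),
                      blocks = NULL, modality_dropout = 0) {
  lr_decay <- match.arg(lr_decay)
  levels_y <- levels(y)
  k <- length(levels_y)
  dims <- c(ncol(x), hidden, k)
  weights <- mlp_init(dims, seed)
  mom <- lapply(weights, function(l) list(
    W = list(m = l$W * 0, v = l$W * 0),
    b = list(m = l$b * 0, v = l$b * 0)))
  onehot <- function(yy) {
    o <- matrix(0, length(yy), k)
    o[cbind(seq_along(yy), as.integer(yy))] <- 1
    if (label_smoothing > 0)
      o <- o * (1 - label_smoothing) + label_smoothing / k
    o
  }
  if (val_frac > 0 && all(table(y) >= 2)) {
    sp <- stratified_split(y, val_frac, seed = seed + 7L)
    tr <- sp$train; va <- sp$test
  } else {
    tr <- seq_len(nrow(x)); va <- integer(0)
  }
  xtr <- x[tr, , drop = FALSE]; ytr <- onehot(y[tr])
  xva <- x[va, , drop = FALSE]; yva <- onehot(y[va])
  best <- list(weights = weights, loss = Inf, epoch = 0L)
  history <- numeric(0)
  t_step <- 0L
  wait <- 0L
  order_seeds <- with_seed(seed + 13L,
                           sample.int(.Machine$integer.max / 2, epochs))
  for (ep in seq_len(epochs)) {
    epoch_rng <- with_seed(order_seeds[ep], {
      ord <- sample(nrow(xtr))
      noise <- if (input_noise_sd > 0)
        matrix(stats::rnorm(length(xtr), 0, input_noise_sd), nrow(xtr))
      else NULL
      inmask <- if (input_dropout > 0)
        matrix(stats::rbinom(length(xtr), 1, 1 - input_dropout),
               nrow(xtr)) / (1 - input_dropout)
      else NULL
      # modality dropout: zero whole feature blocks per sample (never all),
      # inverted scaling keeps train/test pre-activations matched
      bmask <- if (modality_dropout > 0 && length(blocks) > 1) {
        keep <- matrix(stats::rbinom(nrow(xtr) * length(blocks), 1,
                                     1 - modality_dropout), nrow(xtr))
        keep[rowSums(keep) == 0, ] <- 1
        keep / (1 - modality_dropout)
      } else NULL
      masks <- if (dropout > 0)
        lapply(seq_along(hidden), function(i)
          matrix(stats::rbinom(batch_size * hidden[i], 1, 1 - dropout),
                 batch_size) / (1 - dropout))
      else NULL
      list(ord = ord, noise = noise, inmask = inmask, bmask = bmask,
           masks = masks)
    })
    ord <- epoch_rng$ord
    lr_ep <- if (lr_decay == "cosine")
      lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs)) else lr
    for (start in seq(1L, length(ord), by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, length(ord))]
      t_step <- t_step + 1L
      xb <- xtr[sel, , drop = FALSE]
      if (!is.null(epoch_rng$noise))
        xb <- xb + epoch_rng$noise[sel, , drop = FALSE]
      if (!is.null(epoch_rng$inmask))
        xb <- xb * epoch_rng$inmask[sel, , drop = FALSE]
      if (!is.null(epoch_rng$bmask))
        for (bi in seq_along(blocks))
          xb[, blocks[[bi]]] <- xb[, blocks[[bi]]] *
            epoch_rng$bmask[sel, bi]
      masks <- if (!is.null(epoch_rng$masks))
        lapply(epoch_rng$masks, function(m) m[seq_along(sel), , drop = FALSE])
      else NULL
      st <- mlp_step(weights, mom, xb, ytr[sel, , drop = FALSE], lr_ep,
                     t_step, weight_decay = weight_decay, drop_masks = masks)
      weights <- st$weights; mom <- st$mom
      if (input_l1 > 0) {
        # proximal soft-threshold on the input layer: embedded selection of
        # informative input dimensions (sparse-input network)
        W1 <- weights[[1L]]$W
        weights[[1L]]$W <- sign(W1) * pmax(abs(W1) - lr_ep * input_l1, 0)
      }
    }
    monitor <- if (length(va)) mlp_loss(mlp_forward(xva, weights)$probs, yva)
               else mlp_loss(mlp_forward(xtr, weights)$probs, ytr)
    history <- c(history, monitor)
    if (monitor < best$loss - 1e-6) {
      best <- list(weights = weights, loss = monitor, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(weights = best$weights, dims = dims, levels = levels_y,
       history = history, best_epoch = best$epoch)
}
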