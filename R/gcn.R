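# Graph convolutional encoder mapping a triangulated landmark graph to the
# 128-d landmark-graph feature vector (DFLGF).
#
# Edge distances are converted to Gaussian affinities exp(-d^2 / sigma^2)
# (sigma = median edge length) so that propagation weights nearby landmarks
# more strongly; the raw distances remain on the graph object. The adjacency
# is given self-loops and symmetrically normalized, D^-1/2 (A + I) D^-1/2.
# Two propagation layers (2 -> 16 -> 32, ReLU) are followed by global max
# pooling over nodes and a fully connected 32 -> 128 map. Weights are drawn
# once from a seeded He-scaled normal; the encoder is a fixed random
# projection of the graph geometry, not a trained network, which keeps the
# embedding deterministic and the parameter budget small.

#' Construct the landmark-graph encoder
#'
#' @param hidden integer vector of propagation layer widths (default
#'   `c(16, 32)`).
#' @param out_dim embedding dimension (default 128).
#' @param in_dim node feature dimension (default 2: centered x, y).
#' @param seed integer seed for weight initialisation.
#' @return object of class `vacp_gcn`: weight list plus `n_parameters`.
#' @export
gcn_encoder <- function(hidden = c(16L, 32L), out_dim = 128L, in_dim = 2L,
                        seed = 1L) {
  dims <- c(in_dim, hidden, out_dim)
  weights <- with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(i) {
      list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L],
                                   sd = sqrt(2 / dims[i])),
                      dims[i], dims[i + 1L]),
           b = rep(0, dims[i + 1L]))
    })
  })
  n_par <- sum(vapply(weights, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  structure(list(weights = weights, dims = dims, seed = seed,
                 n_parameters = n_par),
            class = "vacp_gcn")
}

#' @export
print.vacp_gcn <- function(x, ...) {
  cat(sprintf("<vacp_gcn> %s (%d parameters, seed %d)\n",
              paste(x$dims, collapse = " -> "), x$n_parameters, x$seed))
  invisible(x)
}

# Symmetrically normalized affinity matrix with self-loops for one graph.
gcn_adjacency <- function(graph) {
  k <- nrow(graph$coords)
  A <- matrix(0, k, k)
  sigma <- stats::median(graph$edges$weight)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  aff <- exp(-graph$edges$weight^2 / sigma^2)
  A[cbind(graph$edges$i, graph$edges$j)] <- aff
  A[cbind(graph$edges$j, graph$edges$i)] <- aff
  A <- A + diag(k)
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

relu <- function(x) pmax(x, 0)

# Forward pass for one graph -> out_dim vector.
gcn_forward <- function(graph, encoder) {
  X <- sweep(graph$coords, 2, colMeans(graph$coords)) / 100
  Ahat <- gcn_adjacency(graph)
  H <- X
  nw <- length(encoder$weights)
  for (i in seq_len(nw - 1L)) {
    w <- encoder$weights[[i]]
    H <- relu(sweep(Ahat %*% (H %*% w$W), 2, -w$b))
  }
  pooled <- apply(H, 2, max)
  w <- encoder$weights[[nw]]
  as.numeric(pooled %*% w$W + w$b)
}

#' Train the graph encoder on labelled graphs
#'
#' Supervised pre-training of the encoder: a temporary linear softmax head
#' is attached to the 128-d embedding and the full chain (two propagation
#' layers, max pooling, fully connected map, head) is trained by Adam under
#' cross-entropy; the head is discarded and the encoder frozen. Typical use
#' is pre-training on a cohort disjoint from the one under evaluation, the
#' same pre-trained-extractor paradigm as the AU models.
#'
#' @param graphs list of [triangulate_region()] graphs.
#' @param labels factor of class labels, one per graph.
#' @param encoder a [gcn_encoder()] to initialize from.
#' @param epochs training epochs (default 40).
#' @param lr Adam learning rate (default 0.01).
#' @param batch_size graphs per step (default 32).
#' @param seed RNG seed for shuffling and head initialisation.
#' @return the trained `vacp_gcn` encoder (same architecture and parameter
#'   count; `trained = TRUE`).
#' @export
train_gcn_encoder <- function(graphs, labels, encoder = gcn_encoder(),
                              epochs = 40L, lr = 0.01, batch_size = 32L,
                              seed = 1L) {
  stopifnot(inherits(encoder, "vacp_gcn"), length(graphs) == length(labels))
  labels <- droplevels(as.factor(labels))
  k <- nlevels(labels)
  out_dim <- encoder$dims[length(encoder$dims)]
  # precompute node features and normalized adjacencies
  pre <- lapply(graphs, function(g)
    list(X = sweep(g$coords, 2, colMeans(g$coords)) / 100,
         A = gcn_adjacency(g)))
  yi <- as.integer(labels)
  W <- encoder$weights
  head <- with_seed(seed, list(
    W = matrix(stats::rnorm(out_dim * k, sd = sqrt(2 / out_dim)), out_dim, k),
    b = rep(0, k)))
  params <- c(W, list(head))
  mom <- lapply(params, function(l) list(
    W = list(m = l$W * 0, v = l$W * 0), b = list(m = l$b * 0, v = l$b * 0)))
  adam <- function(p, mom, g, nm, t, lr) {
    mom[[nm]]$m <- 0.9 * mom[[nm]]$m + 0.1 * g
    mom[[nm]]$v <- 0.999 * mom[[nm]]$v + 0.001 * g^2
    mhat <- mom[[nm]]$m / (1 - 0.9^t)
    vhat <- mom[[nm]]$v / (1 - 0.999^t)
    list(p = p - lr * mhat / (sqrt(vhat) + 1e-8), mom = mom)
  }
  t_step <- 0L
  order_seeds <- with_seed(seed + 1L,
                           sample.int(.Machine$integer.max / 2, epochs))
  n <- length(graphs)
  nw <- length(W)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(order_seeds[ep], sample(n))
    for (start in seq(1L, n, by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, n)]
      t_step <- t_step + 1L
      grads <- NULL
      for (gi in sel) {
        X <- pre[[gi]]$X; A <- pre[[gi]]$A
        acts <- vector("list", nw + 1L); acts[[1]] <- X
        AH <- vector("list", nw)
        for (i in seq_len(nw - 1L)) {
          AH[[i]] <- A %*% (acts[[i]] %*% params[[i]]$W)
          acts[[i + 1L]] <- relu(sweep(AH[[i]], 2, -params[[i]]$b))
        }
        pool_idx <- apply(acts[[nw]], 2, which.max)
        pooled <- acts[[nw]][cbind(pool_idx, seq_along(pool_idx))]
        emb <- as.numeric(pooled %*% params[[nw]]$W + params[[nw]]$b)
        logit <- as.numeric(emb %*% params[[nw + 1L]]$W + params[[nw + 1L]]$b)
        p <- exp(logit - max(logit)); p <- p / sum(p)
        dlogit <- p; dlogit[yi[gi]] <- dlogit[yi[gi]] - 1
        g <- list()
        g[[nw + 1L]] <- list(W = outer(emb, dlogit), b = dlogit)
        demb <- as.numeric(params[[nw + 1L]]$W %*% dlogit)
        g[[nw]] <- list(W = outer(pooled, demb), b = demb)
        dpool <- as.numeric(params[[nw]]$W %*% demb)
        dH <- matrix(0, nrow(acts[[nw]]), ncol(acts[[nw]]))
        dH[cbind(pool_idx, seq_along(pool_idx))] <- dpool
        for (i in rev(seq_len(nw - 1L))) {
          dZ <- dH * (acts[[i + 1L]] > 0)
          g[[i]] <- list(W = crossprod(acts[[i]], crossprod(A, dZ)),
                         b = colSums(dZ))
          if (i > 1) dH <- (A %*% dZ) %*% t(params[[i]]$W)
        }
        grads <- if (is.null(grads)) g else
          lapply(seq_along(g), function(i)
            list(W = grads[[i]]$W + g[[i]]$W, b = grads[[i]]$b + g[[i]]$b))
      }
      for (i in seq_along(params)) {
        up <- adam(params[[i]]$W, mom[[i]], grads[[i]]$W / length(sel),
                   "W", t_step, lr)
        params[[i]]$W <- up$p; mom[[i]] <- up$mom
        up <- adam(params[[i]]$b, mom[[i]], grads[[i]]$b / length(sel),
                   "b", t_step, lr)
        params[[i]]$b <- up$p; mom[[i]] <- up$mom
      }
    }
  }
  encoder$weights <- params[seq_len(nw)]
  encoder$trained <- TRUE
  encoder
}

#' Encode landmark graphs into the 128-d graph feature
#'
#' Runs the graph convolutional encoder over one graph or a list of graphs
#' (e.g. the graphs of a clip's five keyframes) and returns the embedding;
#' for a list, the per-frame embeddings are averaged into the per-clip
#' vector.
#'
#' @param graphs a [triangulate_region()] graph or a list of them.
#' @param encoder a [gcn_encoder()].
#' @return numeric vector of length `encoder$dims[length(encoder$dims)]`
#'   (128 by default).
#' @export
encode_dflgf <- function(graphs, encoder) {
  if (!inherits(encoder, "vacp_gcn"))
    stop("`encoder` must be created by gcn_encoder()", call. = FALSE)
  if (inherits(graphs, "vacp_face_graph")) graphs <- list(graphs)
  if (length(graphs) == 0) stop("no graphs to encode", call. = FALSE)
  emb <- vapply(graphs, gcn_forward, numeric(encoder$dims[length(encoder$dims)]),
                encoder = encoder)
  rowMeans(emb)
}
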