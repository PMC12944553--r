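# Feature fusion and the severity classifier: the 251-d fused vector
# (FAUF 35 ++ DFLGF 128 ++ acoustic 88), a compact fully connected deep
# network (251 -> 128 -> 64 -> 32 -> 4), SVM and random-forest baselines,
# repeated stratified-split evaluation, and the region / feature-set /
# channel ablation harness.

#' Fuse feature blocks into the joint vector
#'
#' Concatenates per-clip feature blocks in FAUF -> DFLGF -> acoustic order.
#' Masked-out blocks are omitted: all three give 251 columns, the visual
#' mask (`c("fauf", "dflgf")`) 163, the acoustic mask 88.
#'
#' @param fauf n x 35 matrix (or NULL if masked out).
#' @param dflgf n x 128 matrix (or NULL).
#' @param acoustic n x 88 matrix (or NULL).
#' @param channels character subset of `c("fauf", "dflgf", "acoustic")`
#'   selecting the blocks to keep, in canonical order.
#' @return numeric matrix with attribute `blocks` (named list of column
#'   ranges).
#' @export
fuse_features <- function(fauf = NULL, dflgf = NULL, acoustic = NULL,
                          channels = c("fauf", "dflgf", "acoustic")) {
  channels <- match.arg(channels, several.ok = TRUE)
  dims <- c(fauf = 35L, dflgf = 128L, acoustic = 88L)
  blocks <- list(fauf = fauf, dflgf = dflgf, acoustic = acoustic)
  keep <- intersect(c("fauf", "dflgf", "acoustic"), channels)
  out <- NULL
  ranges <- list()
  at <- 0L
  for (nm in keep) {
    b <- blocks[[nm]]
    if (is.null(b))
      stop("channel '", nm, "' requested but its block is missing",
           call. = FALSE)
    b <- as.matrix(b)
    if (ncol(b) != dims[nm])
      stop(sprintf("block '%s' must have %d columns, got %d", nm, dims[nm],
                   ncol(b)), call. = FALSE)
    if (!is.null(out) && nrow(out) != nrow(b))
      stop("blocks disagree on the number of clips", call. = FALSE)
    out <- if (is.null(out)) b else cbind(out, b)
    ranges[[nm]] <- (at + 1L):(at + ncol(b))
    at <- at + ncol(b)
  }
  attr(out, "blocks") <- ranges
  out
}

#' Classifier specification
#'
#' @param kind `"dnn"` (default), `"svm"` (RBF kernel, `C = 4`,
#'   `gamma = 0.25`) or `"random_forest"`.
#' @param hidden DNN hidden layer sizes (default `c(128, 64, 32)`; the
#'   4-way softmax output follows).
#' @param lr DNN learning rate (default 0.01, Adam).
#' @param epochs,batch_size,validation_frac,patience DNN training schedule:
#'   `epochs` epochs with minibatches of `batch_size`; when
#'   `validation_frac > 0`, early stopping on a stratified holdout after
#'   `patience` epochs without improvement (off by default: at cohort scale
#'   a fixed schedule with weight decay generalizes better than a noisy
#'   small-holdout stop).
#' @param weight_decay decoupled L2 weight decay of the DNN (default 0.01).
#' @param dropout hidden-layer dropout rate during training (default 0.2).
#' @param input_noise_sd Gaussian noise added to standardized inputs during
#'   training (default 0.2), a Tikhonov-style smoother.
#' @param input_dropout probability of dropping each input feature per
#'   training batch (default 0.2); guards against memorization through
#'   uninformative dimensions.
#' @param input_l1 L1 penalty on the input-layer weights (default 0.003),
#'   applied as a proximal soft-threshold: embedded selection of
#'   informative input dimensions.
#' @param label_smoothing label-smoothing mass (default 0.1).
#' @param lr_decay `"cosine"` (default) anneals the learning rate to zero
#'   over the schedule; `"none"` keeps it constant.
#' @param modality_dropout see [vacp_net()].
#' @param cost,gamma SVM hyperparameters.
#' @param n_trees random-forest size.
#' @param seed integer seed for all stochastic pieces.
#' @return list of class `vacp_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("dnn", "svm", "random_forest"),
                            hidden = c(128L, 64L, 32L), lr = 0.01,
                            epochs = 200L, batch_size = 32L,
                            validation_frac = 0, patience = 50L,
                            weight_decay = 0.01, dropout = 0.2,
                            input_noise_sd = 0.2, input_dropout = 0.2,
                            input_l1 = 0.003, label_smoothing = 0.1,
                            lr_decay = "cosine", modality_dropout = 0.5,
                            cost = 4, gamma = 0.25, n_trees = 500L,
                            seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hidden = hidden, lr = lr, epochs = epochs,
                 batch_size = batch_size, validation_frac = validation_frac,
                 patience = patience, weight_decay = weight_decay,
                 dropout = dropout, input_noise_sd = input_noise_sd,
                 input_dropout = input_dropout, input_l1 = input_l1,
                 label_smoothing = label_smoothing, lr_decay = lr_decay,
                 modality_dropout = modality_dropout,
                 cost = cost, gamma = gamma,
                 n_trees = n_trees, seed = seed),
            class = "vacp_classifier_spec")
}

#' Fit the fused deep-network severity classifier
#'
#' A fully connected network with hidden sizes 128/64/32 and a 4-way
#' softmax output (one unit per severity class), trained with Adam at
#' learning rate 0.01 under cross-entropy, minibatches of 32, and early
#' stopping on a 10% stratified validation split. Inputs are standardized
#' per column with training-set statistics. Training is deterministic
#' given the seed.
#'
#' @param x numeric feature matrix (rows = clips), e.g. a
#'   [fuse_features()] result.
#' @param y severity labels (factor or character; 4 classes for the full
#'   task).
#' @param hidden,lr,epochs,batch_size,validation_frac,patience,weight_decay,dropout,input_noise_sd,input_dropout,input_l1,label_smoothing,lr_decay,seed
#'   see [classifier_spec()].
#' @return object of class `vacp_net` with fields `weights`, `dims`,
#'   `levels`, `center`, `scale`, `n_parameters`, `history`, `best_epoch`,
#'   `seed`.
#' @export
#' @param modality_dropout probability of zeroing an entire feature block
#'   per training sample (default 0.2, active only when `x` carries block
#'   boundaries, e.g. from [fuse_features()]): standard multimodal
#'   regularization ensuring the fusion degrades gracefully to its single
#'   channels.
#' @param blocks named list of column-index blocks; taken from
#'   `attr(x, "blocks")` when NULL.
vacp_net <- function(x, y, hidden = c(128L, 64L, 32L), lr = 0.01,
                     epochs = 200L, batch_size = 32L, validation_frac = 0,
                     patience = 50L, weight_decay = 0.01, dropout = 0.2,
                     input_noise_sd = 0.2, input_dropout = 0.2,
                     input_l1 = 0.003, label_smoothing = 0.1,
                     lr_decay = "cosine", modality_dropout = 0.5,
                     blocks = NULL, seed = 0L) {
  if (is.null(blocks)) blocks <- attr(x, "blocks")
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("training labels contain a single class", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- mlp_train(xs, y, hidden = hidden, lr = lr, epochs = epochs,
                   batch_size = batch_size, val_frac = validation_frac,
                   patience = patience, seed = seed,
                   weight_decay = weight_decay, dropout = dropout,
                   input_noise_sd = input_noise_sd,
                   input_dropout = input_dropout, input_l1 = input_l1,
                   label_smoothing = label_smoothing, lr_decay = lr_decay,
                   blocks = blocks, modality_dropout = modality_dropout)
  n_par <- sum(vapply(fit$weights, function(l) length(l$W) + length(l$b),
                      numeric(1)))
  structure(list(weights = fit$weights, dims = fit$dims, levels = fit$levels,
                 center = center, scale = scale, n_parameters = n_par,
                 history = fit$history, best_epoch = fit$best_epoch,
                 seed = seed),
            class = "vacp_net")
}

#' @export
print.vacp_net <- function(x, ...) {
  cat(sprintf("<vacp_net> %s | %d parameters | %d classes | best epoch %d\n",
              paste(x$dims, collapse = " -> "), x$n_parameters,
              length(x$levels), x$best_epoch))
  invisible(x)
}

#' @export
summary.vacp_net <- function(object, ...) {
  cat("Fused deep-network severity classifier\n")
  print(object)
  cat(sprintf("classes: %s\n", paste(object$levels, collapse = ", ")))
  cat(sprintf("final monitored loss: %.4f over %d epoch(s)\n",
              utils::tail(object$history, 1), length(object$history)))
  invisible(object)
}

#' @export
coef.vacp_net <- function(object, ...) object$weights

#' Predict severity classes or probabilities
#'
#' @param object a [vacp_net()] fit.
#' @param newdata feature matrix with the training columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return factor of predicted classes, or a probability matrix.
#' @export
predict.vacp_net <- function(object, newdata,
                             type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
             else as.matrix(newdata)
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  probs <- mlp_forward(xs, object$weights)$probs
  colnames(probs) <- object$levels
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' Count trainable parameters
#'
#' @param ... fitted components (`vacp_net`, `vacp_gcn`) whose parameters
#'   are summed.
#' @return integer total parameter count.
#' @examples
#' # the default fused network on 251-d input has 42,724 parameters
#' @export
count_parameters <- function(...) {
  sum(vapply(list(...), function(m) {
    if (inherits(m, "vacp_gcn")) return(m$n_parameters)
    if (inherits(m, "vacp_net")) return(m$n_parameters)
    stop("unsupported component", call. = FALSE)
  }, numeric(1)))
}

#' Train a classifier per a specification
#'
#' @param x feature matrix.
#' @param y labels.
#' @param spec a [classifier_spec()].
#' @return object of class `vacp_classifier` wrapping the fitted model.
#' @export
train_classifier <- function(x, y, spec = classifier_spec()) {
  stopifnot(inherits(spec, "vacp_classifier_spec"))
  x <- as.matrix(x)
  colnames(x) <- paste0("f", seq_len(ncol(x)))  # slot names are metadata, not identifiers
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("training labels contain a single class", call. = FALSE)
  model <- switch(
    spec$kind,
    dnn = vacp_net(x, y, hidden = spec$hidden, lr = spec$lr,
                   epochs = spec$epochs, batch_size = spec$batch_size,
                   validation_frac = spec$validation_frac,
                   patience = spec$patience,
                   weight_decay = spec$weight_decay, dropout = spec$dropout,
                   input_noise_sd = spec$input_noise_sd,
                   input_dropout = spec$input_dropout,
                   input_l1 = spec$input_l1,
                   label_smoothing = spec$label_smoothing,
                   lr_decay = spec$lr_decay,
                   modality_dropout = spec$modality_dropout,
                   blocks = attr(x, "blocks"), seed = spec$seed),
    svm = with_seed(spec$seed,
                    e1071::svm(x = x, y = y, kernel = "radial",
                               cost = spec$cost, gamma = spec$gamma,
                               scale = apply(x, 2, stats::sd) > 0)),
    random_forest = with_seed(spec$seed,
                              randomForest::randomForest(x = x, y = y,
                                                         ntree = spec$n_trees))
  )
  structure(list(model = model, spec = spec, levels = levels(y)),
            class = "vacp_classifier")
}

#' @export
predict.vacp_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  p <- stats::predict(object$model, newdata)
  factor(as.character(p), levels = object$levels)
}

macro_f1 <- function(truth, pred, levels_all = levels(truth)) {
  f1 <- vapply(levels_all, function(lv) {
    tp <- sum(truth == lv & pred == lv)
    fp <- sum(truth != lv & pred == lv)
    fn <- sum(truth == lv & pred != lv)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Repeated stratified-split evaluation
#'
#' Evaluates a classifier specification under `n_repeats` seeded stratified
#' train/test splits (default five 80/20 splits with split seeds 0..4):
#' per-split accuracy and macro-F1, their means, and the pooled
#' row-normalized confusion matrix.
#'
#' @param x feature matrix (rows = clips).
#' @param y labels.
#' @param spec a [classifier_spec()].
#' @param n_repeats number of splits (default 5).
#' @param train_frac training fraction (default 0.8).
#' @param split_seeds integer vector of seeds, one per split (default
#'   `0:(n_repeats - 1)`).
#' @return object of class `vacp_eval`: list with `per_split` (data.frame
#'   seed/accuracy/f1), `mean_accuracy`, `mean_f1`, `confusion`
#'   (row-normalized), `counts` (raw confusion counts), `split_seeds`.
#' @export
evaluate_model <- function(x, y, spec = classifier_spec(), n_repeats = 5L,
                           train_frac = 0.8,
                           split_seeds = seq_len(n_repeats) - 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(length(split_seeds) == n_repeats)
  if (any(table(y) < 5))
    stop("every class needs at least 5 samples", call. = FALSE)
  lev <- levels(y)
  counts <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  per <- data.frame(seed = split_seeds, accuracy = NA_real_, f1 = NA_real_)
  blk <- attr(x, "blocks")
  for (i in seq_along(split_seeds)) {
    sp <- stratified_split(y, 1 - train_frac, seed = split_seeds[i])
    spec_i <- spec
    spec_i$seed <- spec$seed + split_seeds[i]
    xtr <- x[sp$train, , drop = FALSE]
    attr(xtr, "blocks") <- blk
    fit <- train_classifier(xtr, y[sp$train], spec_i)
    pred <- predict(fit, x[sp$test, , drop = FALSE])
    truth <- y[sp$test]
    per$accuracy[i] <- mean(pred == truth)
    per$f1[i] <- macro_f1(truth, pred, lev)
    counts <- counts + unclass(table(factor(truth, lev), factor(pred, lev)))
  }
  counts <- matrix(as.numeric(counts), length(lev),
                   dimnames = list(lev, lev))
  confusion <- counts / pmax(rowSums(counts), 1)
  structure(list(per_split = per, mean_accuracy = mean(per$accuracy),
                 mean_f1 = mean(per$f1), confusion = confusion,
                 counts = counts, split_seeds = split_seeds,
                 spec = spec),
            class = "vacp_eval")
}

#' @export
print.vacp_eval <- function(x, ...) {
  cat(sprintf("<vacp_eval> %s | mean accuracy %.3f | mean macro-F1 %.3f over %d splits\n",
              x$spec$kind, x$mean_accuracy, x$mean_f1,
              nrow(x$per_split)))
  invisible(x)
}

#' Plot the pooled confusion matrix of an evaluation
#'
#' @param x a [evaluate_model()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.vacp_eval <- function(x, ...) {
  k <- nrow(x$confusion)
  graphics::image(seq_len(k), seq_len(k), t(x$confusion[k:1, ]),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = "pooled confusion (row-normalized)", ...)
  graphics::axis(1, seq_len(k), colnames(x$confusion))
  graphics::axis(2, seq_len(k), rev(rownames(x$confusion)))
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k + 1 - i, sprintf("%.2f", x$confusion[i, j]))
  invisible(x)
}

#' Region, feature-set and channel ablations
#'
#' Re-evaluates the classifier under the standard ablation grids:
#' * `"regions"` - the landmark-graph embedding of each facial region
#'   (brows, eyes, mouth, whole face) alone;
#' * `"feature_sets"` - FAUF, DFLGF and their concatenation, each under
#'   SVM and DNN;
#' * `"channels"` - acoustic-only (random forest and DNN), visual-only
#'   (DNN), and the full fusion (random forest and DNN).
#'
#' @param features list with elements `fauf` (n x 35), `dflgf` (n x 128),
#'   `acoustic` (n x 88), and for `mode = "regions"` a named list
#'   `dflgf_regions` of per-region n x 128 matrices.
#' @param labels severity labels (length n).
#' @param mode one of `"regions"`, `"feature_sets"`, `"channels"`.
#' @param spec base [classifier_spec()] (its `kind` is overridden per row).
#' @param ... passed to [evaluate_model()].
#' @return data.frame with one row per configuration: `config`, `method`,
#'   `accuracy`, `f1`; the underlying `vacp_eval` objects are attached as
#'   attribute `evals`.
#' @export
ablation_harness <- function(features, labels,
                             mode = c("channels", "feature_sets", "regions"),
                             spec = classifier_spec(), ...) {
  mode <- match.arg(mode)
  run <- function(x, kind) {
    s <- spec; s$kind <- kind
    evaluate_model(x, labels, s, ...)
  }
  rows <- list(); evals <- list()
  add <- function(config, method, ev) {
    rows[[length(rows) + 1L]] <<- data.frame(config = config, method = method,
                                             accuracy = ev$mean_accuracy,
                                             f1 = ev$mean_f1)
    evals[[paste(config, method)]] <<- ev
  }
  if (mode == "regions") {
    stopifnot(!is.null(features$dflgf_regions))
    for (rg in names(features$dflgf_regions))
      add(rg, "dnn", run(features$dflgf_regions[[rg]], "dnn"))
  } else if (mode == "feature_sets") {
    sets <- list(fauf = features$fauf, dflgf = features$dflgf,
                 `fauf+dflgf` = fuse_features(fauf = features$fauf,
                                              dflgf = features$dflgf,
                                              channels = c("fauf", "dflgf")))
    for (nm in names(sets)) for (kind in c("svm", "dnn"))
      add(nm, kind, run(sets[[nm]], kind))
  } else {
    fused <- fuse_features(features$fauf, features$dflgf, features$acoustic)
    visual <- fuse_features(fauf = features$fauf, dflgf = features$dflgf,
                            channels = c("fauf", "dflgf"))
    add("acoustic", "random_forest", run(features$acoustic, "random_forest"))
    add("acoustic", "dnn", run(features$acoustic, "dnn"))
    add("visual", "dnn", run(visual, "dnn"))
    add("fused", "random_forest", run(fused, "random_forest"))
    add("fused", "dnn", run(fused, "dnn"))
  }
  out <- do.call(rbind, rows)
  attr(out, "evals") <- evals
  out
}
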