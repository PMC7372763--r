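# Feedforward classifier on concatenated embedding pairs.
#
# Architecture 2P -> 128 -> 64 -> 32 -> 2 with ReLU hidden activations,
# dropout on the hidden activations during training, and a two-unit softmax
# head trained by cross-entropy with Adam. Interaction is undirected, so by
# default each labeled pair is presented in both concatenation orders and
# test pairs are scored as the mean of both orders.

#' Classifier configuration
#' @param layers hidden layer widths.
#' @param lr Adam learning rate.
#' @param epochs training iterations (full batch).
#' @param dropout dropout rate on hidden activations.
#' @param seed RNG seed for init and dropout.
#' @return config list.
#' @export
classifier_config <- function(layers = c(128L, 64L, 32L), lr = 0.005,
                              epochs = 50L, dropout = 0.5, seed = 1L) {
  stopifnot(length(layers) >= 1, all(layers > 0), dropout >= 0, dropout < 1,
            epochs >= 0)
  list(layers = as.integer(layers), lr = lr, epochs = as.integer(epochs),
       dropout = dropout, seed = as.integer(seed))
}

#' Build pair features by concatenating two proteins' embeddings
#'
#' @param embeddings N x P embedding matrix with protein ids as rownames
#'   (typically `fit$embeddings$mu`).
#' @param pairs edge list (label column optional).
#' @param symmetrize also emit the reversed concatenation \[z_b || z_a\] for
#'   each pair, with the same label (used in training; at prediction the two
#'   orders are averaged).
#' @return list with `x` (matrix, 2P columns), `pair_index` (row index into
#'   `pairs` per feature row) and `y` (0/1 labels or NULL).
#' @export
pair_features <- function(embeddings, pairs, symmetrize = TRUE) {
  i <- match(pairs$id_a, rownames(embeddings))
  j <- match(pairs$id_b, rownames(embeddings))
  if (anyNA(i) || anyNA(j)) {
    bad <- c(pairs$id_a[is.na(i)], pairs$id_b[is.na(j)])[1L]
    stop("unknown protein id in pairs: ", bad, call. = FALSE)
  }
  x <- cbind(embeddings[i, , drop = FALSE], embeddings[j, , drop = FALSE])
  pair_index <- seq_len(nrow(pairs))
  if (symmetrize) {
    x <- rbind(x, cbind(embeddings[j, , drop = FALSE],
                        embeddings[i, , drop = FALSE]))
    pair_index <- c(pair_index, pair_index)
  }
  y <- NULL
  if (!is.null(pairs$label)) {
    y0 <- as.numeric(pairs$label == "positive")
    y <- y0[pair_index]
  }
  rownames(x) <- NULL
  list(x = x, pair_index = pair_index, y = y)
}

# Forward pass; returns activations for backprop. Dropout masks drawn from
# the current RNG stream when training.
mlp_forward <- function(params, x, dropout = 0, training = FALSE) {
  nh <- length(params$W) - 1L
  a <- x
  acts <- vector("list", nh)
  masks <- vector("list", nh)
  for (l in seq_len(nh)) {
    z <- a %*% params$W[[l]] + matrix(params$b[[l]], nrow(a),
                                      length(params$b[[l]]), byrow = TRUE)
    a <- relu(z)
    if (training && dropout > 0) {
      keep <- matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
      a <- a * keep / (1 - dropout)
      masks[[l]] <- keep / (1 - dropout)
    }
    acts[[l]] <- a
  }
  logits <- a %*% params$W[[nh + 1L]] +
    matrix(params$b[[nh + 1L]], nrow(a), 2L, byrow = TRUE)
  list(logits = logits, prob = softmax_rows(logits), acts = acts,
       masks = masks)
}

mlp_backward <- function(params, x, fwd, y) {
  n <- nrow(x)
  nh <- length(params$W) - 1L
  # softmax + cross-entropy: dlogits = (p - onehot) / n
  d <- fwd$prob
  d[cbind(seq_len(n), y + 1L)] <- d[cbind(seq_len(n), y + 1L)] - 1
  d <- d / n
  gW <- vector("list", nh + 1L)
  gb <- vector("list", nh + 1L)
  a_prev <- if (nh >= 1L) fwd$acts[[nh]] else x
  gW[[nh + 1L]] <- crossprod(a_prev, d)
  gb[[nh + 1L]] <- colSums(d)
  da <- d %*% t(params$W[[nh + 1L]])
  for (l in rev(seq_len(nh))) {
    if (!is.null(fwd$masks[[l]])) da <- da * fwd$masks[[l]]
    dz <- da * (fwd$acts[[l]] > 0) # relu grad; acts>0 <=> preact>0
    a_prev <- if (l > 1L) fwd$acts[[l - 1L]] else x
    gW[[l]] <- crossprod(a_prev, dz)
    gb[[l]] <- colSums(dz)
    if (l > 1L) da <- dz %*% t(params$W[[l]])
  }
  list(W = gW, b = gb)
}

init_mlp <- function(d_in, layers, seed) {
  set.seed(seed)
  sizes <- c(d_in, layers, 2L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- glorot_init(sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' Train the feedforward pair classifier
#'
#' @param features output of [pair_features()] with labels present.
#' @param config from [classifier_config()].
#' @param validation optional [pair_features()] output with labels; when
#'   given, per-epoch validation accuracy is recorded in `val_history`.
#' @return object of class `ppi_classifier` with `params`, `config`,
#'   `val_history`.
#' @export
train_classifier <- function(features, config = classifier_config(),
                             validation = NULL) {
  x <- features$x
  y <- features$y
  if (is.null(y)) stop("training features must carry labels", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  params <- init_mlp(ncol(x), config$layers, derive_seed(config$seed, 11L))
  flat <- function(p) c(p$W, p$b)
  opt <- NULL
  val_history <- numeric(0)
  set.seed(derive_seed(config$seed, 22L))
  for (ep in seq_len(config$epochs)) {
    fwd <- mlp_forward(params, x, dropout = config$dropout, training = TRUE)
    g <- mlp_backward(params, x, fwd, y)
    pl <- c(stats::setNames(params$W, paste0("W", seq_along(params$W))),
            stats::setNames(params$b, paste0("b", seq_along(params$b))))
    gl <- c(stats::setNames(g$W, paste0("W", seq_along(g$W))),
            stats::setNames(g$b, paste0("b", seq_along(g$b))))
    if (is.null(opt)) opt <- adam_init(pl)
    step <- adam_step(pl, gl, opt, lr = config$lr)
    opt <- step$state
    nw <- length(params$W)
    params$W <- unname(step$params[paste0("W", seq_len(nw))])
    params$b <- lapply(step$params[paste0("b", seq_len(nw))], as.numeric)
    names(params$b) <- NULL
    if (!is.null(validation)) {
      vp <- mlp_forward(params, validation$x)$prob[, 2L]
      val_history[ep] <- mean((vp >= 0.5) == (validation$y == 1))
    }
  }
  structure(list(params = params, config = config,
                 val_history = val_history),
            class = "ppi_classifier")
}

#' Predict interaction probabilities for protein pairs
#'
#' Dropout is disabled, so prediction is a pure function of the weights and
#' features. When `features` contains both concatenation orders of each pair
#' (symmetrize on), the probabilities of the two orders are averaged, making
#' the score symmetric in the pair.
#'
#' @param model `ppi_classifier`.
#' @param features output of [pair_features()].
#' @param threshold probability at or above which the label is 1.
#' @return data frame with one row per pair: `probability` and `label`.
#' @export
predict_pairs <- function(model, features, threshold = 0.5) {
  if (ncol(features$x) != nrow(model$params$W[[1L]])) {
    stop("feature width ", ncol(features$x), " does not match classifier ",
         "input size ", nrow(model$params$W[[1L]]), call. = FALSE)
  }
  p <- mlp_forward(model$params, features$x)$prob[, 2L]
  prob <- as.numeric(tapply(p, features$pair_index, mean))
  data.frame(pair = sort(unique(features$pair_index)),
             probability = prob,
             label = as.integer(prob >= threshold))
}

#' @export
print.ppi_classifier <- function(x, ...) {
  sizes <- c(nrow(x$params$W[[1]]), vapply(x$params$W, ncol, integer(1)))
  cat("feedforward PPI classifier:", paste(sizes, collapse = " -> "), "\n")
  invisible(x)
}

#' Write predictions TSV (`id_a  id_b  probability  label`)
#' @param pairs edge list the predictions refer to.
#' @param predictions data frame from [predict_pairs()].
#' @param path output path.
#' @export
write_predictions_tsv <- function(pairs, predictions, path) {
  out <- data.frame(id_a = pairs$id_a[predictions$pair],
                    id_b = pairs$id_b[predictions$pair],
                    probability = predictions$probability,
                    label = predictions$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
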