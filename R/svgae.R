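# The signed variational graph auto-encoder (S-VGAE).
#
# Encoder: a two-layer graph-convolutional network producing a diagonal
# Gaussian posterior per node, GCN(X, A) = A' ReLU(A' X W0) W1 where A' is
# the (optionally normalized) signed adjacency with self-loops; the mean and
# log-std heads share W0. Decoder: p(A_ij = 1 | z_i, z_j) = sigmoid(z_i' z_j).
# The loss is the masked reconstruction cross-entropy over the
# high-confidence cells A* plus the KL divergence of the posterior from a
# standard-normal prior. Trained full-batch with Adam; gradients are
# analytic (verified against finite differences in the test suite).

#' S-VGAE training configuration
#'
#' Defaults: 96 first-layer units, 48 latent dimensions, Adam with learning
#' rate 0.005 for 50 iterations, no encoder dropout, degree-normalized
#' signed propagation, KL scaled per node, class-balanced positive weight.
#'
#' @param hidden1 first GCN layer width.
#' @param hidden2 latent dimension P.
#' @param lr Adam learning rate.
#' @param epochs training iterations (full batch).
#' @param dropout encoder dropout rate on the hidden layer.
#' @param propagation_mode "signed_sym_norm" (default; D^-1/2 A D^-1/2 with
#'   D the diagonal of row sums of |A|, numerically stable) or "raw" (the
#'   adjacency exactly as written, no degree scaling).
#' @param kl_scale multiplier on the summed KL term; "per_node" divides by N.
#' @param pos_weight weight on positive cells in the reconstruction term;
#'   "balanced" uses #masked / (2 #positive).
#' @param seed master seed for weight init and latent sampling.
#' @return a config list.
#' @export
svgae_config <- function(hidden1 = 96L, hidden2 = 48L, lr = 0.005,
                         epochs = 50L, dropout = 0,
                         propagation_mode = c("signed_sym_norm", "raw"),
                         kl_scale = "per_node", pos_weight = "balanced",
                         seed = 1L) {
  stopifnot(hidden1 > 0, hidden2 > 0, lr > 0, epochs >= 0,
            dropout >= 0, dropout < 1)
  list(hidden1 = as.integer(hidden1), hidden2 = as.integer(hidden2),
       lr = lr, epochs = as.integer(epochs), dropout = dropout,
       propagation_mode = match.arg(propagation_mode),
       kl_scale = kl_scale, pos_weight = pos_weight, seed = as.integer(seed))
}

#' Propagation matrix for the graph-convolutional encoder
#'
#' @param adj `signed_adjacency`.
#' @param mode "signed_sym_norm" returns D^-1/2 A D^-1/2 with
#'   D = diag(rowSums(|A|)); "raw" returns A unchanged (self-loops already
#'   on the diagonal).
#' @return N x N numeric matrix.
#' @export
propagation_matrix <- function(adj, mode = c("signed_sym_norm", "raw")) {
  mode <- match.arg(mode)
  A <- adj$matrix
  if (mode == "raw") return(A)
  d <- rowSums(abs(A))
  d[d == 0] <- 1
  s <- 1 / sqrt(d)
  A * outer(s, s)
}

#' One graph-convolution layer: activation(P %*% X %*% W)
#' @param X N x F node features.
#' @param P_mat N x N propagation matrix.
#' @param W F x G weight matrix.
#' @param activation "relu" or "identity".
#' @return N x G matrix.
#' @export
gcn_layer <- function(X, P_mat, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(P_mat) != nrow(X) || ncol(X) != nrow(W)) {
    stop("dimension mismatch: P ", nrow(P_mat), "x", ncol(P_mat),
         ", X ", nrow(X), "x", ncol(X), ", W ", nrow(W), "x", ncol(W),
         call. = FALSE)
  }
  out <- P_mat %*% X %*% W
  if (activation == "relu") out <- relu(out)
  out
}

#' Variational encoder forward pass
#'
#' hidden = ReLU(P X W0); mu = P hidden W1_mu; log_sigma = P hidden W1_sig.
#' Dropout (if any) applies to the hidden layer during training only.
#'
#' @param X feature matrix.
#' @param P_mat propagation matrix.
#' @param weights list with `W0`, `W1_mu`, `W1_sig`.
#' @param dropout dropout rate on the hidden layer.
#' @param training apply dropout?
#' @return list with `mu` and `log_sigma` (N x P each).
#' @export
encode <- function(X, P_mat, weights, dropout = 0, training = FALSE) {
  H <- gcn_layer(X, P_mat, weights$W0, "relu")
  if (training && dropout > 0) {
    keep <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
    H <- H * keep / (1 - dropout)
  }
  PH <- P_mat %*% H
  mu <- PH %*% weights$W1_mu
  log_sigma <- PH %*% weights$W1_sig
  if (!all(is.finite(mu)) || !all(is.finite(log_sigma))) {
    stop("non-finite encoder output", call. = FALSE)
  }
  list(mu = mu, log_sigma = log_sigma)
}

#' Reparameterization: z = mu + exp(log_sigma) * eps, eps ~ N(0, I)
#' @param mu,log_sigma matrices of equal shape.
#' @param seed RNG seed for the standard-normal draw.
#' @return sampled latent matrix z.
#' @export
reparameterize <- function(mu, log_sigma, seed = 1L) {
  stopifnot(identical(dim(mu), dim(log_sigma)))
  set.seed(seed)
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  mu + exp(log_sigma) * eps
}

#' Inner-product decoder for a single pair
#' @param z_i,z_j latent vectors of equal length.
#' @return interaction probability sigmoid(z_i' z_j), in (0, 1).
#' @export
decode_pair <- function(z_i, z_j) {
  stopifnot(length(z_i) == length(z_j))
  as.numeric(sigmoid(sum(z_i * z_j)))
}

#' KL divergence of a diagonal Gaussian posterior from the standard normal
#'
#' 0.5 * sum(exp(2 log_sigma) + mu^2 - 1 - 2 log_sigma), optionally scaled.
#'
#' @param mu,log_sigma matrices of equal shape.
#' @param scale multiplier (training uses 1/N for a per-node mean).
#' @return nonnegative scalar.
#' @export
kl_term <- function(mu, log_sigma, scale = 1) {
  stopifnot(identical(dim(mu), dim(log_sigma)) ||
              length(mu) == length(log_sigma))
  scale * 0.5 * sum(exp(2 * log_sigma) + mu^2 - 1 - 2 * log_sigma)
}

# Positive-cell weight: "balanced" = #masked / (2 #positive cells).
resolve_pos_weight <- function(pos_weight, adj) {
  if (identical(pos_weight, "balanced")) {
    npos <- sum(adj$matrix[adj$mask] == 1)
    if (npos == 0) return(1)
    sum(adj$mask) / (2 * npos)
  } else {
    as.numeric(pos_weight)
  }
}

#' Masked reconstruction cross-entropy
#'
#' Mean binary cross-entropy of sigmoid(Z Z') against targets 1 (A = +1) and
#' 0 (A = -1) over the high-confidence mask only; unmasked cells contribute
#' nothing. Positive cells can be up-weighted to balance classes.
#'
#' @param Z latent matrix (N x P).
#' @param adj `signed_adjacency`.
#' @param pos_weight weight on positive cells (1 = unweighted;
#'   "balanced" as in [svgae_config()]).
#' @return scalar loss (weighted mean over masked cells).
#' @export
reconstruction_term <- function(Z, adj, pos_weight = 1) {
  M <- adj$mask
  if (!any(M)) stop("empty confidence mask: nothing to reconstruct",
                    call. = FALSE)
  w_pos <- resolve_pos_weight(pos_weight, adj)
  logits <- (Z %*% t(Z))[M]
  targets <- as.numeric(adj$matrix[M] == 1)
  w <- ifelse(targets == 1, w_pos, 1)
  sum(w * bce_from_logits(logits, targets)) / sum(M)
}

# Forward + backward pass; returns loss components and parameter gradients.
svgae_grad <- function(params, AhX, P_mat, adj, eps, w_pos, kl_scale,
                       dropout = 0, training = TRUE) {
  N <- nrow(AhX)
  Hpre <- AhX %*% params$W0
  H <- relu(Hpre)
  drop_scale <- NULL
  if (training && dropout > 0) {
    keep <- matrix(stats::runif(length(H)) >= dropout, N, ncol(H))
    drop_scale <- keep / (1 - dropout)
    H <- H * drop_scale
  }
  PH <- P_mat %*% H
  mu <- PH %*% params$W1_mu
  S <- PH %*% params$W1_sig
  Z <- mu + exp(S) * eps

  M <- adj$mask
  norm <- sum(M)
  logits <- Z %*% t(Z)
  targets <- (adj$matrix == 1) * 1
  W <- matrix(0, N, N)
  W[M] <- ifelse(targets[M] == 1, w_pos, 1)
  recon <- sum(W[M] * bce_from_logits(logits[M], targets[M])) / norm
  kl <- kl_term(mu, S, kl_scale)
  total <- recon + kl

  # backward
  G <- W * (sigmoid(logits) - targets) / norm # zero off-mask since W is
  dZ <- (G + t(G)) %*% Z
  dmu <- dZ + kl_scale * mu
  dS <- dZ * eps * exp(S) + kl_scale * (exp(2 * S) - 1)

  dW1_mu <- crossprod(PH, dmu)
  dW1_sig <- crossprod(PH, dS)
  dH <- crossprod(P_mat, dmu %*% t(params$W1_mu) + dS %*% t(params$W1_sig))
  if (!is.null(drop_scale)) dH <- dH * drop_scale
  dHpre <- dH * (Hpre > 0)
  dW0 <- crossprod(AhX, dHpre)

  list(loss = list(total = total, reconstruction = recon, kl = kl),
       grads = list(W0 = dW0, W1_mu = dW1_mu, W1_sig = dW1_sig),
       mu = mu, log_sigma = S, z = Z)
}

#' Train the signed variational graph auto-encoder
#'
#' Full-batch Adam minimization of the masked reconstruction + KL loss.
#' Weights are Glorot-initialized under a seed derived from `config$seed`;
#' a fresh standard-normal draw reparameterizes z each epoch. At inference
#' the posterior mean mu is used as the embedding, making downstream
#' predictions deterministic.
#'
#' @param X feature matrix (N x R), rows aligned with `adj$node_index`.
#' @param adj `signed_adjacency` with a nonempty confidence mask.
#' @param config from [svgae_config()].
#' @return object of class `svgae_fit`: `weights`, `embeddings` (list with
#'   `mu`, `log_sigma`, `z`, `seed`), `history` (per-epoch loss data frame),
#'   `config`.
#' @export
train_svgae <- function(X, adj, config = svgae_config()) {
  stopifnot(nrow(X) == nrow(adj$matrix))
  if (!any(adj$mask)) stop("empty confidence mask", call. = FALSE)
  N <- nrow(X)
  P_mat <- propagation_matrix(adj, config$propagation_mode)
  AhX <- P_mat %*% X
  kl_scale <- if (identical(config$kl_scale, "per_node")) 1 / N
              else as.numeric(config$kl_scale)
  w_pos <- resolve_pos_weight(config$pos_weight, adj)

  set.seed(derive_seed(config$seed, 101L))
  params <- list(
    W0 = glorot_init(ncol(X), config$hidden1),
    W1_mu = glorot_init(config$hidden1, config$hidden2),
    W1_sig = glorot_init(config$hidden1, config$hidden2)
  )
  opt <- adam_init(params)
  history <- vector("list", config$epochs)

  set.seed(derive_seed(config$seed, 202L))
  last_ok <- NULL
  for (ep in seq_len(config$epochs)) {
    eps <- matrix(stats::rnorm(N * config$hidden2), N, config$hidden2)
    fb <- svgae_grad(params, AhX, P_mat, adj, eps, w_pos, kl_scale,
                     dropout = config$dropout, training = TRUE)
    if (!is.finite(fb$loss$total)) {
      stop("training diverged at epoch ", ep, "; last finite loss: ",
           if (is.null(last_ok)) "none" else
             format(last_ok$total, digits = 6), call. = FALSE)
    }
    last_ok <- fb$loss
    history[[ep]] <- data.frame(epoch = ep, total = fb$loss$total,
                                reconstruction = fb$loss$reconstruction,
                                kl = fb$loss$kl)
    step <- adam_step(params, fb$grads, opt, lr = config$lr)
    params <- step$params
    opt <- step$state
  }

  post <- encode(X, P_mat, params, dropout = 0, training = FALSE)
  z_seed <- derive_seed(config$seed, 303L)
  z <- reparameterize(post$mu, post$log_sigma, z_seed)
  rownames(post$mu) <- rownames(post$log_sigma) <- rownames(z) <-
    adj$node_index
  structure(list(
    weights = params,
    embeddings = list(mu = post$mu, log_sigma = post$log_sigma, z = z,
                      seed = z_seed),
    history = do.call(rbind, history) %||%
      data.frame(epoch = integer(), total = numeric(),
                 reconstruction = numeric(), kl = numeric()),
    config = config
  ), class = "svgae_fit")
}

#' @export
print.svgae_fit <- function(x, ...) {
  cat("S-VGAE fit:", nrow(x$embeddings$mu), "proteins,",
      ncol(x$embeddings$mu), "latent dimensions,",
      nrow(x$history), "epochs\n")
  if (nrow(x$history)) {
    cat(sprintf("  final loss %.4f (reconstruction %.4f, KL %.4f)\n",
                x$history$total[nrow(x$history)],
                x$history$reconstruction[nrow(x$history)],
                x$history$kl[nrow(x$history)]))
  }
  invisible(x)
}

#' Export embeddings as TSV (id + P columns)
#' @param fit `svgae_fit`.
#' @param path output path.
#' @export
write_embeddings_tsv <- function(fit, path) {
  mu <- fit$embeddings$mu
  df <- data.frame(id = rownames(mu), mu, check.names = FALSE)
  colnames(df) <- c("id", paste0("z", seq_len(ncol(mu))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
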