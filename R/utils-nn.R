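# Small numerical building blocks shared by the encoder and the classifier.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Numerically stable logistic sigmoid
#' @param x numeric vector or matrix of logits.
#' @return values in (0, 1), same shape as `x`.
#' @keywords internal
sigmoid <- function(x) {
  # 1/(1+exp(-x)) overflows for large |x|; split by sign
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# Row-wise softmax with max-shift for stability.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Binary cross-entropy from logits: max(l,0) - l*t + log(1+exp(-|l|)).
bce_from_logits <- function(logits, targets) {
  pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
}

#' Glorot (Xavier) uniform weight initialization
#'
#' Draws from U(-s, s) with s = sqrt(6 / (fan_in + fan_out)), the scheme
#' commonly used for layers feeding (sub)linear activations.
#'
#' @param fan_in,fan_out layer dimensions.
#' @return a `fan_in` x `fan_out` matrix.
#' @keywords internal
glorot_init <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

# Adam optimizer state for a named list of parameter matrices.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

# One Adam update. `grads` is a named list matching `params`.
adam_step <- function(params, grads, state, lr = 0.005,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Derive a stage seed from a master seed
#'
#' One master seed drives every stochastic stage (weight init, sampling,
#' dropout, splitting). Stage seeds are derived with a Lehmer-style mix so
#' stages are decorrelated but fully reproducible; results stay within
#' 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param stage integer stage offset.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647 # 2^31 - 1
  x <- (as.numeric(seed) %% m) + 1
  for (k in seq_len(stage %% 64 + 1)) {
    x <- (x * 48271 + stage * 2246822519 + k) %% m
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
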