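# Fully connected autoencoder with a Poisson reconstruction likelihood.
# Implemented directly in matrix algebra: forward pass, backpropagation and
# a decoupled-weight-decay Adam optimizer. Hidden layers use softplus (a
# smooth rectifier); the decoder's final pre-activation is clamped and
# exponentiated so reconstruction rates are strictly positive and finite.

RATE_LOG_MIN <- log(1e-8)
RATE_LOG_MAX <- log(1e8)

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize multilayer perceptron parameters
#'
#' Fan-in scaled Gaussian initialization (sd = sqrt(2 / fan_in)), zero
#' biases, controlled by a seed for reproducibility.
#'
#' @param widths integer vector of layer widths, input first, output last;
#'   e.g. `c(2000, 256, 128, 32)` for the default encoder.
#' @param seed integer RNG seed.
#' @return list of layers, each `list(W, b)`, with the width spec attached.
#' @export
mlp_init <- function(widths, seed = 0L) {
  stopifnot(length(widths) >= 2, all(widths >= 1))
  set.seed(seed)
  layers <- vector("list", length(widths) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- widths[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, widths[l + 1L]),
      b = numeric(widths[l + 1L])
    )
  }
  structure(list(layers = layers, widths = as.integer(widths)),
            class = "mlp_params")
}

# forward pass; hidden layers softplus, last layer linear.
# keep_cache stores pre-activations and activations for backprop.
mlp_forward <- function(x, params, keep_cache = FALSE) {
  L <- length(params$layers)
  acts <- vector("list", L + 1L)
  pres <- vector("list", L)
  acts[[1L]] <- x
  h <- x
  for (l in seq_len(L)) {
    a <- sweep(h %*% params$layers[[l]]$W, 2L, params$layers[[l]]$b, "+")
    pres[[l]] <- a
    h <- if (l < L) softplus(a) else a
    acts[[l + 1L]] <- h
  }
  if (keep_cache) list(out = h, acts = acts, pres = pres) else list(out = h)
}

# backpropagation given d(loss)/d(output); returns parameter gradients and
# the gradient with respect to the input rows.
mlp_backward <- function(cache, params, d_out) {
  L <- length(params$layers)
  grads <- vector("list", L)
  delta <- d_out
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * sigmoid(cache$pres[[l]])
    grads[[l]] <- list(W = crossprod(cache$acts[[l]], delta),
                       b = colSums(delta))
    delta <- tcrossprod(delta, params$layers[[l]]$W)
  }
  list(grads = grads, d_input = delta)
}

#' Encode cells into the latent space
#'
#' Deterministic map `z = f(x; theta_f)`: a fully connected network applied
#' to rows of the processed expression matrix.
#'
#' @param x numeric matrix, batch x G' (G' must match the encoder's input
#'   width).
#' @param params encoder parameters from [mlp_init()] or a trained model.
#' @return numeric matrix, batch x D.
#' @export
encode <- function(x, params) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  expected <- params$widths[1L]
  if (ncol(x) != expected)
    stop(sprintf("encoder input width mismatch: expected %d columns, got %d",
                 expected, ncol(x)))
  mlp_forward(x, params)$out
}

#' Decode latent rows into Poisson rates
#'
#' Deterministic map `eta = g(z; theta_g)`. The final pre-activation is
#' clamped to `[ln 1e-8, ln 1e8]` and exponentiated, so every rate is
#' strictly positive and finite (canonical Poisson log-link).
#'
#' @param z numeric matrix, batch x D.
#' @param params decoder parameters.
#' @return strictly positive numeric matrix, batch x G'.
#' @export
decode <- function(z, params) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  expected <- params$widths[1L]
  if (ncol(z) != expected)
    stop(sprintf("decoder input width mismatch: expected %d columns, got %d",
                 expected, ncol(z)))
  a <- mlp_forward(z, params)$out
  if (any(!is.finite(a))) {
    bad <- which(!is.finite(rowSums(a)))[1L]
    stop(sprintf("non-finite decoder output at batch row %d", bad))
  }
  exp(pmin(pmax(a, RATE_LOG_MIN), RATE_LOG_MAX))
}

#' Exact Poisson negative log-likelihood
#'
#' `sum_g [eta_g - x_g * ln(eta_g) + ln(x_g!)]`, the full negative log
#' Poisson mass including the `ln(x!)` term (via log-gamma). During gradient
#' optimization the constant `ln(x!)` may be dropped, but this operation
#' always returns the complete value.
#'
#' @param x nonnegative integer vector (or matrix of one cell per row).
#' @param eta positive rate vector of matching length.
#' @return nonnegative real scalar.
#' @export
poisson_nll <- function(x, eta) {
  x <- as.vector(x); eta <- as.vector(eta)
  if (length(x) != length(eta)) stop("x and eta must have equal length")
  if (any(eta <= 0) || any(!is.finite(eta)))
    stop("eta must be strictly positive and finite")
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("x must contain nonnegative integers")
  sum(eta - x * log(eta) + lgamma(x + 1))
}

# ---- AdamW -----------------------------------------------------------------

adamw_init <- function(params) {
  zeros <- lapply(params$layers, function(l)
    list(W = array(0, dim(l$W)), b = numeric(length(l$b))))
  list(m = zeros, v = zeros, t = 0L)
}

adamw_step <- function(params, grads, opt, lr = 1e-4, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(params$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      opt$m[[l]][[p]] <- beta1 * opt$m[[l]][[p]] + (1 - beta1) * g
      opt$v[[l]][[p]] <- beta2 * opt$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- opt$m[[l]][[p]] / bc1
      vhat <- opt$v[[l]][[p]] / bc2
      upd <- mhat / (sqrt(vhat) + eps)
      if (p == "W" && weight_decay > 0)
        upd <- upd + weight_decay * params$layers[[l]][[p]]
      params$layers[[l]][[p]] <- params$layers[[l]][[p]] - lr * upd
    }
  }
  list(params = params, opt = opt)
}
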