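# Training: autoencoder pretraining, then alternating minimization of the
# combined loss  l = l_AE + lambda * l_DPMM_z  with periodic refits of the
# mixture posterior on the full latent matrix.

#' Training configuration
#'
#' Defaults follow the reference hyperparameters: encoder hidden widths
#' (256, 128), latent dimension 32, minibatch size 512, AdamW at a fixed
#' learning rate of 1e-4, loss weight `lambda = 1`, concentration
#' `alpha = 1e-10`, truncation `K_max = 50`.
#'
#' @param n_hvg,scale_factor,clip_max preprocessing parameters.
#' @param latent_dim latent dimensionality D.
#' @param hidden encoder hidden layer widths (decoder mirrors them).
#' @param lambda weight of the mixture-density loss in the combined loss.
#' @param alpha Dirichlet process concentration.
#' @param batch_size minibatch size.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param epochs coupled-training epochs (the fixed loop length T, in
#'   epochs).
#' @param pretrain_epochs maximum pretraining epochs (a plateau rule may
#'   stop earlier).
#' @param s_update_every epochs between mixture refits (the interval I).
#' @param K_max mixture truncation level.
#' @param s_max_iter variational iterations per refit during training
#'   (refits are warm-started; the initial and final fits use
#'   `s_max_iter_full`).
#' @param s_max_iter_full variational iterations for the initial and final
#'   full fits.
#' @param s_tol ELBO improvement threshold for the variational fits.
#' @param seed master seed; all randomness (init, shuffling, mixture
#'   seeding) derives from it.
#' @return list of class `dac_config`.
#' @export
dac_config <- function(n_hvg = 4000L, scale_factor = 1e4, clip_max = 10,
                       latent_dim = 32L, hidden = c(256L, 128L),
                       lambda = 1, alpha = 1e-10, batch_size = 512L,
                       lr = 1e-4, weight_decay = 0.01,
                       epochs = 100L, pretrain_epochs = 50L,
                       s_update_every = 1L, K_max = 50L,
                       s_max_iter = 10L, s_max_iter_full = 500L,
                       s_tol = 1e-6, seed = 0L) {
  stopifnot(lambda >= 0, alpha > 0, batch_size >= 1, s_update_every >= 1,
            epochs >= 0, pretrain_epochs >= 0, K_max >= 2, lr > 0)
  structure(as.list(environment()), class = "dac_config")
}

# one AdamW step on the combined loss for one minibatch.
# state = NULL or lambda = 0 reduces exactly to an autoencoder-only step.
train_step <- function(enc, dec, opt_e, opt_d, Xs, Xr, lgamma_rows,
                       state = NULL, lambda = 0, lr = 1e-4,
                       weight_decay = 0.01) {
  B <- nrow(Xs)
  fe <- mlp_forward(Xs, enc, keep_cache = TRUE)
  Zb <- fe$out
  fd <- mlp_forward(Zb, dec, keep_cache = TRUE)
  a <- pmin(pmax(fd$out, RATE_LOG_MIN), RATE_LOG_MAX)
  eta <- exp(a)
  in_range <- fd$out > RATE_LOG_MIN & fd$out < RATE_LOG_MAX
  recon <- (sum(eta) - sum(Xr * a) + sum(lgamma_rows)) / B
  d_a <- (eta - Xr) * in_range / B
  bd <- mlp_backward(fd, dec, d_a)
  dZ <- bd$d_input
  zl <- 0
  if (!is.null(state) && lambda > 0) {
    zl <- mean(loss_z(Zb, state))
    dZ <- dZ + (lambda / B) * loss_z_grad(Zb, state)
  }
  be <- mlp_backward(fe, enc, dZ)
  sd_ <- adamw_step(dec, bd$grads, opt_d, lr = lr, weight_decay = weight_decay)
  se <- adamw_step(enc, be$grads, opt_e, lr = lr, weight_decay = weight_decay)
  list(enc = se$params, dec = sd_$params, opt_e = se$opt, opt_d = sd_$opt,
       recon = recon, zloss = zl)
}

# deterministic minibatch index list for one epoch
epoch_batches <- function(n, batch_size, seed) {
  set.seed(seed)
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}

#' Pretrain the autoencoder
#'
#' Minimizes the Poisson reconstruction loss alone by minibatch AdamW for at
#' most `pretrain_epochs` epochs, stopping early when the relative epoch-loss
#' improvement over the last 5 epochs falls below 1e-4. The decoder's output
#' bias is initialized at the log of the per-gene mean count so rates start
#' near the data scale.
#'
#' @param data list from [preprocess_counts()] (fields `processed`,
#'   `raw_hvg`), or any list with a `processed$values` matrix and matching
#'   raw integer matrix.
#' @param config a [dac_config()].
#' @return list with `encoder`, `decoder`, `trace` (per-epoch data.frame),
#'   and the optimizer states (so coupled training can continue seamlessly).
#' @export
pretrain_ae <- function(data, config = dac_config()) {
  Xs <- data$processed$values
  Xr <- data$raw_hvg
  stopifnot(nrow(Xs) >= 1, all(dim(Xs) == dim(Xr)))
  gp <- ncol(Xs)
  enc <- mlp_init(c(gp, config$hidden, config$latent_dim),
                  seed = config$seed + 1L)
  dec <- mlp_init(c(config$latent_dim, rev(config$hidden), gp),
                  seed = config$seed + 2L)
  dec$layers[[length(dec$layers)]]$b <- log(pmax(colMeans(Xr), 1e-8))
  opt_e <- adamw_init(enc); opt_d <- adamw_init(dec)
  lgamma_all <- rowSums(lgamma(Xr + 1))
  n <- nrow(Xs)
  trace <- data.frame()
  losses <- numeric(0)
  for (epoch in seq_len(config$pretrain_epochs)) {
    batches <- epoch_batches(n, config$batch_size, config$seed + 7919L * epoch)
    tot <- 0
    for (b in batches) {
      st <- train_step(enc, dec, opt_e, opt_d, Xs[b, , drop = FALSE],
                       Xr[b, , drop = FALSE], lgamma_all[b],
                       lr = config$lr, weight_decay = config$weight_decay)
      enc <- st$enc; dec <- st$dec; opt_e <- st$opt_e; opt_d <- st$opt_d
      tot <- tot + st$recon * length(b)
    }
    ep_loss <- tot / n
    if (!is.finite(ep_loss))
      stop(sprintf("pretraining diverged at epoch %d (last finite epoch %d)",
                   epoch, epoch - 1L))
    losses <- c(losses, ep_loss)
    trace <- rbind(trace, data.frame(phase = "pretrain", epoch = epoch,
                                     recon = ep_loss, zloss = NA_real_,
                                     combined = ep_loss, k_eff = NA_integer_))
    if (epoch > 5L) {
      prev <- losses[epoch - 5L]
      if (abs(prev - ep_loss) < 1e-4 * abs(prev)) break
    }
  }
  list(encoder = enc, decoder = dec, trace = trace,
       opt_e = opt_e, opt_d = opt_d)
}

#' Coupled training of autoencoder and mixture
#'
#' Runs pretraining (unless `pretrained` is supplied), fits the mixture on
#' the pretrained latent matrix, then alternates: minibatch AdamW steps on
#' the combined loss `l_AE + lambda * l_DPMM_z` with the mixture frozen, and
#' every `s_update_every` epochs a warm-started variational refit of the
#' mixture on the full-data latent matrix. Ends with a full refit.
#'
#' @param data list from [preprocess_counts()].
#' @param config a [dac_config()].
#' @param pretrained optional result of [pretrain_ae()] to skip pretraining.
#' @return list with `encoder`, `decoder`, `state` (a `dpmm_state`), and
#'   `trace`.
#' @export
train <- function(data, config = dac_config(), pretrained = NULL) {
  if (is.null(pretrained)) pretrained <- pretrain_ae(data, config)
  enc <- pretrained$encoder; dec <- pretrained$decoder
  opt_e <- pretrained$opt_e; opt_d <- pretrained$opt_d
  trace <- pretrained$trace
  Xs <- data$processed$values; Xr <- data$raw_hvg
  n <- nrow(Xs)
  lgamma_all <- rowSums(lgamma(Xr + 1))

  Zf <- encode(Xs, enc)
  state <- fit_S(Zf, alpha = config$alpha, K_max = config$K_max,
                 max_iter = config$s_max_iter_full, tol = config$s_tol,
                 seed = config$seed + 3L, merge_moves = FALSE)

  for (epoch in seq_len(config$epochs)) {
    batches <- epoch_batches(n, config$batch_size,
                             config$seed + 7919L * epoch + 104729L)
    tot_r <- 0; tot_z <- 0
    for (b in batches) {
      st <- train_step(enc, dec, opt_e, opt_d, Xs[b, , drop = FALSE],
                       Xr[b, , drop = FALSE], lgamma_all[b],
                       state = state, lambda = config$lambda,
                       lr = config$lr, weight_decay = config$weight_decay)
      enc <- st$enc; dec <- st$dec; opt_e <- st$opt_e; opt_d <- st$opt_d
      tot_r <- tot_r + st$recon * length(b)
      tot_z <- tot_z + st$zloss * length(b)
    }
    if (!is.finite(tot_r))
      stop(sprintf("training diverged at epoch %d", epoch))
    if (epoch %% config$s_update_every == 0L) {
      # refits are re-seeded afresh each time (the behavior of the widely
      # used variational mixture implementation this module mirrors):
      # re-drawn micro-partitions never entrench, so the latent condenses
      # collectively around its clusters instead of freezing an arbitrary
      # initial fragmentation
      Zf <- encode(Xs, enc)
      new_state <- tryCatch(
        fit_S(Zf, alpha = config$alpha, K_max = config$K_max,
              max_iter = config$s_max_iter, tol = config$s_tol,
              seed = config$seed + 3L + epoch, merge_moves = FALSE),
        error = function(e) NULL)
      if (!is.null(new_state)) state <- new_state
    }
    trace <- rbind(trace, data.frame(
      phase = "train", epoch = epoch, recon = tot_r / n,
      zloss = tot_z / n,
      combined = tot_r / n + config$lambda * tot_z / n,
      k_eff = effective_cluster_count(state)))
  }

  # final full fit, then observation-space merging: components whose
  # Poisson count profiles are indistinguishable are fused, which is what
  # lets the occupied-component count settle at the data's cluster count
  Zf <- encode(Xs, enc)
  state <- fit_S(Zf, alpha = config$alpha, K_max = config$K_max,
                 max_iter = config$s_max_iter_full, tol = config$s_tol,
                 seed = config$seed + 3L, merge_moves = FALSE)
  state <- merge_components_profiles(state, Zf, Xr, alpha = config$alpha)
  list(encoder = enc, decoder = dec, state = state, trace = trace)
}

#' Infer cluster labels with a trained model
#'
#' `y_n = argmax_k r_k(f(x_n))`, ties broken by the lowest component index.
#'
#' @param data list from [preprocess_counts()] (or a bare processed matrix).
#' @param encoder trained encoder parameters.
#' @param state fitted `dpmm_state`.
#' @return list of class `clustering_result` with integer `labels` (values
#'   are mixture component indices), `k_eff`, `cell_ids`.
#' @export
infer_labels <- function(data, encoder, state) {
  Xs <- if (is.matrix(data)) data else data$processed$values
  cell_ids <- if (is.matrix(data)) rownames(data) else data$cell_ids
  Zf <- encode(Xs, encoder)
  r <- responsibilities(Zf, state)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  labels <- max.col(r, ties.method = "first")
  structure(list(labels = labels, k_eff = length(unique(labels)),
                 cell_ids = cell_ids),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d cells in %d cluster(s)\n",
              length(x$labels), x$k_eff))
  invisible(x)
}

#' Fit the full pipeline on a count matrix
#'
#' Preprocessing (HVG selection, normalization, scaling), autoencoder
#' pretraining, coupled training with the DPMM, and label inference.
#'
#' @param counts a [count_matrix()].
#' @param config a [dac_config()].
#' @param couple logical; `FALSE` gives the decoupled reduce-then-cluster
#'   baseline (pretraining followed by a single mixture fit, no joint
#'   optimization).
#' @return object of class `celldpm_fit`: `config`, `prep` (preprocessing
#'   statistics), `encoder`, `decoder`, `state`, `trace`, `result`
#'   (a `clustering_result`).
#' @export
dac_fit <- function(counts, config = dac_config(), couple = TRUE) {
  data <- preprocess_counts(counts, n_hvg = config$n_hvg,
                            scale_factor = config$scale_factor,
                            clip_max = config$clip_max)
  if (couple) {
    tr <- train(data, config)
  } else {
    pre <- pretrain_ae(data, config)
    Zf <- encode(data$processed$values, pre$encoder)
    state <- fit_S(Zf, alpha = config$alpha, K_max = config$K_max,
                   max_iter = config$s_max_iter_full, tol = config$s_tol,
                   seed = config$seed + 3L, merge_moves = FALSE)
    state <- merge_components_profiles(state, Zf, data$raw_hvg,
                                       alpha = config$alpha)
    tr <- list(encoder = pre$encoder, decoder = pre$decoder, state = state,
               trace = pre$trace)
  }
  res <- infer_labels(data, tr$encoder, tr$state)
  structure(list(config = config, prep = data[c("processed", "cell_ids",
                                                "gene_ids")],
                 encoder = tr$encoder, decoder = tr$decoder,
                 state = tr$state, trace = tr$trace, result = res),
            class = "celldpm_fit")
}

#' @export
print.celldpm_fit <- function(x, ...) {
  cat(sprintf(
    "celldpm_fit: %d cells, %d selected genes, %d cluster(s) found\n",
    length(x$result$labels), ncol(x$prep$processed$values), x$result$k_eff))
  invisible(x)
}

#' Encode a count matrix with a fitted model's preprocessing and encoder
#'
#' Applies the stored recipe (HVG columns, normalization, per-gene scaling
#' statistics recorded at fit time) and the trained encoder.
#'
#' @param fit a `celldpm_fit` or loaded checkpoint.
#' @param counts a [count_matrix()] with the same gene universe.
#' @return latent matrix, cells x D.
#' @export
encode_counts <- function(fit, counts) {
  norm <- normalize_log(counts, scale_factor = fit$config$scale_factor)
  pm <- fit$prep$processed
  sub <- norm[, pm$hvg_indices, drop = FALSE]
  vals <- sweep(sweep(sub, 2L, pm$per_gene_mean, "-"), 2L,
                pm$per_gene_sd, "/")
  vals <- pmin(vals, fit$config$clip_max)
  encode(vals, fit$encoder)
}
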