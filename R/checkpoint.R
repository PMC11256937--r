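# Versioned JSON checkpoint: encoder/decoder weights, layer spec, HVG
# indices and scaling statistics, and the mixture state needed for
# inference, so labels and latent coordinates can be recomputed without
# retraining. Plain text on purpose - portable and diffable.

CHECKPOINT_VERSION <- "celldpm-checkpoint-1"

mlp_to_list <- function(p) {
  list(widths = p$widths,
       layers = lapply(p$layers, function(l) list(W = l$W, b = l$b)))
}

mlp_from_list <- function(x) {
  layers <- lapply(x$layers, function(l) {
    W <- if (is.list(l$W) && !is.data.frame(l$W))
      do.call(rbind, lapply(l$W, as.numeric))
    else as.matrix(l$W)
    storage.mode(W) <- "double"
    list(W = unname(W), b = as.numeric(l$b))
  })
  structure(list(layers = layers, widths = as.integer(unlist(x$widths))),
            class = "mlp_params")
}

#' Save a fitted model to a JSON checkpoint
#'
#' @param fit a `celldpm_fit` from [dac_fit()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "celldpm_fit"))
  st <- fit$state
  obj <- list(
    version = CHECKPOINT_VERSION,
    config = unclass(fit$config),
    prep = list(hvg_indices = fit$prep$processed$hvg_indices,
                per_gene_mean = fit$prep$processed$per_gene_mean,
                per_gene_sd = fit$prep$processed$per_gene_sd),
    encoder = mlp_to_list(fit$encoder),
    decoder = mlp_to_list(fit$decoder),
    state = list(delta = st$delta, alpha = st$alpha, weights = st$weights,
                 mu = st$mu, Lambda = st$Lambda, gamma1 = st$gamma1,
                 gamma2 = st$gamma2, kappa = st$kappa, nu = st$nu,
                 hyper = st$hyper, K_max = st$K_max, D = st$D)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a JSON checkpoint
#'
#' Restores an object usable by [encode_counts()], [infer_labels()] and
#' [responsibilities()]; training history and responsibilities are not
#' stored.
#'
#' @param path checkpoint path from [save_checkpoint()].
#' @return list of class `celldpm_fit`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("unrecognized checkpoint version: ", obj$version)
  cfg <- obj$config
  class(cfg) <- "dac_config"
  st <- obj$state
  K <- as.integer(st$K_max); D <- as.integer(st$D)
  Lambda <- if (is.array(st$Lambda)) {
    lapply(seq_len(K), function(k) matrix(st$Lambda[k, , ], D, D))
  } else {
    lapply(st$Lambda, function(m) matrix(unlist(m), D, D))
  }
  state <- structure(list(
    delta = st$delta, alpha = st$alpha, weights = st$weights,
    mu = matrix(unlist(st$mu), K, D), Lambda = Lambda,
    gamma1 = st$gamma1, gamma2 = st$gamma2, kappa = st$kappa, nu = st$nu,
    resp = NULL, hard_labels = integer(0), elbo_trace = numeric(0),
    hyper = st$hyper, K_max = K, D = D), class = "dpmm_state")
  prep <- list(processed = structure(
    list(values = NULL, hvg_indices = as.integer(obj$prep$hvg_indices),
         per_gene_mean = obj$prep$per_gene_mean,
         per_gene_sd = obj$prep$per_gene_sd),
    class = "processed_matrix"))
  structure(list(config = cfg, prep = prep,
                 encoder = mlp_from_list(obj$encoder),
                 decoder = mlp_from_list(obj$decoder),
                 state = state, trace = NULL, result = NULL),
            class = "celldpm_fit")
}
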