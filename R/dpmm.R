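# Dirichlet process mixture model over the latent space.
#
# Truncated stick-breaking representation: delta_k ~ Beta(1, alpha),
# pi_k = delta_k * prod_{j<k}(1 - delta_j); component means/precisions carry
# a conjugate Normal-Wishart prior NW(mu, Lambda | sigma, kappa0, nu0, zeta)
# with zeta the INVERSE Wishart scale (set from the empirical latent
# variance). Posterior fitting is coordinate-ascent variational inference
# with closed-form conjugate updates and a full evidence lower bound.

#' Stick-breaking weights from stick fractions
#'
#' `pi_k = delta_k * prod_{j<k} (1 - delta_j)`. Under truncation the weights
#' sum to `1 - prod_k (1 - delta_k) <= 1`; the remainder is the unbroken
#' tail mass.
#'
#' @param delta numeric vector of stick fractions, each in (0, 1).
#' @return numeric vector of mixture weights, same length.
#' @export
stick_to_weights <- function(delta) {
  delta <- as.numeric(delta)
  if (any(delta <= 0 | delta >= 1) || any(!is.finite(delta)))
    stop("stick fractions must lie strictly inside (0, 1)")
  delta * cumprod(c(1, 1 - delta[-length(delta)]))
}

#' Multivariate normal log-density, precision parameterization
#'
#' `0.5 * ln det(Lambda) - (D/2) ln(2 pi) - 0.5 (z - mu)' Lambda (z - mu)`.
#'
#' @param z,mu numeric D-vectors.
#' @param Lambda symmetric positive-definite D x D precision matrix.
#' @return scalar log-density.
#' @export
component_loglik <- function(z, mu, Lambda) {
  z <- as.numeric(z); mu <- as.numeric(mu)
  d <- length(z)
  stopifnot(length(mu) == d, all(dim(Lambda) == d))
  if (max(abs(Lambda - t(Lambda))) > 1e-8)
    stop("precision matrix must be symmetric")
  R <- tryCatch(chol(Lambda), error = function(e)
    stop("precision matrix must be positive definite", call. = FALSE))
  logdet <- 2 * sum(log(diag(R)))
  quad <- sum((R %*% (z - mu))^2)
  0.5 * logdet - 0.5 * d * log(2 * pi) - 0.5 * quad
}

#' Normal-Wishart hyperparameters from a latent matrix
#'
#' The prior mean location `sigma` and the diagonal inverse Wishart scale
#' `zeta` are set empirically from the mean and per-dimension variance of
#' the latent representation; `kappa0 = 1`, `nu0 = D`. Re-derived each time
#' the mixture is refitted, since the latent space moves during training.
#'
#' @param Z numeric latent matrix, N x D.
#' @param kappa0 prior mean-precision scale.
#' @return list with `sigma`, `kappa0`, `nu0`, `zeta` (diagonal vector).
#' @export
dpmm_hyper <- function(Z, kappa0 = 1) {
  d <- ncol(Z)
  list(sigma = colMeans(Z), kappa0 = kappa0, nu0 = d,
       zeta = pmax(apply(Z, 2L, var), 1e-6))
}

# log multivariate gamma
lmvgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

# log Wishart normalizer B(W, nu) given log det W
log_wishart_b <- function(logdetW, nu, d) {
  -(nu / 2) * logdetW - (nu * d / 2) * log(2) - lmvgamma(nu / 2, d)
}

# one k-means++ seeding followed by Lloyd iterations to convergence
kmeanspp_once <- function(Z, k, seed) {
  set.seed(seed)
  n <- nrow(Z)
  centers <- matrix(0, k, ncol(Z))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- Z[idx, ]
  d2 <- rowSums(sweep(Z, 2L, centers[1L, ], "-")^2)
  if (k > 1L) for (j in 2L:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j, ] <- Z[idx, ]
    d2 <- pmin(d2, rowSums(sweep(Z, 2L, centers[j, ], "-")^2))
  }
  zz <- rowSums(Z^2)
  labels <- integer(n)
  for (it in seq_len(100L)) {
    dists <- outer(zz, rowSums(centers^2), "+") - 2 * tcrossprod(Z, centers)
    new_labels <- max.col(-dists, ties.method = "first")
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      sel <- labels == j
      if (any(sel)) centers[j, ] <- colMeans(Z[sel, , drop = FALSE])
    }
  }
  dists <- outer(zz, rowSums(centers^2), "+") - 2 * tcrossprod(Z, centers)
  list(labels = labels, wss = sum(dists[cbind(seq_len(n), labels)]))
}

# k-means++ with a few restarts (best within-cluster SS); returns hard labels
kmeanspp_labels <- function(Z, k, seed, n_restart = 4L) {
  k <- min(k, nrow(Z))
  best <- NULL
  for (r in seq_len(n_restart)) {
    cand <- kmeanspp_once(Z, k, seed + 1000L * (r - 1L))
    if (is.null(best) || cand$wss < best$wss) best <- cand
  }
  best$labels
}

# core coordinate-ascent loop: alternating conjugate M-step and E-step with
# the exact evidence lower bound tracked each iteration. `resp` is an
# N x K responsibility matrix (rows sum to 1); returns the refined
# responsibilities, the posterior blocks, and the ELBO trace.
vb_iterate <- function(Z, resp, alpha, hyper, max_iter, tol) {
  n <- nrow(Z); d <- ncol(Z); K <- ncol(resp)
  kappa0 <- hyper$kappa0; nu0 <- hyper$nu0
  sigma0 <- hyper$sigma; zeta <- hyper$zeta
  W0inv_diag <- zeta
  logdetW0 <- -sum(log(zeta))
  logB0 <- log_wishart_b(logdetW0, nu0, d)
  two_pi <- 2 * pi

  elbo_trace <- numeric(0)
  prev_elbo <- -Inf
  post <- NULL

  for (iter in seq_len(max_iter)) {
    ## ---- M-step: conjugate updates from current responsibilities
    Nk <- colSums(resp)
    xbar <- crossprod(resp, Z) / pmax(Nk, 1e-12)          # K x D
    gamma1 <- 1 + Nk
    # tail counts sum_{j>k} N_j via reverse cumsum: exact zeros for trailing
    # empty components, so the Beta ELBO terms below stay cancellation-free
    Tk <- c(rev(cumsum(rev(Nk)))[-1L], 0)
    gamma2 <- alpha + Tk
    kappa <- kappa0 + Nk
    nu <- nu0 + Nk
    m <- (kappa0 * matrix(sigma0, K, d, byrow = TRUE) + xbar * Nk) / kappa

    Lchol <- vector("list", K)     # lower Cholesky of W_k^{-1}
    Wdiag_tr <- numeric(K)         # tr(W0^{-1} W_k)
    q_m <- numeric(K)              # (m_k - sigma)' W_k (m_k - sigma)
    logdetW <- numeric(K)
    for (k in seq_len(K)) {
      rk <- resp[, k]
      Zs <- Z * sqrt(rk)
      Ck <- crossprod(Zs)                                  # sum r z z'
      dx <- xbar[k, ] - sigma0
      Winv <- diag(W0inv_diag, d) + (Ck - Nk[k] * tcrossprod(xbar[k, ])) +
        (kappa0 * Nk[k] / (kappa0 + Nk[k])) * tcrossprod(dx) +
        diag(1e-6, d)
      Winv <- (Winv + t(Winv)) / 2
      R <- chol(Winv)
      L <- t(R)
      Lchol[[k]] <- L
      logdetW[k] <- -2 * sum(log(diag(R)))
      Linv <- forwardsolve(L, diag(d))
      Wk <- crossprod(Linv)                                # W_k
      Wdiag_tr[k] <- sum(W0inv_diag * diag(Wk))
      dm <- m[k, ] - sigma0
      q_m[k] <- sum(forwardsolve(L, dm)^2)
    }

    ## ---- E-step: expected log weights + expected Gaussian log-densities
    dg12 <- digamma(gamma1 + gamma2)
    dg1 <- digamma(gamma1); dg2 <- digamma(gamma2)
    Elog1m <- dg2 - dg12
    Elogpi <- (dg1 - dg12) + c(0, cumsum(Elog1m))[seq_len(K)]
    Elogdet <- vapply(seq_len(K), function(k)
      sum(digamma((nu[k] + 1 - seq_len(d)) / 2)) + d * log(2) + logdetW[k],
      0)
    logrho <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Zc <- t(Z) - m[k, ]
      maha <- colSums(forwardsolve(Lchol[[k]], Zc)^2)
      logrho[, k] <- Elogpi[k] + 0.5 * Elogdet[k] - 0.5 * d * log(two_pi) -
        0.5 * (d / kappa[k] + nu[k] * maha)
    }
    mx <- apply(logrho, 1L, max)
    lse <- mx + log(rowSums(exp(logrho - mx)))
    resp <- exp(logrho - lse)

    ## ---- ELBO (coordinate-ascent lower bound, non-decreasing)
    # E[log p(delta)] - E[log q(delta)] combined analytically:
    # log(alpha) + (alpha - gamma2) Elog1m - (gamma1 - 1)(dg1 - dg12)
    # + lbeta(gamma1, gamma2), with alpha - gamma2 = -Tk; avoids the
    # cancellation of ~1/alpha digamma terms for empty components
    lpq_delta <- sum(log(alpha) - Tk * Elog1m -
                       (gamma1 - 1) * (dg1 - dg12) + lbeta(gamma1, gamma2))
    lp_mu_lambda <- sum(
      0.5 * (d * log(kappa0 / two_pi) + Elogdet - d * kappa0 / kappa -
               kappa0 * nu * q_m) +
        logB0 + (nu0 - d - 1) / 2 * Elogdet - 0.5 * nu * Wdiag_tr)
    logB_k <- vapply(seq_len(K), function(k)
      log_wishart_b(logdetW[k], nu[k], d), 0)
    wishart_entropy <- -logB_k - (nu - d - 1) / 2 * Elogdet + nu * d / 2
    lq_mu_lambda <- sum(0.5 * Elogdet + d / 2 * log(kappa / two_pi) -
                          d / 2 - wishart_entropy)
    elbo <- sum(lse) + lpq_delta + lp_mu_lambda - lq_mu_lambda
    elbo_trace <- c(elbo_trace, elbo)

    post <- list(gamma1 = gamma1, gamma2 = gamma2, kappa = kappa, nu = nu,
                 m = m, Lchol = Lchol, logdetW = logdetW)
    if (is.finite(prev_elbo) && (elbo - prev_elbo) < tol) break
    prev_elbo <- elbo
  }
  list(resp = resp, post = post, elbo_trace = elbo_trace,
       elbo = elbo_trace[length(elbo_trace)])
}

# ELBO-guided merge phase. Plain coordinate ascent cannot fuse two occupied
# components even when a single component explains their cells better, so
# after convergence we propose merging close pairs (responsibility columns
# summed), refine each proposal with a few VB iterations, and accept a merge
# whenever it reaches a higher ELBO than the equally-refined current state.
# Repeats until no proposal improves.
vb_merge_phase <- function(Z, fit, alpha, hyper, tol, K_out,
                           refine_iter = 5L, max_cand = 12L) {
  # drop never-winning components: with the combined Beta term and a
  # posterior-equals-prior cancellation, empty components contribute
  # essentially nothing to the ELBO, so the compacted model's bound is
  # comparable and every iteration gets cheaper as merges proceed
  hard <- max.col(fit$resp, ties.method = "first")
  occ <- sort(unique(hard))
  resp <- fit$resp[, occ, drop = FALSE]
  resp <- resp / rowSums(resp)
  fit <- vb_iterate(Z, resp, alpha, hyper, max_iter = refine_iter, tol = 0)
  repeat {
    K <- ncol(fit$resp)
    if (K < 2L) break
    dm <- as.matrix(dist(fit$post$m))
    pairs <- which(upper.tri(dm), arr.ind = TRUE)
    pairs <- pairs[order(dm[pairs]), , drop = FALSE]
    n_try <- min(nrow(pairs), max_cand)
    accepted <- FALSE
    for (p in seq_len(n_try)) {
      lo <- min(pairs[p, ]); hi <- max(pairs[p, ])
      r2 <- fit$resp
      r2[, lo] <- r2[, lo] + r2[, hi]
      r2 <- r2[, -hi, drop = FALSE]
      cand <- vb_iterate(Z, r2, alpha, hyper, max_iter = refine_iter, tol = 0)
      if (cand$elbo > fit$elbo + 1e-6) {
        fit <- cand
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  # settle to convergence, then pad back to the requested truncation level
  fit <- vb_iterate(Z, fit$resp, alpha, hyper, max_iter = 100L, tol = tol)
  if (ncol(fit$resp) < K_out) {
    pad <- matrix(0, nrow(fit$resp), K_out - ncol(fit$resp))
    fit <- vb_iterate(Z, cbind(fit$resp, pad), alpha, hyper,
                      max_iter = 2L, tol = 0)
  }
  fit
}

#' Fit the DPMM posterior on a latent matrix
#'
#' Truncated variational inference for the Dirichlet process Gaussian
#' mixture. The E-step computes responsibilities from expected log stick
#' weights and expected Gaussian log-densities under the Normal-Wishart
#' posteriors; the M-step applies the conjugate closed-form updates
#' (`gamma_k1 = 1 + sum_n r_nk`, `gamma_k2 = alpha + sum_n sum_{j>k} r_nj`,
#' and standard Normal-Wishart sufficient-statistic updates). Iterates until
#' the evidence lower bound improves by less than `tol` or `max_iter` is
#' reached; the tracked ELBO is non-decreasing.
#'
#' Coordinate ascent alone can leave redundant components occupied (it has
#' no move that fuses two components), so `merge_moves = TRUE` adds an
#' ELBO-guided merge phase after convergence: close component pairs are
#' tentatively merged, refined for a few iterations, and kept only when the
#' bound improves. This is what lets the occupied-component count adapt
#' downward once the latent space has condensed around its clusters.
#'
#' @param Z numeric latent matrix, N x D (N >= 2).
#' @param alpha Dirichlet process concentration (> 0); small values favour
#'   few clusters.
#' @param hyper optional [dpmm_hyper()] list; derived from `Z` when NULL.
#' @param K_max truncation level (>= 2).
#' @param max_iter maximum variational iterations.
#' @param tol absolute ELBO improvement threshold for convergence.
#' @param seed seed for the k-means++ initialization.
#' @param init_resp optional N x K_max responsibility matrix to warm-start
#'   from (rows must sum to 1); overrides the seeded initialization.
#' @param merge_moves logical; run the ELBO-guided merge phase (default
#'   TRUE).
#' @return A `dpmm_state` object: stick posteriors (`gamma1`, `gamma2`,
#'   point fractions `delta`), normalized point weights `weights`, component
#'   posterior means `mu` (K x D) and precisions `Lambda` (list of D x D),
#'   Normal-Wishart posterior blocks, `resp` (N x K), `hard_labels`,
#'   `elbo_trace`, and the hyperparameters used.
#' @export
fit_S <- function(Z, alpha = 1e-10, hyper = NULL, K_max = 50L,
                  max_iter = 500L, tol = 1e-6, seed = 0L,
                  init_resp = NULL, merge_moves = TRUE) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z))) stop("Z must be finite")
  n <- nrow(Z); d <- ncol(Z)
  if (n < 2L) stop("fitting requires at least 2 cells")
  if (K_max < 2L) stop("K_max must be >= 2")
  if (alpha <= 0) stop("alpha must be positive")
  if (is.null(hyper)) hyper <- dpmm_hyper(Z)
  K <- as.integer(K_max)

  if (is.null(init_resp)) {
    labels <- kmeanspp_labels(Z, K, seed)
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), labels)] <- 1
  } else {
    stopifnot(nrow(init_resp) == n, ncol(init_resp) == K)
    resp <- init_resp / rowSums(init_resp)
  }

  fit <- vb_iterate(Z, resp, alpha, hyper, max_iter = max_iter, tol = tol)
  elbo_trace <- fit$elbo_trace
  if (merge_moves) {
    fit <- vb_merge_phase(Z, fit, alpha, hyper, tol = tol, K_out = K)
  }
  assemble_state(fit, hyper, alpha, elbo_trace, K, d)
}

# build the user-facing state object from a vb_iterate result
assemble_state <- function(fit, hyper, alpha, elbo_trace, K, d) {
  post <- fit$post
  resp <- fit$resp
  delta <- post$gamma1 / (post$gamma1 + post$gamma2)
  w_raw <- stick_to_weights(pmin(pmax(delta, 1e-15), 1 - 1e-15))
  weights <- w_raw / sum(w_raw)
  Lambda <- vector("list", K)
  for (k in seq_len(K)) {
    Linv <- forwardsolve(post$Lchol[[k]], diag(d))
    Wk <- crossprod(Linv)
    Lambda[[k]] <- (Wk + t(Wk)) / 2 * post$nu[k]           # E[Lambda] = nu W
  }
  hard <- max.col(resp, ties.method = "first")

  structure(list(
    delta = delta, alpha = alpha, weights = weights,
    mu = post$m, Lambda = Lambda,
    gamma1 = post$gamma1, gamma2 = post$gamma2,
    kappa = post$kappa, nu = post$nu,
    resp = resp, hard_labels = hard,
    elbo_trace = elbo_trace, hyper = hyper, K_max = K, D = d
  ), class = "dpmm_state")
}

#' @export
print.dpmm_state <- function(x, ...) {
  cat(sprintf(
    "dpmm_state: %d cells, truncation %d, %d occupied cluster(s), alpha = %g\n",
    nrow(x$resp), x$K_max, effective_cluster_count(x), x$alpha))
  invisible(x)
}

# log of pi_hat_k * N(z | mu_k, Lambda_k^{-1}) for all components;
# z may be a vector or an N x D matrix. Returned as N x K matrix.
state_log_dens <- function(z, state) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != state$D)
    stop(sprintf("latent dimension mismatch: state has D = %d, input has %d",
                 state$D, ncol(z)))
  K <- state$K_max
  lw <- log(state$weights)
  out <- matrix(0, nrow(z), K)
  for (k in seq_len(K)) {
    R <- chol(state$Lambda[[k]])
    logdet <- 2 * sum(log(diag(R)))
    quad <- colSums((R %*% (t(z) - state$mu[k, ]))^2)
    out[, k] <- lw[k] + 0.5 * logdet - 0.5 * state$D * log(2 * pi) -
      0.5 * quad
  }
  out
}

#' Mixture-density loss of a latent point
#'
#' `-ln sum_k pi_hat_k N(z | mu_k, Lambda_k^{-1})` under the fitted state's
#' normalized point weights: the negative log mixture marginal that
#' back-propagates into the encoder during coupled training.
#'
#' @param z numeric D-vector or N x D matrix.
#' @param state a fitted `dpmm_state`.
#' @return scalar (or vector of length N) loss value(s).
#' @export
loss_z <- function(z, state) {
  if (all(state$weights == 0)) stop("all mixture weights are zero")
  ld <- state_log_dens(z, state)
  mx <- apply(ld, 1L, max)
  out <- -(mx + log(rowSums(exp(ld - mx))))
  if (length(out) == 1L) out[[1L]] else out
}

# gradient of loss_z with respect to z rows: sum_k r_k Lambda_k (z - mu_k)
loss_z_grad <- function(z, state) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  r <- responsibilities(z, state)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  g <- matrix(0, nrow(z), ncol(z))
  for (k in seq_len(state$K_max)) {
    zc <- sweep(z, 2L, state$mu[k, ], "-")
    g <- g + r[, k] * (zc %*% state$Lambda[[k]])
  }
  g
}

#' Posterior responsibilities of latent points
#'
#' `r_k` proportional to `pi_hat_k N(z | mu_k, Lambda_k^{-1})`, normalized in
#' log space so underflow never produces NaN.
#'
#' @param z numeric D-vector or N x D matrix.
#' @param state a fitted `dpmm_state`.
#' @return probability vector of length `K_max` (or an N x K matrix).
#' @export
responsibilities <- function(z, state) {
  ld <- state_log_dens(z, state)
  mx <- apply(ld, 1L, max)
  r <- exp(ld - (mx + log(rowSums(exp(ld - mx)))))
  if (nrow(r) == 1L) r[1L, ] else r
}

#' Number of occupied mixture components
#'
#' Counts the distinct values among the hard labels, i.e. the components
#' that win the argmax assignment of at least one cell.
#'
#' @param state a fitted `dpmm_state`.
#' @return positive integer.
#' @export
effective_cluster_count <- function(state) {
  length(unique(state$hard_labels))
}

#' Log prior density of a DPMM variable set
#'
#' Evaluates the generative prior at the state's point estimates:
#' `sum_k ln Beta(delta_k | 1, alpha) + sum_k ln NW(mu_k, Lambda_k | sigma,
#' kappa0, nu0, zeta) + sum_n ln Categorical(y_n | pi)`, with `pi` the
#' (truncated, unnormalized) stick-breaking weights.
#'
#' @param state a `dpmm_state`.
#' @param hyper a [dpmm_hyper()] list; defaults to the state's own.
#' @param alpha concentration; defaults to the state's own.
#' @return scalar log prior density.
#' @export
log_prior_S <- function(state, hyper = state$hyper, alpha = state$alpha) {
  d <- state$D
  delta <- pmin(pmax(state$delta, 1e-300), 1 - 1e-15)
  lp <- sum(dbeta(delta, 1, alpha, log = TRUE))
  W0inv <- diag(hyper$zeta, d)
  logdetW0 <- -sum(log(hyper$zeta))
  logB0 <- log_wishart_b(logdetW0, hyper$nu0, d)
  for (k in seq_len(state$K_max)) {
    Lam <- state$Lambda[[k]]
    lp <- lp + component_loglik(state$mu[k, ], hyper$sigma,
                                hyper$kappa0 * Lam)
    R <- chol(Lam)
    logdetLam <- 2 * sum(log(diag(R)))
    lp <- lp + (hyper$nu0 - d - 1) / 2 * logdetLam -
      0.5 * sum(diag(W0inv %*% Lam)) + logB0
  }
  piw <- stick_to_weights(delta)
  lp + sum(log(piw[state$hard_labels]))
}
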