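# Independent oracles used by the unit tests. These are written directly
# from the defining formulas (densities, pair counting, contingency tables)
# and never call the implementation paths they check.

# Brute-force variational EM for a 1-D Dirichlet-process Gaussian mixture
# with Normal-Gamma components, truncation K. Scalar arithmetic throughout,
# coded independently of fit_S (which works with matrices and Cholesky
# factors). Hyperparameters mirror the empirical-Bayes convention:
# location m0, mean-precision scale kappa0 = 1, gamma shape a0 = nu0/2,
# gamma rate b0 = zeta/2 (zeta = empirical variance), so that the implied
# Wishart scale matches W0^{-1} = zeta in 1-D.
oracle_vb_dpgmm_1d <- function(z, alpha, K, init_labels, n_iter = 400) {
  n <- length(z)
  m0 <- mean(z); kappa0 <- 1; nu0 <- 1
  zeta <- max(var(z), 1e-6)
  a0 <- nu0 / 2; b0 <- zeta / 2
  r <- matrix(0, n, K)
  r[cbind(seq_len(n), init_labels)] <- 1
  for (iter in seq_len(n_iter)) {
    Nk <- colSums(r)
    xbar <- ifelse(Nk > 0, colSums(r * z) / pmax(Nk, 1e-12), 0)
    g1 <- 1 + Nk
    g2 <- alpha + c(rev(cumsum(rev(Nk)))[-1], 0)
    kap <- kappa0 + Nk
    mk <- (kappa0 * m0 + Nk * xbar) / kap
    ak <- a0 + Nk / 2
    Sk <- sapply(seq_len(K), function(k) sum(r[, k] * (z - xbar[k])^2))
    bk <- b0 + 0.5 * (Sk + kappa0 * Nk / (kappa0 + Nk) * (xbar - m0)^2) +
      0.5e-6  # same diagonal flooring as the implementation (1e-6 / 2)
    # E-step with expected log weights and expected Gaussian densities
    Elogtau <- digamma(ak) - log(bk)
    Etau <- ak / bk
    Elog1m <- digamma(g2) - digamma(g1 + g2)
    Elogpi <- digamma(g1) - digamma(g1 + g2) + c(0, cumsum(Elog1m))[seq_len(K)]
    logr <- sapply(seq_len(K), function(k)
      Elogpi[k] + 0.5 * Elogtau[k] - 0.5 * log(2 * pi) -
        0.5 * (1 / kap[k] + Etau[k] * (z - mk[k])^2))
    mx <- apply(logr, 1, max)
    r <- exp(logr - mx)
    r <- r / rowSums(r)
  }
  r
}

# NMI from first principles on a contingency table (arithmetic-mean
# normalization), using plain loops
oracle_nmi <- function(a, b) {
  ta <- table(a); tb <- table(b); n <- length(a)
  mi <- 0
  for (x in names(ta)) for (y in names(tb)) {
    nxy <- sum(a == x & b == y)
    if (nxy > 0) mi <- mi + nxy / n * log(nxy * n / (ta[[x]] * tb[[y]]))
  }
  ha <- -sum(ta / n * log(ta / n)); hb <- -sum(tb / n * log(tb / n))
  if (ha + hb == 0) return(1)
  mi / ((ha + hb) / 2)
}

# ARI by brute-force enumeration of all point pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# mean silhouette by explicit distance table
oracle_silhouette <- function(Z, labels) {
  n <- nrow(Z)
  dmat <- as.matrix(dist(Z))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a_i <- if (sum(own) > 1) mean(dmat[i, own & seq_len(n) != i]) else 0
    b_i <- min(sapply(setdiff(unique(labels), labels[i]),
                      function(l) mean(dmat[i, labels == l])))
    s[i] <- if (sum(own) > 1) (b_i - a_i) / max(a_i, b_i) else 0
  }
  mean(s)
}
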