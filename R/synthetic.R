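# Synthetic count matrices and latent-space mixtures with known ground
# truth. The count generator emulates the statistical structure the model
# assumes: cluster-specific Poisson rates, a log-normal spread of per-cell
# sequencing depths, differential-expression blocks per cluster, and an
# optional rare cluster. It does NOT emulate any real dataset's gene-level
# statistics, batch effects, or over-dispersion beyond the optional
# gamma-mixed variant.

#' Build a simulation recipe
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param K number of clusters.
#' @param cluster_proportions probability vector of length K (sums to 1);
#'   defaults to uniform.
#' @param base_rate baseline Poisson rate per gene (default 1, a typical
#'   per-gene UMI rate at moderate depth).
#' @param de_fraction fraction of genes differentially expressed per
#'   cluster; may be a vector of length K.
#' @param fold_change multiplicative rate shift of DE genes (alternating up
#'   and down); may be a vector of length K.
#' @param library_size_spread log-normal sd of per-cell depth factors
#'   (default 0.3, a realistic droplet-protocol depth spread).
#' @param overdispersion gamma-mixing variance of rates (0 = pure Poisson,
#'   the model's own likelihood; > 0 gives an over-dispersed variant).
#' @param seed RNG seed.
#' @return A `simulation_recipe` list.
#' @export
simulation_recipe <- function(n_cells = 1000L, n_genes = 500L, K = 5L,
                              cluster_proportions = NULL, base_rate = 1,
                              de_fraction = 0.1, fold_change = 8,
                              library_size_spread = 0.3,
                              overdispersion = 0, seed = 1L) {
  if (is.null(cluster_proportions)) cluster_proportions <- rep(1 / K, K)
  if (K < 1L) stop("K must be >= 1")
  if (length(cluster_proportions) != K)
    stop("cluster_proportions must have length K")
  if (abs(sum(cluster_proportions) - 1) > 1e-12)
    stop("cluster_proportions must sum to 1")
  if (any(de_fraction < 0 | de_fraction > 1))
    stop("de_fraction must lie in [0, 1]")
  if (any(fold_change <= 0)) stop("fold_change must be positive")
  if (base_rate <= 0) stop("base_rate must be positive")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 K = as.integer(K), cluster_proportions = cluster_proportions,
                 base_rate = base_rate,
                 de_fraction = rep_len(de_fraction, K),
                 fold_change = rep_len(fold_change, K),
                 library_size_spread = library_size_spread,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "simulation_recipe")
}

#' Simulate a clustered UMI count matrix
#'
#' Cells are assigned to clusters by the recipe proportions; each cluster's
#' DE gene block (disjoint across clusters while genes last) has its rate
#' multiplied or divided by `fold_change`, alternating gene by gene;
#' per-cell depth factors are log-normal; counts are Poisson (optionally
#' gamma-mixed). Deterministic given the recipe seed.
#'
#' @param recipe a [simulation_recipe()].
#' @return list with `counts` (a [count_matrix()]), `labels` (integer vector
#'   of true cluster ids 1..K), `rates` (K x G matrix of generating rates),
#'   `depth` (per-cell depth factors).
#' @export
simulate_counts <- function(recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  set.seed(recipe$seed)
  n <- recipe$n_cells; g <- recipe$n_genes; K <- recipe$K
  labels <- sample.int(K, n, replace = TRUE, prob = recipe$cluster_proportions)
  rates <- matrix(recipe$base_rate, K, g)
  offset <- 0L
  for (k in seq_len(K)) {
    n_de <- round(recipe$de_fraction[k] * g)
    if (n_de > 0) {
      idx <- (offset + seq_len(n_de) - 1L) %% g + 1L
      offset <- offset + n_de
      mult <- ifelse(seq_len(n_de) %% 2L == 1L,
                     recipe$fold_change[k], 1 / recipe$fold_change[k])
      rates[k, idx] <- rates[k, idx] * mult
    }
  }
  depth <- exp(rnorm(n, mean = 0, sd = recipe$library_size_spread))
  lam <- rates[labels, , drop = FALSE] * depth
  if (recipe$overdispersion > 0) {
    shape <- 1 / recipe$overdispersion
    lam <- lam * matrix(rgamma(n * g, shape = shape, rate = shape), n, g)
  }
  m <- matrix(rpois(n * g, lam), n, g)
  list(counts = count_matrix(m), labels = labels, rates = rates,
       depth = depth)
}

#' Recipe preset with a rare cluster
#'
#' K clusters with one held at 2% of cells whose signature is a 5-fold rate
#' shift on 30 genes; the remaining clusters follow the default recipe.
#'
#' @inheritParams simulation_recipe
#' @return A `simulation_recipe`.
#' @export
recipe_rare_cluster <- function(n_cells = 2000L, n_genes = 500L, K = 5L,
                                seed = 1L) {
  props <- c(rep((1 - 0.02) / (K - 1), K - 1), 0.02)
  simulation_recipe(
    n_cells = n_cells, n_genes = n_genes, K = K,
    cluster_proportions = props,
    de_fraction = c(rep(0.1, K - 1), 30 / n_genes),
    fold_change = c(rep(8, K - 1), 5),
    seed = seed)
}

#' Simulate counts where two clusters differ only nonlinearly
#'
#' Clusters 1..K-2 follow the standard DE-block recipe. The last two
#' clusters share identical per-gene marginal rates: each of their cells
#' carries a latent factor `s ~ N(0, 1)` that moves two gene blocks P and Q
#' multiplicatively (`exp(0.8 s)`); in cluster K-1 the blocks move together
#' (positive correlation) and in cluster K they move oppositely. No linear
#' functional of the genes separates the pair - only the sign of the P-Q
#' covariation does - which is the regime where coupling the encoder to the
#' clustering prior should pay off against reduce-then-cluster.
#'
#' @param n_cells,n_genes,K,seed as in [simulation_recipe()].
#' @param block_size genes per correlated block.
#' @param factor_scale multiplicative scale of the latent factor.
#' @return list with `counts`, `labels` as in [simulate_counts()].
#' @export
simulate_counts_nonlinear <- function(n_cells = 1200L, n_genes = 300L,
                                      K = 6L, block_size = 40L,
                                      factor_scale = 0.8, seed = 1L) {
  stopifnot(K >= 3L)
  set.seed(seed)
  n <- n_cells; g <- n_genes
  labels <- sample.int(K, n, replace = TRUE)
  rates <- matrix(1, K, g)
  offset <- 0L
  for (k in seq_len(K - 2L)) {
    n_de <- round(0.1 * g)
    idx <- (offset + seq_len(n_de) - 1L) %% g + 1L
    offset <- offset + n_de
    mult <- ifelse(seq_len(n_de) %% 2L == 1L, 8, 1 / 8)
    rates[k, idx] <- rates[k, idx] * mult
  }
  lam <- rates[labels, , drop = FALSE]
  # correlated blocks for the nonlinear pair, placed on genes untouched by
  # the linear DE blocks when possible
  pq <- max(offset %% g, 0L)
  blockP <- (pq + seq_len(block_size) - 1L) %% g + 1L
  blockQ <- (pq + block_size + seq_len(block_size) - 1L) %% g + 1L
  s <- rnorm(n)
  pairA <- labels == K - 1L   # blocks move together
  pairB <- labels == K        # blocks move oppositely
  fac <- exp(factor_scale * s)
  lam[pairA, blockP] <- lam[pairA, blockP] * fac[pairA]
  lam[pairA, blockQ] <- lam[pairA, blockQ] * fac[pairA]
  lam[pairB, blockP] <- lam[pairB, blockP] * fac[pairB]
  lam[pairB, blockQ] <- lam[pairB, blockQ] / fac[pairB]
  depth <- exp(rnorm(n, sd = 0.3))
  lam <- lam * depth
  m <- matrix(rpois(n * g, lam), n, g)
  list(counts = count_matrix(m), labels = labels)
}

#' Simulate a Gaussian latent mixture with known labels
#'
#' Component means are placed at mutual Euclidean distance
#' `mean_separation` (scaled orthogonal placement when `K <= D`, otherwise
#' random directions rescaled to the requested minimum distance), unit
#' covariance, cells drawn per `weights`. Deterministic given the seed.
#'
#' @param N number of points.
#' @param D latent dimension.
#' @param K number of components.
#' @param mean_separation pairwise distance between component means.
#' @param weights mixture weights (default uniform).
#' @param seed RNG seed.
#' @return list with `Z` (N x D matrix), `labels`, `means` (K x D).
#' @export
simulate_latent_mixture <- function(N, D, K, mean_separation = 10,
                                    weights = NULL, seed = 1L) {
  stopifnot(N >= 1, D >= 1, K >= 1, mean_separation >= 0)
  if (is.null(weights)) weights <- rep(1 / K, K)
  stopifnot(length(weights) == K, abs(sum(weights) - 1) < 1e-9)
  set.seed(seed)
  if (K == 1L) {
    means <- matrix(0, 1L, D)
  } else if (K <= D) {
    # orthogonal unit vectors scaled so pairwise distances equal the target
    means <- diag(mean_separation / sqrt(2), K, D)
  } else if (D >= 2L) {
    # equally spaced on a circle in the first two dimensions: minimum
    # (adjacent) distance equals the target, total spread stays bounded
    r <- mean_separation / (2 * sin(pi / K))
    th <- 2 * pi * (seq_len(K) - 1L) / K
    means <- matrix(0, K, D)
    means[, 1L] <- r * cos(th); means[, 2L] <- r * sin(th)
  } else {
    means <- matrix(mean_separation * (seq_len(K) - (K + 1) / 2), K, 1L)
  }
  labels <- sample.int(K, N, replace = TRUE, prob = weights)
  Z <- means[labels, , drop = FALSE] + matrix(rnorm(N * D), N, D)
  list(Z = Z, labels = labels, means = means)
}
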