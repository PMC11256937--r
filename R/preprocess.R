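#' Library-size normalize and log-transform counts
#'
#' Each cell's counts are divided by its total count, multiplied by
#' `scale_factor` and passed through `log1p`, i.e. entry (n, g) becomes
#' `ln(1 + count_ng / cellsum_n * scale_factor)`. Cells with zero total
#' count map to all-zero rows (with a warning) so matrix shapes stay stable
#' for downstream batching.
#'
#' @param counts a [count_matrix()].
#' @param scale_factor positive scalar, default 1e4.
#' @return dense numeric matrix, cells x genes.
#' @export
normalize_log <- function(counts, scale_factor = 1e4) {
  stopifnot(inherits(counts, "count_matrix"), scale_factor > 0)
  m <- dense_counts(counts)
  cs <- rowSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warning(sprintf("%d cell(s) with zero total count mapped to all-zero rows",
                    sum(zero)))
    cs[zero] <- 1 # divisor placeholder; rows are all zero anyway
  }
  log1p(m / cs * scale_factor)
}

#' Select highly variable genes by variance-stabilized ranking
#'
#' Ranks genes by the variance of clipped standardized counts: a loess curve
#' of log10(variance) on log10(mean) predicts each gene's expected standard
#' deviation, raw counts are standardized by it, clipped at `sqrt(N)`, and
#' genes are ranked by the variance of the result. Zero-variance genes rank
#' strictly below any gene with positive standardized variance.
#'
#' @param counts a [count_matrix()].
#' @param n_hvg number of genes to keep (default 4000; capped at G).
#' @param loess_span span of the mean-variance trend fit.
#' @return integer vector of `min(n_hvg, G)` gene column indices (1-based),
#'   ordered from most to least variable.
#' @export
select_hvgs <- function(counts, n_hvg = 4000, loess_span = 0.3) {
  stopifnot(inherits(counts, "count_matrix"), n_hvg >= 1)
  m <- dense_counts(counts)
  n <- nrow(m); g <- ncol(m)
  mu <- colMeans(m)
  v <- apply(m, 2L, var)
  if (all(v == 0)) stop("all genes have zero variance: no variable genes to select")
  pos <- v > 0
  std_var <- numeric(g) # zero for constant genes
  sd_pred <- sqrt(v)
  if (sum(pos) >= 10) {
    fit <- try(suppressWarnings(
      loess(log10(v[pos]) ~ log10(mu[pos]), span = loess_span, degree = 2)),
      silent = TRUE)
    if (!inherits(fit, "try-error"))
      sd_pred[pos] <- sqrt(10^fitted(fit))
  }
  clip <- sqrt(n)
  for (j in which(pos)) {
    zj <- (m[, j] - mu[j]) / sd_pred[j]
    zj <- pmin(zj, clip)
    # variance about the pre-clip mean, as in the variance-stabilizing recipe
    std_var[j] <- sum((zj - mean(zj))^2) / (n - 1)
  }
  # deterministic ranking: ties broken by lower gene index
  k <- min(n_hvg, g)
  head(order(-std_var, seq_len(g)), k)
}

#' Scale selected genes to zero mean and unit variance
#'
#' Per-gene z-score (sample sd, denominator N-1) over cells on the HVG
#' submatrix of a normalized matrix, with values clipped from above at
#' `clip_max`. Constant genes map to all-zero columns.
#'
#' @param normalized dense numeric matrix from [normalize_log()].
#' @param hvg_indices integer gene indices from [select_hvgs()].
#' @param clip_max upper clip for scaled values (default 10).
#' @return A `processed_matrix`: list with `values` (N x G'), `hvg_indices`,
#'   `per_gene_mean`, `per_gene_sd`.
#' @export
scale_genes <- function(normalized, hvg_indices, clip_max = 10) {
  stopifnot(is.matrix(normalized))
  g <- ncol(normalized)
  if (any(hvg_indices < 1 | hvg_indices > g) || anyDuplicated(hvg_indices))
    stop("hvg_indices must be unique indices within [1, G]")
  sub <- normalized[, hvg_indices, drop = FALSE]
  mu <- colMeans(sub)
  s <- apply(sub, 2L, sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  vals <- sweep(sweep(sub, 2L, mu, "-"), 2L, s, "/")
  vals[, const] <- 0
  vals <- pmin(vals, clip_max)
  structure(list(values = vals, hvg_indices = as.integer(hvg_indices),
                 per_gene_mean = mu, per_gene_sd = s),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("processed_matrix: %d cells x %d selected genes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Full preprocessing recipe
#'
#' Convenience wrapper: [select_hvgs()] on the raw counts, then
#' [normalize_log()] and [scale_genes()] restricted to those genes. Also
#' returns the raw counts on the HVG columns, which are the target of the
#' Poisson reconstruction loss (the encoder consumes the scaled values; the
#' likelihood needs integer support).
#'
#' @param counts a [count_matrix()].
#' @inheritParams normalize_log
#' @inheritParams select_hvgs
#' @inheritParams scale_genes
#' @return list with `processed` (a `processed_matrix`), `raw_hvg`
#'   (dense integer matrix N x G'), `cell_ids`, `gene_ids` (selected).
#' @export
preprocess_counts <- function(counts, n_hvg = 4000, scale_factor = 1e4,
                              clip_max = 10) {
  hvg <- select_hvgs(counts, n_hvg = n_hvg)
  norm <- normalize_log(counts, scale_factor = scale_factor)
  proc <- scale_genes(norm, hvg, clip_max = clip_max)
  raw <- dense_counts(counts)[, hvg, drop = FALSE]
  list(processed = proc, raw_hvg = raw, cell_ids = counts$cell_ids,
       gene_ids = counts$gene_ids[hvg])
}
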