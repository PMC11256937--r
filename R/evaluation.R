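# Clustering evaluation: normalized mutual information, adjusted Rand
# index, silhouette coefficient rescaled to [0, 1], and the deviation ratio
# between predicted and true cluster counts.

check_labels <- function(truth, pred) {
  truth <- as.vector(truth); pred <- as.vector(pred)
  if (length(truth) != length(pred))
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(truth), length(pred)))
  if (length(truth) < 2L) stop("metrics require at least 2 observations")
  if (anyNA(truth) || anyNA(pred)) stop("labels must not contain NA")
  list(truth = truth, pred = pred)
}

entropy_from_counts <- function(cnt) {
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized by the
#' arithmetic mean of their entropies: 1 for identical partitions, 0 for
#' independent ones. Invariant to label renaming and symmetric in its
#' arguments.
#'
#' @param truth,pred label vectors of equal length (integers, factors or
#'   strings).
#' @return real in `[0, 1]`.
#' @export
nmi <- function(truth, pred) {
  l <- check_labels(truth, pred)
  tab <- table(l$truth, l$pred)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * (log(pij[nz]) -
                         log(outer(pi_, pj_))[nz]))
  h1 <- entropy_from_counts(rowSums(tab))
  h2 <- entropy_from_counts(colSums(tab))
  denom <- (h1 + h2) / 2
  if (denom == 0) return(1)       # both partitions trivial, hence identical
  val <- mi / denom
  max(0, min(1, val))
}

#' Adjusted Rand index
#'
#' Pair-counting Rand index adjusted for chance with the hypergeometric
#' expectation. Identical partitions score 1; random agreement scores about
#' 0. The formula can go slightly negative for worse-than-chance
#' agreement; the true value is returned.
#'
#' @inheritParams nmi
#' @return real `<= 1`.
#' @export
ari <- function(truth, pred) {
  l <- check_labels(truth, pred)
  tab <- table(l$truth, l$pred)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- sum_i * sum_j / total
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Mean silhouette coefficient scaled to [0, 1]
#'
#' Per-cell silhouette `s_n = (b_n - a_n) / max(a_n, b_n)` with Euclidean
#' distances on the latent representation, averaged over cells, then mapped
#' by `(s + 1) / 2` so it can be averaged with NMI and ARI.
#'
#' @param Z numeric latent matrix, N x D.
#' @param pred predicted label vector of length N with at least 2 distinct
#'   values.
#' @return real in `[0, 1]`.
#' @export
silhouette_scaled <- function(Z, pred) {
  Z <- as.matrix(Z)
  pred <- as.vector(pred)
  stopifnot(nrow(Z) == length(pred))
  if (length(unique(pred)) < 2L)
    stop("silhouette is undefined for a single predicted cluster")
  sil <- cluster::silhouette(as.integer(factor(pred)), dist(Z))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' Deviation ratio between predicted and true cluster counts
#'
#' `(k_pred - k_true) / k_true`; negative when too few clusters are
#' predicted, positive when too many, 0 when the count is exact.
#'
#' @param k_pred,k_true positive integers.
#' @return real.
#' @export
deviation_ratio <- function(k_pred, k_true) {
  if (k_true < 1) stop("k_true must be >= 1")
  (k_pred - k_true) / k_true
}

#' Full metric report for a clustering
#'
#' Computes NMI, ARI, the scaled silhouette (NA when no latent matrix is
#' given or only one cluster is predicted), the deviation ratio, and the
#' arithmetic mean of the three similarity scores.
#'
#' @param truth,pred label vectors.
#' @param latent optional N x D latent matrix for the silhouette.
#' @return list of class `metric_report` with fields `nmi`, `ari`,
#'   `sc_scaled`, `deviation_ratio`, `k_true`, `k_pred`, `mean_score`.
#' @export
metric_report <- function(truth, pred, latent = NULL) {
  l <- check_labels(truth, pred)
  k_true <- length(unique(l$truth))
  k_pred <- length(unique(l$pred))
  sc <- NA_real_
  if (!is.null(latent) && k_pred >= 2L)
    sc <- silhouette_scaled(latent, l$pred)
  v_nmi <- nmi(l$truth, l$pred)
  v_ari <- ari(l$truth, l$pred)
  structure(list(
    nmi = v_nmi, ari = v_ari, sc_scaled = sc,
    deviation_ratio = deviation_ratio(k_pred, k_true),
    k_true = k_true, k_pred = k_pred,
    mean_score = mean(c(v_nmi, v_ari, sc))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "NMI %.4f | ARI %.4f | SC(scaled) %s | DR %+.3f (k_pred %d, k_true %d)\n",
    x$nmi, x$ari,
    if (is.na(x$sc_scaled)) "NA" else sprintf("%.4f", x$sc_scaled),
    x$deviation_ratio, x$k_pred, x$k_true))
  invisible(x)
}

#' Write labels to CSV
#'
#' @param labels vector of labels.
#' @param cell_ids cell identifiers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, cell_ids, path) {
  write.csv(data.frame(cell_id = cell_ids, label = labels), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read labels from CSV
#'
#' @param path CSV with columns `cell_id,label`.
#' @return data.frame with `cell_id` and `label`.
#' @export
read_labels <- function(path) {
  df <- read.csv(path)
  if (!all(c("cell_id", "label") %in% names(df)))
    stop("labels CSV must have columns cell_id,label")
  df
}
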