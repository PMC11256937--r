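#' Construct a cells x genes count matrix
#'
#' The canonical container for raw UMI counts: nonnegative integer entries,
#' cells as rows, genes as columns, with unique cell and gene identifiers.
#' Sparse (`Matrix::dgCMatrix`) and dense base matrices are both accepted and
#' kept as-is; no densification happens here.
#'
#' @param counts matrix or sparse Matrix of nonnegative integers,
#'   cells x genes.
#' @param cell_ids character vector of length `nrow(counts)`; defaults to
#'   existing rownames or `cell1..cellN`.
#' @param gene_ids character vector of length `ncol(counts)`; defaults to
#'   existing colnames or `gene1..geneG`.
#' @return An object of class `count_matrix` with fields `counts`,
#'   `cell_ids`, `gene_ids`.
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  if (is.null(dim(counts)) || length(dim(counts)) != 2L)
    stop("`counts` must be a 2-dimensional matrix")
  n <- nrow(counts); g <- ncol(counts)
  if (n < 1L || g < 1L) stop("count matrix must have at least 1 cell and 1 gene")
  if (is.null(cell_ids)) cell_ids <- rownames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(g))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) stop("cell_ids length != number of rows")
  if (length(gene_ids) != g) stop("gene_ids length != number of columns")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  validate_count_values(counts, cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "count_matrix")
}

# integer / nonnegativity check naming the first offending coordinate;
# works on dense and on dgCMatrix / dgTMatrix without densifying
validate_count_values <- function(counts, cell_ids, gene_ids) {
  if (inherits(counts, "sparseMatrix")) {
    tm <- methods::as(counts, "TsparseMatrix")
    x <- tm@x; i <- tm@i + 1L; j <- tm@j + 1L
  } else {
    x <- as.vector(counts)
    i <- rep(seq_len(nrow(counts)), times = ncol(counts))
    j <- rep(seq_len(ncol(counts)), each = nrow(counts))
  }
  bad <- which(!is.finite(x) | x < 0 | abs(x - round(x)) > 1e-8)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "counts must be nonnegative integers; first offending entry is %s at (cell '%s', gene '%s')",
      format(x[b]), cell_ids[i[b]], gene_ids[j[b]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%s storage)\n",
              nrow(x$counts), ncol(x$counts),
              if (inherits(x$counts, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Supports MatrixMarket triplets with `barcodes.tsv` / `features.tsv` (or
#' `genes.tsv`) sidecars in the same directory, and dense CSV/TSV with a
#' header row of gene ids and a first column of cell ids. Orientation is
#' declared explicitly, never guessed: `cells_as_rows = NULL` uses the
#' format's convention (MTX files follow the genes-as-rows convention of
#' droplet pipelines, so `FALSE`; CSV defaults to `TRUE`).
#'
#' The `h5` format named in the interface is not available in this build
#' (no HDF5 reader in the supported dependency set) and raises an error.
#'
#' @param path file path (for `mtx`, the `.mtx` file itself).
#' @param format one of `"mtx"`, `"csv"`, `"h5"`.
#' @param cells_as_rows logical or NULL; whether rows of the stored matrix
#'   are cells.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx", "csv", "h5"),
                        cells_as_rows = NULL) {
  format <- match.arg(format)
  if (format == "h5")
    stop("format 'h5' is not supported in this build: no HDF5 reader is ",
         "available; export the container to MTX or CSV instead")
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (format == "mtx") {
    if (is.null(cells_as_rows)) cells_as_rows <- FALSE
    m <- Matrix::readMM(path)
    dirn <- dirname(path)
    bc <- file.path(dirn, "barcodes.tsv")
    ft <- file.path(dirn, "features.tsv")
    if (!file.exists(ft)) ft <- file.path(dirn, "genes.tsv")
    if (!file.exists(bc) || !file.exists(ft))
      stop("mtx sidecar files barcodes.tsv and features.tsv/genes.tsv not found next to ", path)
    barcodes <- readLines(bc)
    features <- vapply(strsplit(readLines(ft), "\t", fixed = TRUE), `[[`, "", 1L)
    if (!cells_as_rows) m <- Matrix::t(m)
    count_matrix(m, cell_ids = barcodes, gene_ids = features)
  } else {
    if (is.null(cells_as_rows)) cells_as_rows <- TRUE
    df <- read.csv(path, check.names = FALSE, row.names = 1L)
    m <- as.matrix(df)
    if (!cells_as_rows) m <- t(m)
    count_matrix(m)
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()] for the `mtx` and `csv` formats; round-trips
#' are bit-exact for integer matrices.
#'
#' @param x a [count_matrix()].
#' @param path output path (for `mtx`, the `.mtx` file; sidecars are written
#'   next to it).
#' @param format `"mtx"` or `"csv"`.
#' @param cells_as_rows orientation to write; NULL uses the format default
#'   (see [read_counts()]).
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("mtx", "csv"),
                         cells_as_rows = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    if (is.null(cells_as_rows)) cells_as_rows <- FALSE
    m <- if (inherits(x$counts, "sparseMatrix"))
      methods::as(x$counts, "CsparseMatrix")
    else Matrix::Matrix(as.matrix(x$counts), sparse = TRUE)
    if (!cells_as_rows) m <- Matrix::t(m)
    Matrix::writeMM(m, path)
    dirn <- dirname(path)
    writeLines(x$cell_ids, file.path(dirn, "barcodes.tsv"))
    writeLines(x$gene_ids, file.path(dirn, "features.tsv"))
  } else {
    if (is.null(cells_as_rows)) cells_as_rows <- TRUE
    m <- as.matrix(x$counts)
    dimnames(m) <- list(x$cell_ids, x$gene_ids)
    if (!cells_as_rows) m <- t(m)
    write.csv(m, path)
  }
  invisible(path)
}

# dense base-matrix view of the counts (used by the model internals)
dense_counts <- function(x) {
  m <- as.matrix(x$counts)
  dimnames(m) <- list(x$cell_ids, x$gene_ids)
  m
}
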