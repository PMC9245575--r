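#' Construct a gene-by-barcode count matrix
#'
#' The central container of the package is a sparse integer matrix
#' (`Matrix::dgCMatrix`) with genes as rows and cell barcodes as columns,
#' carrying its identifiers as `dimnames`. This constructor validates the
#' invariants every downstream step relies on: unique gene and barcode ids,
#' non-negative integer-valued entries, and dimensions consistent with the
#' id vectors.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   genes in rows, barcodes in columns.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param barcode_ids Character vector of unique barcode identifiers;
#'   defaults to `colnames(counts)`.
#' @return A validated `dgCMatrix` with `dimnames = list(gene_ids, barcode_ids)`.
#' @examples
#' m <- count_matrix(matrix(c(3, 0, 0, 1), 2, 2),
#'                   gene_ids = c("g1", "g2"), barcode_ids = c("b1", "b2"))
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcode_ids = colnames(counts)) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(barcode_ids)) {
    stop("count_matrix: gene_ids and barcode_ids are required ",
         "(supply them or set dimnames on 'counts')")
  }
  dimnames(m) <- list(as.character(gene_ids), as.character(barcode_ids))
  validate_count_matrix(m)
}

#' Validate count-matrix invariants
#'
#' @param m A matrix-like object with gene/barcode dimnames.
#' @param what Label used in error messages (e.g. a file name).
#' @return The validated matrix, invisibly coercible downstream.
#' @export
validate_count_matrix <- function(m, what = "count matrix") {
  g <- rownames(m)
  b <- colnames(m)
  if (is.null(g) || is.null(b)) {
    stop(what, ": gene and barcode ids must be set as dimnames")
  }
  if (anyDuplicated(g)) {
    stop(what, ": duplicate gene ids (first: ",
         g[duplicated(g)][1], ")")
  }
  if (anyDuplicated(b)) {
    stop(what, ": duplicate barcode ids (first: ",
         b[duplicated(b)][1], ")")
  }
  if (length(g) != nrow(m) || length(b) != ncol(m)) {
    stop(what, ": id vectors do not match matrix dimensions")
  }
  x <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x)) {
    if (any(!is.finite(x))) stop(what, ": non-finite entries")
    if (any(x < 0)) stop(what, ": negative entries")
    if (any(x != floor(x))) stop(what, ": non-integer entries")
  }
  m
}

#' Read a count matrix from an MTX triplet
#'
#' Reads the conventional Matrix Market triplet layout: `matrix.mtx`
#' (coordinate integer), `genes.tsv` (one gene id per line, first column) and
#' `barcodes.tsv` (one barcode per line). Genes are rows, barcodes columns,
#' entries 1-based in the MTX file.
#'
#' @param dir Directory containing the three files, or `NULL` to pass paths.
#' @param mtx,genes,barcodes Explicit file paths (override `dir`).
#' @return A validated sparse count matrix.
#' @export
read_count_matrix <- function(dir = NULL, mtx = NULL, genes = NULL,
                              barcodes = NULL) {
  if (!is.null(dir)) {
    mtx <- mtx %||% file.path(dir, "matrix.mtx")
    genes <- genes %||% file.path(dir, "genes.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
  }
  for (f in c(mtx, genes, barcodes)) {
    if (!file.exists(f)) stop("read_count_matrix: file not found: ", f)
  }
  m <- Matrix::readMM(mtx)
  # writeMM may store a structurally symmetric matrix in symmetric format;
  # expand to general storage before attaching ids
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  gid <- utils::read.table(genes, sep = "\t", header = FALSE,
                           colClasses = "character")[[1]]
  bid <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                           colClasses = "character")[[1]]
  if (nrow(m) != length(gid)) {
    stop("read_count_matrix: ", mtx, " declares ", nrow(m), " genes but ",
         genes, " has ", length(gid), " rows")
  }
  if (ncol(m) != length(bid)) {
    stop("read_count_matrix: ", mtx, " declares ", ncol(m), " barcodes but ",
         barcodes, " has ", length(bid), " rows")
  }
  dimnames(m) <- list(gid, bid)
  validate_count_matrix(m, what = mtx)
}

#' Write a count matrix as an MTX triplet
#'
#' Inverse of [read_count_matrix()]; `write` then `read` is the identity on
#' entries and identifiers.
#'
#' @param m Count matrix (genes x barcodes).
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  m <- validate_count_matrix(m)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
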