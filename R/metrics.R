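#' Filter a count matrix by gene prevalence and per-cell gene detection
#'
#' Two fixed stages, genes first: drop genes detected (count > 0) in fewer
#' than `min_cells` cells, then drop cells with fewer than `min_genes`
#' detected genes (the `min.cells = 5`, `min.genes = 500` object-creation
#' filter).
#'
#' @param matrix Count matrix (genes x cells).
#' @param min_cells Minimum number of cells a gene must be detected in.
#' @param min_genes Minimum number of detected genes a cell must have.
#' @return Filtered count matrix; errors with stage-wise survivor counts if
#'   nothing survives.
#' @export
filter_matrix <- function(matrix, min_cells = 5L, min_genes = 500L) {
  stopifnot(min_cells >= 0, min_genes >= 0)
  det_cells <- Matrix::rowSums(matrix > 0)
  m1 <- matrix[det_cells >= min_cells, , drop = FALSE]
  det_genes <- Matrix::colSums(m1 > 0)
  m2 <- m1[, det_genes >= min_genes, drop = FALSE]
  if (!nrow(m2) || !ncol(m2)) {
    stop("filter_matrix: empty result (", nrow(m1), "/", nrow(matrix),
         " genes survived min_cells=", min_cells, "; ", ncol(m2), "/",
         ncol(matrix), " cells survived min_genes=", min_genes, ")")
  }
  m2
}

#' Per-cell QC proportions
#'
#' Computes, per cell, the fraction of counts attributable to mitochondrial
#' genes, ribosomal-protein genes and rRNA genes, identified by configurable
#' regular-expression lists (no hardcoded species list).
#'
#' @param matrix Count matrix (genes x cells).
#' @param mito_patterns,ribo_patterns,rrna_patterns Character vectors of
#'   regular expressions matched against gene ids.
#' @return Data frame with one row per cell: `barcode`, `total_reads`,
#'   `genes_detected`, `mito_fraction`, `ribo_protein_fraction`,
#'   `rrna_fraction`, `zero_total` flag (fractions reported as 0).
#' @export
qc_proportions <- function(matrix,
                           mito_patterns = c("^mt-", "^MT-"),
                           ribo_patterns = c("^Rp[sl]", "^RP[SL]"),
                           rrna_patterns = c("^Rn[0-9]*s", "rRNA")) {
  stopifnot(length(mito_patterns) > 0, length(ribo_patterns) > 0,
            length(rrna_patterns) > 0)
  genes <- rownames(matrix)
  match_any <- function(patterns) {
    Reduce(`|`, lapply(patterns, grepl, x = genes))
  }
  totals <- Matrix::colSums(matrix)
  frac <- function(patterns) {
    hit <- match_any(patterns)
    s <- if (any(hit)) Matrix::colSums(matrix[hit, , drop = FALSE]) else
      numeric(ncol(matrix))
    ifelse(totals > 0, s / pmax(totals, 1), 0)
  }
  data.frame(
    barcode = colnames(matrix),
    total_reads = as.integer(totals),
    genes_detected = as.integer(Matrix::colSums(matrix > 0)),
    mito_fraction = frac(mito_patterns),
    ribo_protein_fraction = frac(ribo_patterns),
    rrna_fraction = frac(rrna_patterns),
    zero_total = totals == 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Remove high-mitochondrial cells
#'
#' Filters out cells whose mitochondrial fraction is strictly over the
#' threshold; a cell at exactly the threshold (e.g. 0.25) is retained.
#'
#' @param records QC table from [qc_proportions()].
#' @param matrix Count matrix (genes x cells) aligned with `records`.
#' @param threshold Maximum allowed mitochondrial fraction, in (0, 1].
#' @return Column-filtered count matrix.
#' @export
filter_cells_mito <- function(records, matrix, threshold = 0.25) {
  stopifnot(threshold > 0, threshold <= 1)
  frac <- records$mito_fraction[match(colnames(matrix), records$barcode)]
  if (anyNA(frac)) stop("filter_cells_mito: barcodes missing from QC records")
  matrix[, frac <= threshold, drop = FALSE]
}

#' Log counts-per-scale normalization
#'
#' `value = ln(1 + count / cell_total * scale)` with the scale factor of
#' 1,000,000 used throughout (per-million).
#'
#' @param matrix Count matrix (genes x cells) with positive cell totals.
#' @param scale Scale factor (default 1e6).
#' @return Dense-capable sparse real matrix of normalized values.
#' @export
normalize_log_cpm <- function(matrix, scale = 1e6) {
  totals <- Matrix::colSums(matrix)
  if (any(totals <= 0)) {
    stop("normalize_log_cpm: ", sum(totals <= 0),
         " cell(s) with zero total; filter before normalizing")
  }
  m <- methods::as(Matrix::Matrix(matrix, sparse = TRUE), "CsparseMatrix")
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log(1 + m@x / totals[j] * scale)
  m
}

#' Highly variable genes by the mean/variance-plot ("mvp") recipe
#'
#' Per gene, mean and dispersion `ln(variance / mean)` are computed on the
#' de-logged normalized values (`expm1` of [normalize_log_cpm()] output);
#' genes are binned into `n_bins` equal-width bins of mean and the
#' dispersion is z-scored within each bin. Selected genes have mean inside
#' `mean_cutoff` and z-scored dispersion inside `dispersion_cutoff`
#' (defaults `c(0.1, Inf)` and `c(0.5, Inf)`). Zero-variance genes are
#' excluded (flagged); a single-gene bin gets z-score 0.
#'
#' @param norm_matrix Normalized matrix from [normalize_log_cpm()].
#' @param mean_cutoff,dispersion_cutoff Two-sided inclusion intervals.
#' @param n_bins Number of equal-width mean bins (default 20).
#' @return Character vector of selected gene ids; attribute `stats` holds
#'   the per-gene table (mean, dispersion, bin, z-scored dispersion).
#' @export
find_variable_genes_mvp <- function(norm_matrix,
                                    mean_cutoff = c(0.1, Inf),
                                    dispersion_cutoff = c(0.5, Inf),
                                    n_bins = 20L) {
  x <- expm1(as.matrix(norm_matrix))
  mu <- rowMeans(x)
  v <- apply(x, 1L, stats::var)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), NA_real_)
  finite <- is.finite(disp)
  if (sum(finite) < n_bins) {
    stop("find_variable_genes_mvp: only ", sum(finite),
         " genes with finite dispersion; need >= n_bins = ", n_bins)
  }
  bin <- rep(NA_integer_, length(mu))
  bin[finite] <- as.integer(cut(mu[finite], breaks = n_bins))
  z <- rep(NA_real_, length(mu))
  for (b in unique(bin[finite])) {
    idx <- which(bin == b)
    d <- disp[idx]
    s <- stats::sd(d)
    z[idx] <- if (length(idx) < 2L || !is.finite(s) || s == 0) 0 else
      (d - mean(d)) / s
  }
  sel <- finite &
    mu >= mean_cutoff[1] & mu <= mean_cutoff[2] &
    z >= dispersion_cutoff[1] & z <= dispersion_cutoff[2]
  sel[is.na(sel)] <- FALSE
  out <- rownames(norm_matrix)[sel]
  attr(out, "stats") <- data.frame(
    gene = rownames(norm_matrix), mean = mu, dispersion = disp,
    bin = bin, z_dispersion = z, selected = sel,
    row.names = NULL, stringsAsFactors = FALSE)
  out
}
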