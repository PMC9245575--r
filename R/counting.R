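#' Tally non-UMI gene-by-barcode counts
#'
#' Counts the number of primary mapped reads per (gene, barcode) pair.
#' Deliberately no UMI deduplication: two reads sharing barcode, gene and
#' UMI contribute two counts, because the platform's 8-base bead UMIs are
#' too short for reliable molecule identification. Records with a missing
#' barcode or gene, or that are unmapped, are skipped and tallied in the
#' `skipped` attribute so that `sum(matrix) + skipped == nrow(records)`.
#'
#' @param records Data frame of tagged records (see [read_tagged_records()]).
#' @param valid_barcodes Optional character vector restricting the output
#'   to these barcodes (others are skipped and tallied).
#' @return A sparse count matrix (genes x barcodes) with a `skipped`
#'   attribute (named integer vector of skip reasons).
#' @export
count_genes <- function(records, valid_barcodes = NULL) {
  n <- nrow(records)
  usable <- records$is_mapped & !is.na(records$cell_barcode) &
    !is.na(records$gene_id)
  skipped <- c(unusable = sum(!usable))
  r <- records[usable, , drop = FALSE]
  if (!is.null(valid_barcodes)) {
    inset <- r$cell_barcode %in% valid_barcodes
    skipped <- c(skipped, off_list = sum(!inset))
    r <- r[inset, , drop = FALSE]
  }
  if (!nrow(r)) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0L, 0L),
                              dimnames = list(character(0), character(0)))
    attr(m, "skipped") <- skipped
    return(m)
  }
  genes <- sort(unique(r$gene_id))
  bcs <- sort(unique(r$cell_barcode))
  m <- Matrix::sparseMatrix(
    i = match(r$gene_id, genes),
    j = match(r$cell_barcode, bcs),
    x = rep(1, nrow(r)),
    dims = c(length(genes), length(bcs)),
    dimnames = list(genes, bcs)
  )
  m <- validate_count_matrix(m, "count_genes output")
  attr(m, "skipped") <- skipped
  m
}

#' Tally hashtag reads per barcode
#'
#' Hashtag (cell hashing) libraries carry a sample tag instead of a gene; the
#' tag id is expected in the `gene_id` field of the records. Reads whose tag
#' is not in the panel are excluded from the matrix and counted into an
#' `unmapped_tag` bucket reported as an attribute.
#'
#' @param records Data frame of tagged records.
#' @param tag_panel Character vector of expected tag ids (e.g. `A0301`...).
#' @return Sparse count matrix (tags x barcodes), rows in panel order, with
#'   attributes `unmapped_tag` (count of off-panel reads) and `skipped`.
#' @export
count_hashtags <- function(records, tag_panel) {
  if (!length(tag_panel)) stop("count_hashtags: empty tag panel")
  if (anyDuplicated(tag_panel)) stop("count_hashtags: duplicate tag ids")
  usable <- records$is_mapped & !is.na(records$cell_barcode) &
    !is.na(records$gene_id)
  r <- records[usable, , drop = FALSE]
  on_panel <- r$gene_id %in% tag_panel
  bcs <- sort(unique(r$cell_barcode[on_panel]))
  m <- Matrix::sparseMatrix(
    i = match(r$gene_id[on_panel], tag_panel),
    j = match(r$cell_barcode[on_panel], bcs),
    x = rep(1, sum(on_panel)),
    dims = c(length(tag_panel), length(bcs)),
    dimnames = list(tag_panel, bcs)
  )
  attr(m, "unmapped_tag") <- sum(!on_panel)
  attr(m, "skipped") <- c(unusable = sum(!usable))
  m
}

#' Demultiplex barcodes from hashtag counts
#'
#' Threshold classifier: per barcode, with top-two tag counts `c1 >= c2`, the
#' barcode is `negative` when `c1 < min_total`, a `singlet` of the top tag
#' when `c1 / max(c2, 1) >= singlet_ratio`, and a `doublet` otherwise. Ties
#' between tags are broken lexicographically by tag id for determinism.
#'
#' @param tag_counts Count matrix (tags x barcodes), e.g. from
#'   [count_hashtags()].
#' @param min_total Minimum top-tag count to call anything (default 10).
#' @param singlet_ratio Minimum top/second ratio for a singlet (default 3).
#' @return Data frame with one row per barcode: `barcode`, `label`
#'   (`singlet:<tag>`, `doublet`, `negative`), `top_tag`, `top_count`,
#'   `second_count`.
#' @export
demux_hashtags <- function(tag_counts, min_total = 10L, singlet_ratio = 3) {
  stopifnot(min_total >= 1, singlet_ratio > 1)
  tags <- rownames(tag_counts)
  ord <- order(tags)
  m <- as.matrix(tag_counts)[ord, , drop = FALSE]
  tags <- tags[ord]
  res <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    top <- which.max(v)  # first (lexicographically smallest) tag on ties
    c1 <- v[top]
    c2 <- if (length(v) > 1L) max(v[-top]) else 0
    label <- if (c1 < min_total) {
      "negative"
    } else if (c1 / max(c2, 1) >= singlet_ratio) {
      paste0("singlet:", tags[top])
    } else {
      "doublet"
    }
    data.frame(barcode = colnames(m)[j], label = label, top_tag = tags[top],
               top_count = unname(c1), second_count = unname(c2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
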