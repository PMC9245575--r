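#' Read per-read tagged records from SAM/BAM or TSV
#'
#' A tagged record is one sequencing read annotated with the cell barcode,
#' UMI and gene assignment attached during preprocessing. Records are
#' returned as a data frame with columns `read_id`, `cell_barcode`, `umi`,
#' `gene_id`, `is_primary`, `is_mapped` (one row per primary alignment;
#' secondary and supplementary alignments are skipped, unmapped reads are
#' kept with `is_mapped = FALSE`). The UMI is carried through but never used
#' for deduplication: counting is read-based because 8-base bead UMIs are too
#' short to avoid collisions.
#'
#' @param path A SAM/BAM file or a tab-separated file with a header naming
#'   the columns above.
#' @param format `"auto"` (by extension), `"bam"`, `"sam"` or `"tsv"`.
#' @param tags Named list giving the BAM tag names that hold the cell
#'   barcode, UMI and gene (defaults `CB`/`UB`/`GN`), overridable in config
#'   because the upstream annotation convention varies.
#' @param strict If `TRUE`, a mapped record missing its gene or barcode tag
#'   is an error; if `FALSE` (default) the field is `NA` and the record is
#'   reported in the `skipped` attribute.
#' @return A data frame of tagged records. Attribute `n_input` holds the
#'   number of alignment lines inspected (so yielded + skipped lines can be
#'   audited), attribute `n_secondary` the number skipped as secondary or
#'   supplementary.
#' @export
read_tagged_records <- function(path, format = c("auto", "bam", "sam", "tsv"),
                                tags = list(cb = "CB", umi = "UB", gene = "GN"),
                                strict = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     bam = "bam", sam = "sam", "tsv")
  }
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character", na.strings = c("NA", ""))
    need <- c("read_id", "cell_barcode", "umi", "gene_id",
              "is_primary", "is_mapped")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("read_tagged_records: ", path, " lacks columns: ",
           paste(miss, collapse = ", "))
    }
    df$is_primary <- as.logical(df$is_primary)
    df$is_mapped <- as.logical(df$is_mapped)
    out <- df[df$is_primary, need]
    attr(out, "n_input") <- nrow(df)
    attr(out, "n_secondary") <- sum(!df$is_primary)
    rownames(out) <- NULL
    return(check_strict(out, strict, path))
  }
  f <- if (format == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  what <- c("qname", "flag")
  p <- Rsamtools::ScanBamParam(what = what,
                               tag = unlist(tags, use.names = FALSE))
  res <- Rsamtools::scanBam(f, param = p)[[1]]
  flag <- res$flag
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  tagval <- function(nm) {
    v <- res$tag[[nm]]
    if (is.null(v)) rep(NA_character_, length(flag)) else as.character(v)
  }
  out <- data.frame(
    read_id = res$qname,
    cell_barcode = tagval(tags$cb),
    umi = tagval(tags$umi),
    gene_id = tagval(tags$gene),
    is_primary = !secondary,
    is_mapped = bitwAnd(flag, 4L) == 0L,
    stringsAsFactors = FALSE
  )
  keep <- out[!secondary, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_input") <- length(flag)
  attr(keep, "n_secondary") <- sum(secondary)
  check_strict(keep, strict, path)
}

check_strict <- function(records, strict, path) {
  if (strict) {
    bad <- records$is_mapped &
      (is.na(records$cell_barcode) | is.na(records$gene_id))
    if (any(bad)) {
      stop("read_tagged_records: ", sum(bad), " mapped record(s) in ", path,
           " missing barcode or gene tag (first read: ",
           records$read_id[bad][1], ")")
    }
  }
  records
}

#' Write tagged records as TSV
#'
#' Plain-text companion of [read_tagged_records()] used for fixtures and the
#' intermediate between barcode annotation and counting.
#'
#' @param records Data frame of tagged records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tagged_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
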