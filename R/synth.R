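#' Generate synthetic barcode reads with planted substitution errors
#'
#' Emulates the structure of bead cell-barcode reads: whitelist sections at
#' their configured offsets (gaps filled with the geometry's linker
#' sequences, or with `A` when no linker is configured), a random UMI, and a
#' polyT tail. A chosen proportion of reads carries 0, 1 or 2 substitution
#' errors planted at random positions inside barcode sections (never the
#' same position twice; for 2 errors both substitutions land in the same
#' section, so a sufficiently separated whitelist guarantees rejection).
#' The manifest records the ground truth per read.
#'
#' @param geometry A [barcode_geometry()].
#' @param n_reads Number of reads.
#' @param error_rates Numeric triple `(p0, p1, p2)`: proportions of reads
#'   with 0, 1 and 2 planted substitutions; must sum to 1.
#' @param seed Integer seed; regeneration is bitwise identical.
#' @param fastq Optional path; when given, reads are also written as FASTQ
#'   (constant quality).
#' @return List with `reads` (character vector) and `manifest` (data frame:
#'   `read_id`, `true_barcode`, `umi`, `n_errors`, `error_section`), plus
#'   `fastq` when written.
#' @export
generate_barcode_reads <- function(geometry, n_reads,
                                   error_rates = c(1, 0, 0), seed = 1L,
                                   fastq = NULL) {
  stopifnot(inherits(geometry, "barcode_geometry"),
            length(error_rates) == 3, all(error_rates >= 0))
  if (abs(sum(error_rates) - 1) > 1e-8) {
    stop("generate_barcode_reads: error_rates must sum to 1")
  }
  with_local_seed(seed, {
    secs <- geometry$sections
    read_len <- min_read_length(geometry) + 6L  # short polyT tail
    template <- rep("A", read_len)
    if (!is.null(geometry$linkers)) {
      for (lk in geometry$linkers) {
        idx <- lk$offset + seq_len(nchar(lk$seq))
        template[idx] <- strsplit(lk$seq, "", fixed = TRUE)[[1]]
      }
    }
    tail_start <- min_read_length(geometry) + 1L
    template[tail_start:read_len] <- "T"

    n_err <- sample(0:2, n_reads, replace = TRUE, prob = error_rates)
    picks <- lapply(secs, function(s) sample(s$whitelist, n_reads,
                                             replace = TRUE))
    umi_len <- if (is.null(geometry$umi)) 0L else geometry$umi$length
    umis <- if (umi_len) {
      vapply(seq_len(n_reads), function(i) {
        paste0(sample(c("A", "C", "G", "T"), umi_len, replace = TRUE),
               collapse = "")
      }, character(1))
    } else rep(NA_character_, n_reads)
    err_sec <- ifelse(n_err > 0, sample(length(secs), n_reads, replace = TRUE),
                      NA_integer_)
    bases <- c("A", "C", "G", "T")
    reads <- character(n_reads)
    true_bc <- character(n_reads)
    for (i in seq_len(n_reads)) {
      chars <- template
      for (j in seq_along(secs)) {
        s <- secs[[j]]
        sec_chars <- strsplit(picks[[j]][i], "", fixed = TRUE)[[1]]
        if (!is.na(err_sec[i]) && err_sec[i] == j && n_err[i] > 0) {
          pos <- sample(s$length, n_err[i])
          for (p in pos) {
            sec_chars[p] <- sample(setdiff(bases, sec_chars[p]), 1L)
          }
        }
        chars[s$offset + seq_len(s$length)] <- sec_chars
      }
      if (umi_len) {
        chars[geometry$umi$offset + seq_len(umi_len)] <-
          strsplit(umis[i], "", fixed = TRUE)[[1]]
      }
      reads[i] <- paste0(chars, collapse = "")
      true_bc[i] <- paste0(vapply(seq_along(secs),
                                  function(j) picks[[j]][i], character(1)),
                           collapse = "")
    }
    manifest <- data.frame(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      true_barcode = true_bc, umi = umis, n_errors = n_err,
      error_section = err_sec, stringsAsFactors = FALSE)
    out <- list(reads = reads, manifest = manifest,
                params = list(seed = seed, n_reads = n_reads,
                              error_rates = error_rates))
    if (!is.null(fastq)) {
      qual <- strrep("I", read_len)
      lines <- as.vector(rbind(paste0("@", manifest$read_id), reads,
                               "+", qual))
      writeLines(lines, fastq)
      out$fastq <- fastq
    }
    out
  })
}

#' Generate a two-regime barcode-rank curve
#'
#' Per-barcode totals are drawn from two log-normal regimes: cell-containing
#' barcodes around `cell_count_mean` and ambient barcodes around
#' `ambient_count_mean` (geometric means; log-sd `cell_sdlog` /
#' `ambient_sdlog`). Totals are spread over `n_genes` genes by multinomial
#' draws. The manifest labels the true cells, giving ground truth for the
#' knee-plot cell caller.
#'
#' @param n_cells,n_ambient Numbers of cell/ambient barcodes.
#' @param cell_count_mean,ambient_count_mean Geometric-mean totals; their
#'   ratio must be at least 20 for the two regimes to be separable.
#' @param cell_sdlog,ambient_sdlog Log-normal sd (natural log scale).
#' @param n_genes Number of genes the totals are spread over.
#' @param seed Integer seed.
#' @return List with `matrix` (count matrix) and `manifest` (data frame
#'   `barcode`, `is_cell`, `total`).
#' @export
generate_rank_curve <- function(n_cells, n_ambient,
                                cell_count_mean = 10000,
                                ambient_count_mean = 50,
                                cell_sdlog = 0.15, ambient_sdlog = 0.3,
                                n_genes = 50L, seed = 1L) {
  stopifnot(n_cells >= 1)
  if (n_ambient > 0 && cell_count_mean / ambient_count_mean < 20) {
    stop("generate_rank_curve: cell/ambient mean ratio must be >= 20")
  }
  with_local_seed(seed, {
    n <- n_cells + n_ambient
    totals <- c(
      pmax(1, round(stats::rlnorm(n_cells, log(cell_count_mean), cell_sdlog))),
      if (n_ambient > 0) {
        pmax(1, round(stats::rlnorm(n_ambient, log(ambient_count_mean),
                                    ambient_sdlog)))
      } else numeric(0)
    )
    barcodes <- sprintf("BC%06d", seq_len(n))
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    prob <- rep(1 / n_genes, n_genes)
    counts <- vapply(totals, function(tt) {
      stats::rmultinom(1L, size = tt, prob = prob)[, 1L]
    }, numeric(n_genes))
    m <- count_matrix(counts, gene_ids = gene_ids, barcode_ids = barcodes)
    manifest <- data.frame(barcode = barcodes,
                           is_cell = c(rep(TRUE, n_cells),
                                       rep(FALSE, n_ambient)),
                           total = totals, stringsAsFactors = FALSE)
    list(matrix = m, manifest = manifest,
         params = list(seed = seed, n_cells = n_cells, n_ambient = n_ambient,
                       cell_count_mean = cell_count_mean,
                       ambient_count_mean = ambient_count_mean))
  })
}

#' Generate a signal-plus-background matrix for DBEC validation
#'
#' Emulates the diffusion-background regime that DBEC corrects: signal genes
#' carry high counts `round(2^N(high_mean_log2, sd^2) - 1)` in a fraction of
#' cells and low background counts `round(2^N(low_mean_log2, sd^2) - 1)`
#' elsewhere; non-signal genes carry the low regime everywhere. Counts are
#' clipped at zero. The manifest labels every nonzero entry of every gene as
#' signal or background, giving entry-level ground truth.
#'
#' @param n_genes,n_cells Matrix dimensions (defaults 200 x 1000).
#' @param n_signal_genes Number of genes with a planted signal component
#'   (default 50).
#' @param signal_cell_fraction Fraction of cells carrying the signal in a
#'   signal gene (default 0.3), in (0, 1).
#' @param high_mean_log2,low_mean_log2 Means of the two log2-scale regimes
#'   (defaults 10 and 2; must differ by >= 4).
#' @param sd_log2 Common log2-scale sd (default 0.7).
#' @param seed Integer seed.
#' @return List with `matrix`, `manifest` (data frame `gene`, `barcode`,
#'   `count`, `label` in `signal`/`background` covering all nonzero
#'   entries) and `signal_genes`.
#' @export
generate_dbec_matrix <- function(n_genes = 200L, n_cells = 1000L,
                                 n_signal_genes = 50L,
                                 signal_cell_fraction = 0.3,
                                 high_mean_log2 = 10, low_mean_log2 = 2,
                                 sd_log2 = 0.7, seed = 1L) {
  if (signal_cell_fraction <= 0 || signal_cell_fraction >= 1) {
    stop("generate_dbec_matrix: signal_cell_fraction must be in (0,1)")
  }
  if (high_mean_log2 - low_mean_log2 < 4) {
    stop("generate_dbec_matrix: high and low log2 means must differ by >= 4")
  }
  with_local_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    barcodes <- sprintf("CELL%05d", seq_len(n_cells))
    signal_genes <- gene_ids[seq_len(n_signal_genes)]
    counts <- matrix(0, n_genes, n_cells,
                     dimnames = list(gene_ids, barcodes))
    labels <- matrix("background", n_genes, n_cells)
    n_sig_cells <- round(signal_cell_fraction * n_cells)
    for (g in seq_len(n_genes)) {
      lo <- pmax(0, round(2^stats::rnorm(n_cells, low_mean_log2, sd_log2) - 1))
      counts[g, ] <- lo
      if (g <= n_signal_genes) {
        sig_cells <- sample(n_cells, n_sig_cells)
        counts[g, sig_cells] <-
          pmax(0, round(2^stats::rnorm(n_sig_cells, high_mean_log2,
                                       sd_log2) - 1))
        labels[g, sig_cells] <- "signal"
      }
    }
    nz <- which(counts > 0, arr.ind = TRUE)
    manifest <- data.frame(
      gene = gene_ids[nz[, 1]], barcode = barcodes[nz[, 2]],
      count = counts[nz], label = labels[nz],
      stringsAsFactors = FALSE)
    list(matrix = count_matrix(counts), manifest = manifest,
         signal_genes = signal_genes,
         params = list(seed = seed, n_genes = n_genes, n_cells = n_cells,
                       n_signal_genes = n_signal_genes,
                       signal_cell_fraction = signal_cell_fraction,
                       high_mean_log2 = high_mean_log2,
                       low_mean_log2 = low_mean_log2, sd_log2 = sd_log2))
  })
}

#' Generate a matched platform pair with gene-specific extra dropout
#'
#' Platform A counts are drawn per gene as Bernoulli(detection) x
#' (1 + Poisson); platform B is A with entries independently zeroed at a
#' gene-specific extra dropout rate (`dropout_boost`), emulating a less
#' sensitive platform. Gene annotations (GC fraction, transcript length) are
#' drawn from configurable distributions, and the manifest declares each
#' gene's expected detection class from the planted rates.
#'
#' @param n_genes,n_cells Dimensions (defaults 300 x 2000).
#' @param detection_rate Per-gene detection probability on platform A;
#'   recycled (default 0.5).
#' @param dropout_boost Per-gene extra dropout probability for platform B in
#'   `[0, 1)`; recycled (default 0).
#' @param mean_extra_counts Poisson mean of counts above 1 (default 2).
#' @param seed Integer seed.
#' @return List with `matrix_a`, `matrix_b`, `annotations` (synthetic
#'   `gene_id`/`gc_fraction`/`transcript_length` table) and `manifest`
#'   (per-gene planted rates and expected class at the 0.10 cutoff).
#' @export
generate_platform_pair <- function(n_genes = 300L, n_cells = 2000L,
                                   detection_rate = 0.5, dropout_boost = 0,
                                   mean_extra_counts = 2, seed = 1L) {
  detection_rate <- rep_len(detection_rate, n_genes)
  dropout_boost <- rep_len(dropout_boost, n_genes)
  if (any(dropout_boost < 0 | dropout_boost >= 1)) {
    stop("generate_platform_pair: dropout_boost must be in [0, 1)")
  }
  with_local_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    barcodes <- sprintf("CELL%05d", seq_len(n_cells))
    a <- matrix(0, n_genes, n_cells, dimnames = list(gene_ids, barcodes))
    b <- a
    for (g in seq_len(n_genes)) {
      present <- stats::rbinom(n_cells, 1L, detection_rate[g])
      cnt <- present * (1L + stats::rpois(n_cells, mean_extra_counts))
      a[g, ] <- cnt
      keep <- stats::rbinom(n_cells, 1L, 1 - dropout_boost[g])
      b[g, ] <- cnt * keep
    }
    expected_delta <- detection_rate * dropout_boost
    annotations <- data.frame(
      gene_id = gene_ids,
      gc_fraction = stats::rbeta(n_genes, 10, 10),
      transcript_length = pmax(200L, round(stats::rlnorm(n_genes, log(2000),
                                                         0.6))),
      stringsAsFactors = FALSE)
    manifest <- data.frame(
      gene_id = gene_ids, detection_rate = detection_rate,
      dropout_boost = dropout_boost, expected_delta = expected_delta,
      expected_class = ifelse(expected_delta >= 0.10, "a_favored", "common"),
      stringsAsFactors = FALSE)
    list(matrix_a = count_matrix(a), matrix_b = count_matrix(b),
         annotations = annotations, manifest = manifest,
         params = list(seed = seed, n_genes = n_genes, n_cells = n_cells))
  })
}
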