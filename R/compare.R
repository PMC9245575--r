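#' Per-gene cross-platform detection statistics
#'
#' For one cell subset measured on two platforms, computes per gene the
#' fraction of cells with count > 0 on each platform (`pct_a`, `pct_b`,
#' gene universes unified: a gene absent from one matrix has pct 0 there),
#' the difference `delta = pct_a - pct_b`, and the detection class:
#' `a_favored` when `delta >= 0.10` or the gene is detected only in A,
#' `b_favored` when `delta <= -0.10` or only in B, `common` otherwise.
#'
#' @param matrix_a,matrix_b Count matrices for the same cell subset on
#'   platforms A and B (cells need not match; genes are unified by id).
#' @param annotations Optional data frame with columns `gene_id`,
#'   `gc_fraction`, `transcript_length`, merged onto the result.
#' @param delta_cutoff Classification cutoff (default 0.10).
#' @return Data frame of gene comparison records.
#' @export
detection_stats <- function(matrix_a, matrix_b, annotations = NULL,
                            delta_cutoff = 0.10) {
  pct <- function(m) Matrix::rowSums(m > 0) / ncol(m)
  pa <- pct(matrix_a)
  pb <- pct(matrix_b)
  genes <- sort(union(names(pa), names(pb)))
  pct_a <- ifelse(genes %in% names(pa), pa[genes], 0)
  pct_a[is.na(pct_a)] <- 0
  pct_b <- ifelse(genes %in% names(pb), pb[genes], 0)
  pct_b[is.na(pct_b)] <- 0
  delta <- pct_a - pct_b
  only_a <- pct_a > 0 & pct_b == 0
  only_b <- pct_b > 0 & pct_a == 0
  class <- ifelse(delta >= delta_cutoff | only_a, "a_favored",
                  ifelse(delta <= -delta_cutoff | only_b, "b_favored",
                         "common"))
  out <- data.frame(gene_id = genes, pct_a = unname(pct_a),
                    pct_b = unname(pct_b), delta = unname(delta),
                    detection_class = class,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    out <- merge(out, annotations[, c("gene_id", "gc_fraction",
                                      "transcript_length")],
                 by = "gene_id", all.x = TRUE, sort = TRUE)
  }
  out
}

#' Annotation bias between detection classes
#'
#' Compares GC fraction and transcript length between detection classes
#' (e.g. platform-favored vs commonly detected genes): per-class medians and
#' IQRs, and two-sided Wilcoxon rank-sum p-values for every class pair,
#' Holm-adjusted across all tests.
#'
#' @param records Output of [detection_stats()] carrying `gc_fraction` and
#'   `transcript_length`.
#' @param variables Columns to compare (default both annotation columns).
#' @return List with `summaries` (class x variable medians/IQRs) and
#'   `tests` (pairwise rank-sum tests with raw and Holm-adjusted p-values).
#' @export
compare_annotation_bias <- function(records,
                                    variables = c("gc_fraction",
                                                  "transcript_length")) {
  classes <- sort(unique(records$detection_class))
  summaries <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(classes, function(cl) {
      x <- records[[v]][records$detection_class == cl]
      x <- x[is.finite(x)]
      if (length(x) < 2L) {
        warning("compare_annotation_bias: class '", cl,
                "' has < 2 finite values for ", v, "; summary omitted")
        return(NULL)
      }
      data.frame(variable = v, class = cl, n = length(x),
                 median = stats::median(x), iqr = stats::IQR(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- if (length(classes) >= 2) utils::combn(classes, 2,
                                                  simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(variables, function(v) {
    do.call(rbind, lapply(pairs, function(pr) {
      x <- records[[v]][records$detection_class == pr[1]]
      y <- records[[v]][records$detection_class == pr[2]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2L || length(y) < 2L) return(NULL)
      p <- stats::wilcox.test(x, y, alternative = "two.sided",
                              exact = FALSE)$p.value
      data.frame(variable = v, class_a = pr[1], class_b = pr[2],
                 p_value = p, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(tests) && nrow(tests)) {
    tests$p_adjusted <- stats::p.adjust(tests$p_value, method = "holm")
  }
  rownames(summaries) <- rownames(tests) <- NULL
  list(summaries = summaries, tests = tests)
}

#' Pseudo-bulk profiles per cell subset
#'
#' Sums raw counts over the cells of each subset label and rescales every
#' profile to a total of 10,000,000 reads.
#'
#' @param matrix Count matrix (genes x cells).
#' @param cell_labels Character vector of subset labels, one per cell.
#' @param total Target total (default 1e7).
#' @return Named list of `pseudobulk_profile` objects (fields `label`,
#'   `values` named per-gene normalized counts, `n_cells`, `raw_total`).
#'   Empty labels are skipped with a warning.
#' @export
pseudobulk <- function(matrix, cell_labels, total = 1e7) {
  if (length(cell_labels) != ncol(matrix)) {
    stop("pseudobulk: need one label per cell")
  }
  if (anyNA(cell_labels)) stop("pseudobulk: every cell must be labeled")
  out <- list()
  for (lab in sort(unique(cell_labels))) {
    cols <- cell_labels == lab
    sums <- Matrix::rowSums(matrix[, cols, drop = FALSE])
    rt <- sum(sums)
    if (rt == 0) {
      warning("pseudobulk: label '", lab, "' has zero total; skipped")
      next
    }
    out[[lab]] <- structure(
      list(label = lab, values = sums / rt * total,
           n_cells = sum(cols), raw_total = rt),
      class = "pseudobulk_profile")
  }
  out
}

#' Kullback-Leibler divergence between two expression distributions
#'
#' Histograms both profiles' per-gene `log10(normalized count + 1)` values
#' over shared equal-width bins spanning the pooled range, adds `epsilon` to
#' every bin and renormalizes, then computes the (asymmetric)
#' `KL(P || Q) = sum p * ln(p / q)` in nats.
#'
#' @param p,q `pseudobulk_profile` objects over the same gene universe.
#' @param n_bins Number of histogram bins (default 100).
#' @param epsilon Pseudocount added to every bin (default 1e-9).
#' @return KL divergence in nats (non-negative; 0 when P = Q).
#' @export
kl_divergence_profiles <- function(p, q, n_bins = 100L, epsilon = 1e-9) {
  stopifnot(inherits(p, "pseudobulk_profile"),
            inherits(q, "pseudobulk_profile"))
  if (!identical(sort(names(p$values)), sort(names(q$values)))) {
    stop("kl_divergence_profiles: profiles must share one gene universe")
  }
  xp <- log10(p$values + 1)
  xq <- log10(q$values + 1)
  rng <- range(c(xp, xq))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  hp <- graphics::hist(xp, breaks = breaks, plot = FALSE)$counts
  hq <- graphics::hist(xq, breaks = breaks, plot = FALSE)$counts
  kl_divergence(hp / sum(hp), hq / sum(hq), epsilon = epsilon)
}

#' Kullback-Leibler divergence of two discrete distributions
#'
#' `KL(P || Q) = sum p * ln(p / q)` after adding `epsilon` to every bin and
#' renormalizing both vectors.
#'
#' @param p,q Non-negative vectors of equal length (normalized internally).
#' @param epsilon Pseudocount (default 1e-9).
#' @return Divergence in nats.
#' @export
kl_divergence <- function(p, q, epsilon = 1e-9) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  p <- p + epsilon
  q <- q + epsilon
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Correlate cell-subset compositions between assays
#'
#' Pearson correlation (with two-sided p-value) and ordinary least-squares
#' regression of composition A on composition B over matched subset labels,
#' as used to compare scRNA-seq compositions with flow cytometry.
#'
#' @param comp_a,comp_b Named numeric vectors of subset fractions; names
#'   must match one-to-one (unmatched labels are an error, never silently
#'   dropped).
#' @return List: `pearson_r`, `r_squared`, `slope`, `intercept`, `p_value`,
#'   `n`.
#' @export
composition_correlation <- function(comp_a, comp_b) {
  if (!is.null(names(comp_a)) || !is.null(names(comp_b))) {
    if (is.null(names(comp_a)) || is.null(names(comp_b)) ||
        !setequal(names(comp_a), names(comp_b))) {
      stop("composition_correlation: subset labels do not match")
    }
    comp_b <- comp_b[names(comp_a)]
  }
  if (length(comp_a) < 3L) {
    stop("composition_correlation: need >= 3 matched labels")
  }
  if (stats::sd(comp_a) == 0 || stats::sd(comp_b) == 0) {
    stop("composition_correlation: zero-variance composition vector")
  }
  ct <- stats::cor.test(comp_a, comp_b, method = "pearson")
  fit <- stats::lm(comp_a ~ comp_b)
  list(pearson_r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = ct$p.value,
       n = length(comp_a))
}
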