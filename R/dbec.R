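#' DBEC parameter set
#'
#' Distribution-based error correction thresholds. Defaults are the values
#' used for shallow-sequenced data: genes enter correction when their
#' log2(max count + 1) exceeds 8; a gene is touched only when its largest
#' component mean exceeds 5.5 (6 for deep-sequenced data); components whose
#' mean sits more than 5 (5.5 deep) below the largest are classified as
#' diffusion-derived background and zeroed.
#'
#' @param depth_mode `"shallow"` or `"deep"`; selects the threshold pair.
#' @param select_log2max_gt Selection gate on log2(max + 1) (default 8).
#' @param comp_mean_gt Gate on the maximum component mean; default 5.5
#'   (shallow) / 6 (deep).
#' @param diff_gt Gate on the difference from the maximum component mean;
#'   default 5 (shallow) / 5.5 (deep).
#' @param k_range Component numbers to try (default 1:3).
#' @param mean_scale Scale on which component means are compared to the
#'   gates: `"transformed"` (the fitted biexponential scale, default) or
#'   `"log2"` (component means recomputed as responsibility-weighted means
#'   of log2(count + 1)).
#' @param include_zeros Include zero counts in the fit (default `FALSE`:
#'   zeros carry no background signal and swamp the low component).
#' @param em List of EM settings: `max_iter`, `tol`, `n_restarts`, `seed`.
#' @return A `dbec_params` list.
#' @export
dbec_params <- function(depth_mode = c("shallow", "deep"),
                        select_log2max_gt = 8,
                        comp_mean_gt = NULL,
                        diff_gt = NULL,
                        k_range = 1:3,
                        mean_scale = c("transformed", "log2"),
                        include_zeros = FALSE,
                        em = list()) {
  depth_mode <- match.arg(depth_mode)
  mean_scale <- match.arg(mean_scale)
  comp_mean_gt <- comp_mean_gt %||% c(shallow = 5.5, deep = 6)[[depth_mode]]
  diff_gt <- diff_gt %||% c(shallow = 5, deep = 5.5)[[depth_mode]]
  stopifnot(select_log2max_gt > 0 || is.infinite(select_log2max_gt),
            comp_mean_gt > 0, diff_gt > 0,
            all(k_range %in% 1:3))
  em_def <- list(max_iter = 500L, tol = 1e-8, n_restarts = 5L, seed = 1L)
  em <- utils::modifyList(em_def, em)
  structure(list(depth_mode = depth_mode,
                 select_log2max_gt = select_log2max_gt,
                 comp_mean_gt = comp_mean_gt, diff_gt = diff_gt,
                 k_range = sort(unique(as.integer(k_range))),
                 mean_scale = mean_scale, include_zeros = include_zeros,
                 em = em),
            class = "dbec_params")
}

#' Select genes for DBEC correction
#'
#' A gene is selected iff `log2(max per-cell count + 1)` is strictly greater
#' than the gate (default 8): a gene whose maximum count is 255 sits exactly
#' at the boundary (`log2(256) = 8`) and is excluded.
#'
#' @param matrix Count matrix (genes x cells).
#' @param params A [dbec_params()] set.
#' @return Character vector of selected gene ids.
#' @export
select_genes <- function(matrix, params = dbec_params()) {
  if (!nrow(matrix) || !ncol(matrix)) stop("select_genes: empty matrix")
  gene_max <- gene_row_max(matrix)
  rownames(matrix)[log2(gene_max + 1) > params$select_log2max_gt]
}

gene_row_max <- function(m) {
  mx <- numeric(nrow(m))
  trip <- Matrix::summary(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                      "CsparseMatrix"))
  if (nrow(trip)) {
    agg <- tapply(trip$x, trip$i, max)
    mx[as.integer(names(agg))] <- as.numeric(agg)
  }
  stats::setNames(mx, rownames(m))
}

#' Classify mixture components as background
#'
#' Let `m*` be the largest component mean (on the configured scale). If `m*`
#' does not exceed `comp_mean_gt` the gene is left untouched (empty set,
#' whatever the gaps). Otherwise every component whose mean sits more than
#' `diff_gt` below `m*` is background.
#'
#' @param fit A `mixture_fit` (components sorted by mean).
#' @param params A [dbec_params()] set.
#' @param means Optional override of the component means to gate on (used
#'   for the `"log2"` mean scale).
#' @return Integer vector of background component indices (possibly empty).
#' @export
classify_components <- function(fit, params = dbec_params(), means = NULL) {
  m <- means %||% fit$means
  m_star <- max(m)
  if (!(m_star > params$comp_mean_gt)) return(integer(0))
  which(m_star - m > params$diff_gt)
}

#' Apply distribution-based error correction to a count matrix
#'
#' For each selected gene (see [select_genes()]): the gene's nonzero
#' per-cell counts are variance-stabilized with a fitted biexponential
#' transform ([fit_biexponential()]), an equal-variance Gaussian mixture is
#' fitted for each K in `k_range` ([fit_mixture_model_e()]) and the fit with
#' minimal BIC is kept ([select_model_bic()]); components are gated by
#' [classify_components()], and every cell whose maximum-a-posteriori
#' component is background has that gene's count set to zero. Zero counts
#' are never modified, non-selected genes pass through unchanged, and a
#' per-gene fit failure leaves that gene unchanged (logged in its decision
#' record) rather than aborting the matrix.
#'
#' @param matrix Count matrix of called cells (genes x cells).
#' @param params A [dbec_params()] set.
#' @return A list with `matrix` (corrected counts, elementwise `<=` input)
#'   and `decisions` (one record per gene: `gene_id`, `selected`,
#'   `transform`, `fit`, `component_means`, `background_components`,
#'   `n_entries_zeroed`, `error`).
#' @export
apply_dbec <- function(matrix, params = dbec_params()) {
  matrix <- Matrix::drop0(validate_count_matrix(matrix))
  sel <- select_genes(matrix, params)
  trip <- Matrix::summary(matrix)
  decisions <- vector("list", nrow(matrix))
  names(decisions) <- rownames(matrix)
  drop_mask <- logical(nrow(trip))
  for (g in rownames(matrix)) {
    if (!g %in% sel) {
      decisions[[g]] <- dbec_decision(g, selected = FALSE)
      next
    }
    gi <- match(g, rownames(matrix))
    rows <- which(trip$i == gi)
    vals <- trip$x[rows]
    x_fit <- vals
    if (params$include_zeros) {
      x_fit <- c(vals, rep(0, ncol(matrix) - length(vals)))
    }
    dec <- tryCatch(
      dbec_gene(g, x_fit, params, seed = child_seed(params$em$seed, gi)),
      error = function(e) dbec_decision(g, selected = TRUE,
                                        error = conditionMessage(e))
    )
    if (length(dec$background_components) && is.null(dec$error)) {
      # MAP assignment of each nonzero cell, in the order of x_fit
      map <- max.col(dec$fit$responsibilities, ties.method = "first")
      bg_cells <- map[seq_along(vals)] %in% dec$background_components
      drop_mask[rows[bg_cells]] <- TRUE
      dec$n_entries_zeroed <- sum(bg_cells)
    }
    decisions[[g]] <- dec
  }
  keep <- trip[!drop_mask, , drop = FALSE]
  out <- Matrix::sparseMatrix(i = keep$i, j = keep$j, x = keep$x,
                              dims = dim(matrix), dimnames = dimnames(matrix))
  list(matrix = out, decisions = decisions)
}

dbec_gene <- function(gene_id, x_fit, params, seed) {
  tr <- fit_biexponential(x_fit, n_starts = 5L, seed = seed)
  t_vals <- biexp_apply(tr, x_fit)
  fits <- lapply(params$k_range[params$k_range * 5L <= length(t_vals)],
                 function(k) {
                   fit_mixture_model_e(t_vals, k,
                                       max_iter = params$em$max_iter,
                                       tol = params$em$tol,
                                       n_restarts = params$em$n_restarts,
                                       seed = child_seed(seed, k))
                 })
  if (!length(fits)) stop("too few observations for any K in k_range")
  fit <- select_model_bic(fits)
  gate_means <- fit$means
  if (params$mean_scale == "log2") {
    l2 <- log2(x_fit + 1)
    nk <- colSums(fit$responsibilities)
    gate_means <- as.numeric(crossprod(fit$responsibilities, l2)) /
      pmax(nk, 1e-12)
  }
  bg <- classify_components(fit, params, means = gate_means)
  dbec_decision(gene_id, selected = TRUE, transform = tr, fit = fit,
                component_means = gate_means, background_components = bg)
}

dbec_decision <- function(gene_id, selected, transform = NULL, fit = NULL,
                          component_means = numeric(0),
                          background_components = integer(0),
                          n_entries_zeroed = 0L, error = NULL) {
  structure(list(gene_id = gene_id, selected = selected,
                 transform = transform, fit = fit,
                 component_means = component_means,
                 background_components = background_components,
                 n_entries_zeroed = n_entries_zeroed, error = error),
            class = "dbec_decision")
}

#' Summarize DBEC decisions as a table
#'
#' One row per gene: selection status, chosen K, component means, background
#' component set and number of zeroed entries — the layout written by the
#' `dbec` CLI subcommand.
#'
#' @param decisions The `decisions` element of an [apply_dbec()] result.
#' @return A data frame.
#' @export
dbec_decisions_table <- function(decisions) {
  rows <- lapply(decisions, function(d) {
    data.frame(
      gene = d$gene_id,
      selected = d$selected,
      K = if (is.null(d$fit)) NA_integer_ else d$fit$K,
      component_means = paste(sprintf("%.4f", d$component_means),
                              collapse = ","),
      background_components = paste(d$background_components, collapse = ","),
      n_entries_zeroed = d$n_entries_zeroed,
      fallback_transform = isTRUE(d$transform$fallback),
      error = d$error %||% "",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
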