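test_that("matrix filtering drops sparse genes then shallow cells", {
  set.seed(61)
  m <- rand_count_matrix(30, 20, density = 0.9, seed = 61)
  f <- filter_matrix(m, min_cells = 5, min_genes = 10)
  expect_true(all(Matrix::rowSums(f > 0) >= 5))
  expect_true(all(Matrix::colSums(f > 0) >= 10))

  # gene present in 4 cells is dropped at min_cells = 5
  m2 <- count_matrix(rbind(rare = c(1, 1, 1, 1, 0, 0),
                           common = c(5, 5, 5, 5, 5, 5)),
                     gene_ids = c("rare", "common"),
                     barcode_ids = sprintf("c%d", 1:6))
  f2 <- filter_matrix(m2, min_cells = 5, min_genes = 1)
  expect_false("rare" %in% rownames(f2))
  expect_true("common" %in% rownames(f2))

  # cell with 499 detected genes is dropped at min_genes = 500
  m3 <- count_matrix(cbind(deep = rep(1, 501),
                           shallow = c(rep(1, 499), 0, 0)),
                     gene_ids = sprintf("g%03d", 1:501),
                     barcode_ids = c("deep", "shallow"))
  f3 <- filter_matrix(m3, min_cells = 0, min_genes = 500)
  expect_equal(colnames(f3), "deep")

  # all-pass matrix is untouched; impossible thresholds raise
  expect_equal(as.matrix(filter_matrix(m2, 0, 0)), as.matrix(m2))
  expect_error(filter_matrix(m2, min_cells = 100, min_genes = 1),
               "empty result")
})

test_that("QC proportions match exhaustive per-cell sums", {
  genes <- c("mt-Nd1", "mt-Co1", "Rps6", "Actb", "Rn45s")
  set.seed(71)
  m <- count_matrix(matrix(rpois(5 * 8, 10), 5, 8,
                           dimnames = list(genes, sprintf("c%d", 1:8))))
  qc <- qc_proportions(m)
  dense <- as.matrix(m)
  for (j in 1:8) {
    tot <- sum(dense[, j])
    expect_equal(qc$mito_fraction[j], sum(dense[1:2, j]) / tot)
    expect_equal(qc$ribo_protein_fraction[j], dense[3, j] / tot)
    expect_equal(qc$rrna_fraction[j], dense[5, j] / tot)
    expect_equal(qc$genes_detected[j], sum(dense[, j] > 0))
  }
  # 25 mito of 100 total -> 0.25 exactly
  m1 <- count_matrix(matrix(c(25, 75), 2, 1),
                     gene_ids = c("mt-Nd1", "Actb"), barcode_ids = "c1")
  expect_equal(qc_proportions(m1)$mito_fraction, 0.25)
  # no matching genes -> all zero fractions
  m0 <- count_matrix(matrix(5, 1, 1), "Actb", "c1")
  expect_equal(qc_proportions(m0)$mito_fraction, 0)
})

test_that("mito filtering keeps the boundary cell (strict 'over')", {
  m <- count_matrix(matrix(c(25, 75, 26, 74, 0, 100), 2, 3),
                    gene_ids = c("mt-Nd1", "Actb"),
                    barcode_ids = c("at", "over", "zero"))
  qc <- qc_proportions(m)
  f <- filter_cells_mito(qc, m, threshold = 0.25)
  expect_true("at" %in% colnames(f))     # exactly 0.25 retained
  expect_false("over" %in% colnames(f))  # 0.26 removed
  expect_true("zero" %in% colnames(f))
  expect_equal(ncol(filter_cells_mito(qc, m, threshold = 1)), 3L)
})

test_that("log-CPM normalization matches the direct formula", {
  # count 10 in a cell of total 1,000 -> ln(1 + 10/1000 * 1e6)
  m <- count_matrix(matrix(c(10, 990), 2, 1),
                    gene_ids = c("a", "b"), barcode_ids = "c1")
  norm <- normalize_log_cpm(m)
  expect_equal(norm["a", "c1"], log(1 + 10000), tolerance = 1e-12)

  big <- rand_count_matrix(60, 40, density = 0.8, seed = 81)
  big <- big[, Matrix::colSums(big) > 0]
  norm2 <- as.matrix(normalize_log_cpm(big))
  dense <- as.matrix(big)
  want <- log(1 + sweep(dense, 2, colSums(dense), "/") * 1e6)
  expect_lt(max(abs(norm2 - want)), 1e-12)
  expect_equal(norm2[dense == 0], rep(0, sum(dense == 0)))

  # per-cell gene rank order is preserved
  for (j in 1:5) {
    expect_equal(order(norm2[, j]), order(dense[, j]))
  }
  z <- count_matrix(matrix(0, 1, 1), "g", "c")
  expect_error(normalize_log_cpm(z), "zero total")
})

test_that("mvp highly variable genes match a step-by-step recomputation", {
  set.seed(91)
  n_genes <- 200; n_cells <- 100
  counts <- matrix(rpois(n_genes * n_cells, 5), n_genes, n_cells)
  # overdispersed gene with a background-like mean: 50 counts in 10 cells
  counts[1, ] <- 0
  counts[1, sample(n_cells, 10)] <- 50
  m <- count_matrix(matrix(as.numeric(counts), n_genes, n_cells,
                           dimnames = list(sprintf("g%03d", 1:n_genes),
                                           sprintf("c%03d", 1:n_cells))))
  norm <- normalize_log_cpm(m)
  got <- find_variable_genes_mvp(norm)

  # independent recomputation with explicit loops
  x <- expm1(as.matrix(norm))
  mu <- numeric(n_genes); dsp <- numeric(n_genes)
  for (g in 1:n_genes) {
    mu[g] <- mean(x[g, ])
    vg <- var(x[g, ])
    dsp[g] <- if (mu[g] > 0 && vg > 0) log(vg / mu[g]) else NA
  }
  fin <- is.finite(dsp)
  bins <- cut(mu[fin], breaks = 20)
  z <- rep(NA_real_, n_genes)
  for (b in levels(bins)) {
    idx <- which(fin)[bins == b]
    if (!length(idx)) next
    z[idx] <- if (length(idx) < 2 || sd(dsp[idx]) == 0) 0 else
      (dsp[idx] - mean(dsp[idx])) / sd(dsp[idx])
  }
  want <- rownames(m)[which(fin & mu >= 0.1 & z >= 0.5)]
  expect_setequal(got, want)
  # the planted overdispersed gene is found
  expect_true("g001" %in% got)
})

test_that("zero-variance genes are excluded from HVG selection", {
  # build the normalized matrix directly so one gene has exactly zero
  # variance across cells
  set.seed(92)
  norm <- matrix(log1p(rpois(50 * 40, 20)), 50, 40,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%02d", 1:40)))
  norm["g01", ] <- log1p(7)
  sel <- find_variable_genes_mvp(Matrix::Matrix(norm, sparse = TRUE),
                                 n_bins = 5)
  stats <- attr(sel, "stats")
  expect_false("g01" %in% sel)
  expect_false(is.finite(stats$dispersion[stats$gene == "g01"]))
})
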