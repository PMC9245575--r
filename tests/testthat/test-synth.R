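test_that("generators are pure functions of (params, seed)", {
  g1 <- generate_rank_curve(200, 2000, seed = 5)
  g2 <- generate_rank_curve(200, 2000, seed = 5)
  expect_identical(as.matrix(g1$matrix), as.matrix(g2$matrix))
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_rank_curve(200, 2000, seed = 6)
  expect_false(identical(g1$manifest$total, g3$manifest$total))

  d1 <- generate_dbec_matrix(n_genes = 20, n_cells = 100, n_signal_genes = 5,
                             seed = 9)
  d2 <- generate_dbec_matrix(n_genes = 20, n_cells = 100, n_signal_genes = 5,
                             seed = 9)
  expect_identical(as.matrix(d1$matrix), as.matrix(d2$matrix))
  expect_identical(d1$manifest, d2$manifest)

  geom <- toy_geometry()
  b1 <- generate_barcode_reads(geom, 100, c(0.5, 0.3, 0.2), seed = 3)
  b2 <- generate_barcode_reads(geom, 100, c(0.5, 0.3, 0.2), seed = 3)
  expect_identical(b1$reads, b2$reads)
})

test_that("planted barcode error classes behave as designed", {
  geom <- toy_geometry()  # pairwise Hamming >= 5 in every section
  clean <- generate_barcode_reads(geom, 500, c(1, 0, 0), seed = 12)
  hits <- parse_barcodes(clean$reads, geom)
  expect_true(all(hits$status == "exact"))
  expect_identical(hits$barcode, clean$manifest$true_barcode)

  one <- generate_barcode_reads(geom, 500, c(0, 1, 0), seed = 13)
  hits1 <- parse_barcodes(one$reads, geom)
  expect_true(all(hits1$status == "corrected"))
  expect_identical(hits1$barcode, one$manifest$true_barcode)

  two <- generate_barcode_reads(geom, 500, c(0, 0, 1), seed = 14)
  hits2 <- parse_barcodes(two$reads, geom)
  expect_true(all(hits2$status == "rejected"))
})

test_that("barcode reads can be written as FASTQ", {
  geom <- toy_geometry()
  path <- withr::local_tempfile(fileext = ".fastq")
  sim <- generate_barcode_reads(geom, 10, seed = 2, fastq = path)
  lines <- readLines(path)
  expect_equal(length(lines), 40L)
  expect_true(all(startsWith(lines[seq(1, 40, 4)], "@read")))
  expect_identical(lines[seq(2, 40, 4)], sim$reads)
})

test_that("rank-curve generator enforces regime separation", {
  expect_error(generate_rank_curve(100, 100, cell_count_mean = 100,
                                   ambient_count_mean = 50),
               "ratio must be >= 20")
  pure <- generate_rank_curve(300, 0, seed = 4)
  expect_true(all(pure$manifest$is_cell))
  expect_equal(ncol(pure$matrix), 300L)
  # totals in the matrix match the manifest
  expect_equal(unname(Matrix::colSums(pure$matrix)),
               pure$manifest$total)
})

test_that("dbec generator labels entries and respects its regime gap", {
  expect_error(generate_dbec_matrix(high_mean_log2 = 5, low_mean_log2 = 2),
               "differ by >= 4")
  expect_error(generate_dbec_matrix(signal_cell_fraction = 1.2), "in \\(0,1\\)")
  sim <- generate_dbec_matrix(n_genes = 20, n_cells = 200, n_signal_genes = 5,
                              seed = 31)
  # manifest covers exactly the nonzero entries
  expect_equal(nrow(sim$manifest), Matrix::nnzero(sim$matrix))
  # signal labels only in signal genes, in ~ the configured cell fraction
  sig <- sim$manifest[sim$manifest$label == "signal", ]
  expect_true(all(sig$gene %in% sim$signal_genes))
  per_gene <- table(sig$gene)
  expect_true(all(per_gene <= 0.3 * 200))
  # signal-gene transformed distributions are far above background ones
  for (g in sim$signal_genes[1:2]) {
    v <- sim$matrix[g, ]
    expect_gt(log2(max(v) + 1), 8)
  }
  off <- setdiff(rownames(sim$matrix), sim$signal_genes)
  expect_true(all(log2(apply(as.matrix(sim$matrix[off, ]), 1, max) + 1) < 8))

  # with no signal genes nothing passes DBEC selection
  none <- generate_dbec_matrix(n_genes = 15, n_cells = 150,
                               n_signal_genes = 0, seed = 32)
  expect_equal(length(select_genes(none$matrix, dbec_params())), 0L)
})

test_that("platform pair plants gene-specific dropout with annotations", {
  same <- generate_platform_pair(n_genes = 40, n_cells = 300,
                                 dropout_boost = 0, seed = 41)
  expect_identical(as.matrix(same$matrix_a), as.matrix(same$matrix_b))
  st <- detection_stats(same$matrix_a, same$matrix_b, same$annotations)
  expect_true(all(st$detection_class == "common"))
  expect_true(all(st$gc_fraction >= 0 & st$gc_fraction <= 1))
  expect_true(all(st$transcript_length >= 1))

  # boost 0.5 on detection 0.8 -> delta ~ 0.4
  boosted <- generate_platform_pair(n_genes = 10, n_cells = 2000,
                                    detection_rate = 0.8,
                                    dropout_boost = 0.5, seed = 42)
  st2 <- detection_stats(boosted$matrix_a, boosted$matrix_b)
  expect_true(all(abs(st2$delta - 0.4) < 0.08))
  expect_true(all(st2$detection_class == "a_favored"))

  expect_error(generate_platform_pair(dropout_boost = 1), "\\[0, 1\\)")
})

test_that("planted detection classes are recovered across seeds", {
  ok <- 0L; total <- 0L
  for (s in 1:20) {
    sim <- generate_platform_pair(
      n_genes = 30, n_cells = 2000, detection_rate = 0.6,
      dropout_boost = rep(c(0, 0.5), 15), seed = 500 + s)
    st <- detection_stats(sim$matrix_a, sim$matrix_b)
    got <- st$detection_class[match(sim$manifest$gene_id, st$gene_id)]
    planted <- sim$manifest$expected_class
    big <- abs(sim$manifest$expected_delta) >= 0.2 |
      sim$manifest$expected_delta == 0
    ok <- ok + sum(got[big] == planted[big])
    total <- total + sum(big)
  }
  expect_gte(ok / total, 0.95)
})
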