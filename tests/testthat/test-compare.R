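test_that("detection classes follow the 0.10 delta rule and exclusivity", {
  mk <- function(p, n = 20) {
    count_matrix(matrix(as.numeric(sapply(p, function(pp)
      c(rep(1, round(pp * n)), rep(0, n - round(pp * n))))), length(p), n,
      byrow = TRUE,
      dimnames = list(sprintf("g%d", seq_along(p)), sprintf("c%d", 1:n))))
  }
  a <- mk(c(0.30, 0.05, 0.50))
  b <- mk(c(0.15, 0.00, 0.50))
  st <- detection_stats(a, b)
  expect_equal(st$delta, st$pct_a - st$pct_b, tolerance = 1e-15)
  expect_equal(st$detection_class[st$gene_id == "g1"], "a_favored")  # 0.15
  expect_equal(st$detection_class[st$gene_id == "g2"], "a_favored")  # only A
  expect_equal(st$detection_class[st$gene_id == "g3"], "common")

  # identical matrices -> all deltas 0, all common
  st_same <- detection_stats(a, a)
  expect_true(all(st_same$delta == 0))
  expect_true(all(st_same$detection_class == "common"))

  # swapping platforms negates deltas and swaps classes
  st_rev <- detection_stats(b, a)
  expect_equal(st_rev$delta, -st$delta)
  expect_equal(st_rev$detection_class,
               c(a_favored = "b_favored", b_favored = "a_favored",
                 common = "common")[st$detection_class], ignore_attr = TRUE)

  # unified gene universes: a gene absent from one matrix has pct 0 there
  st_u <- detection_stats(rbind(as.matrix(a), g9 = rep(1, 20)), b)
  expect_equal(st_u$pct_b[st_u$gene_id == "g9"], 0)
  expect_equal(st_u$detection_class[st_u$gene_id == "g9"], "a_favored")
})

test_that("annotation bias tests use rank-sums with Holm correction", {
  set.seed(15)
  rec <- data.frame(
    gene_id = sprintf("g%03d", 1:120),
    detection_class = rep(c("a_favored", "common"), each = 60),
    gc_fraction = runif(120, 0.3, 0.7),
    transcript_length = c(round(rlnorm(60, log(12000), 0.1)),
                          round(rlnorm(60, log(2000), 0.1))))
  out <- compare_annotation_bias(rec)
  expect_setequal(out$summaries$class, c("a_favored", "common"))
  med <- out$summaries
  expect_gt(med$median[med$variable == "transcript_length" &
                         med$class == "a_favored"],
            med$median[med$variable == "transcript_length" &
                         med$class == "common"])
  tl <- out$tests[out$tests$variable == "transcript_length", ]
  gc <- out$tests[out$tests$variable == "gc_fraction", ]
  expect_lt(tl$p_value, 1e-10)   # planted shift detected
  expect_gt(gc$p_value, 0.01)    # same distribution
  # Holm adjustment matches p.adjust and the hand formula on (0.01, 0.04)
  expect_equal(out$tests$p_adjusted,
               p.adjust(out$tests$p_value, method = "holm"))
  expect_equal(p.adjust(c(0.01, 0.04), method = "holm"), c(0.02, 0.04))

  # planted constant shift appears in the medians exactly
  rec2 <- rec
  rec2$transcript_length <- rep(c(10000 + 1:60, 1:60), 1)
  out2 <- compare_annotation_bias(rec2, variables = "transcript_length")
  s2 <- out2$summaries
  expect_equal(s2$median[s2$class == "a_favored"] -
                 s2$median[s2$class == "common"], 10000)
})

test_that("identical class distributions give p near 1", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:40),
                    detection_class = rep(c("a_favored", "common"), 20),
                    gc_fraction = rep(seq(0.3, 0.7, length.out = 20), each = 2),
                    transcript_length = rep(1000, 40))
  out <- compare_annotation_bias(rec, variables = "gc_fraction")
  expect_gt(out$tests$p_value, 0.9)
})

test_that("pseudobulk sums counts per label and rescales to 1e7", {
  # two genes with raw sums (3, 1) -> (7.5e6, 2.5e6)
  m <- count_matrix(matrix(c(2, 1, 1, 0), 2, 2),
                    gene_ids = c("a", "b"), barcode_ids = c("c1", "c2"))
  pb <- pseudobulk(m, c("x", "x"))
  expect_equal(unname(pb$x$values), c(7.5e6, 2.5e6))
  expect_equal(sum(pb$x$values), 1e7, tolerance = 1e-6)

  # group sums equal a brute-force tally before rescaling
  big <- rand_count_matrix(40, 30, seed = 19)
  labels <- rep(c("t", "u", "v"), each = 10)
  pb2 <- pseudobulk(big, labels)
  dense <- as.matrix(big)
  for (lab in c("t", "u", "v")) {
    raw <- rowSums(dense[, labels == lab])
    expect_equal(unname(pb2[[lab]]$values), unname(raw / sum(raw) * 1e7))
    expect_equal(sum(pb2[[lab]]$values) / 1e7, 1, tolerance = 1e-6)
  }
  # single-cell label is that cell rescaled
  pb3 <- pseudobulk(big, c("solo", rep("rest", 29)))
  expect_equal(unname(pb3$solo$values),
               unname(dense[, 1] / sum(dense[, 1]) * 1e7))
  expect_error(pseudobulk(big, labels[1:5]), "one label per cell")
})

test_that("KL divergence matches hand computation and Gibbs' inequality", {
  # two-bin hand example: 0.5 ln(0.5/0.9) + 0.5 ln(0.5/0.1)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-6)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-12)

  # KL(P||P) = 0 on profiles, KL >= 0 on random pairs
  m <- rand_count_matrix(100, 40, lambda = 20, seed = 23)
  pb <- pseudobulk(m, rep(c("p", "q"), each = 20))
  expect_equal(kl_divergence_profiles(pb$p, pb$p), 0, tolerance = 1e-12)
  for (s in 1:100) {
    set.seed(s)
    p <- runif(30); q <- runif(30)
    expect_gte(kl_divergence(p / sum(p), q / sum(q)), 0)
  }
  # asymmetry in general
  expect_false(isTRUE(all.equal(kl_divergence_profiles(pb$p, pb$q),
                                kl_divergence_profiles(pb$q, pb$p))))
})

test_that("composition correlation reports Pearson r and OLS line", {
  a <- c(T_cell = 0.1, B_cell = 0.3, myeloid = 0.6)
  ident <- composition_correlation(a, a)
  expect_equal(ident$pearson_r, 1, tolerance = 1e-12)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  b <- c(T_cell = 0.2, B_cell = 0.3, myeloid = 0.5)
  out <- composition_correlation(a, b)
  # closed-form Pearson r
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(out$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(out$r_squared, r_hand^2, tolerance = 1e-12)
  slope_hand <- sum((a - mean(a)) * (b - mean(b))) / sum((b - mean(b))^2)
  expect_equal(out$slope, slope_hand, tolerance = 1e-12)

  # affine relation keeps r = 1
  aff <- composition_correlation(a, 2 * a - 0.05)
  expect_equal(aff$pearson_r, 1, tolerance = 1e-12)
  expect_equal(aff$slope, 0.5, tolerance = 1e-12)

  expect_error(composition_correlation(a[1:2], b[1:2]), ">= 3")
  expect_error(composition_correlation(a, c(X = 1, Y = 1, Z = 1)),
               "labels do not match")
  expect_error(
    composition_correlation(c(p = .3, q = .3, r = .4) * 0 + 1/3,
                            c(p = .2, q = .3, r = .5)),
    "zero-variance")
})
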