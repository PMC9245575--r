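# Shared fixtures and independent oracles, built in code at test time.

# A 3-section geometry over separated whitelists. min_dist = 5 guarantees
# unique-neighbour correction for 1 substitution and rejection for 2.
toy_geometry <- function(n_per_section = 16L, sec_len = 7L, min_dist = 5L,
                         seed = 101L) {
  wl <- lapply(1:3, function(i) {
    random_whitelist(n_per_section, sec_len, min_dist = min_dist,
                     seed = seed + i)
  })
  barcode_geometry(
    sections = list(
      list(offset = 0L, length = sec_len, whitelist = wl[[1]]),
      list(offset = sec_len, length = sec_len, whitelist = wl[[2]]),
      list(offset = 2L * sec_len, length = sec_len, whitelist = wl[[3]])
    ),
    umi = list(offset = 3L * sec_len, length = 8L)
  )
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Exhaustive minimum-Hamming oracle for one read: per section, exact match
# stands, else the unique whitelist entry at distance 1, else rejection.
oracle_parse <- function(read, geometry) {
  calls <- character(length(geometry$sections))
  for (j in seq_along(geometry$sections)) {
    s <- geometry$sections[[j]]
    sub <- substr(read, s$offset + 1L, s$offset + s$length)
    d <- vapply(s$whitelist, hamming, 1L, a = sub)
    if (min(d) == 0L) {
      calls[j] <- s$whitelist[which.min(d)]
    } else if (sum(d == 1L) == 1L) {
      calls[j] <- s$whitelist[d == 1L]
    } else {
      return(NA_character_)
    }
  }
  paste0(calls, collapse = "")
}

# Exhaustive (gene, barcode) tally, independent of the sparse-matrix path.
oracle_tally <- function(records, valid_barcodes = NULL) {
  r <- records[records$is_mapped & !is.na(records$cell_barcode) &
                 !is.na(records$gene_id), ]
  if (!is.null(valid_barcodes)) r <- r[r$cell_barcode %in% valid_barcodes, ]
  tab <- table(r$gene_id, r$cell_barcode)
  mat <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  mat[sort(rownames(mat)), sort(colnames(mat)), drop = FALSE]
}

rand_count_matrix <- function(n_genes, n_cells, lambda = 2, density = 0.3,
                              seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rbinom(n_genes * n_cells, 1L, density) *
                (1L + stats::rpois(n_genes * n_cells, lambda)),
              n_genes, n_cells,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("b%04d", seq_len(n_cells))))
  count_matrix(m)
}

rand_tagged_records <- function(n, n_genes = 5L, n_barcodes = 4L, seed = 1L) {
  set.seed(seed)
  data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    cell_barcode = sample(sprintf("BC%02d", seq_len(n_barcodes)), n,
                          replace = TRUE),
    umi = sample(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"), n, replace = TRUE),
    gene_id = sample(sprintf("gene%02d", seq_len(n_genes)), n, replace = TRUE),
    is_primary = TRUE,
    is_mapped = TRUE,
    stringsAsFactors = FALSE
  )
}
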