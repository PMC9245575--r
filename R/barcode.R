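#' Describe the positional layout of a bead barcode read
#'
#' Bead barcodes on nanowell platforms are split into several short sections
#' separated by fixed linker sequences, with the UMI directly before the
#' polyT stretch. The geometry is entirely configuration-driven: section
#' offsets, lengths and whitelists, the UMI position, and (optionally) linker
#' sequences used for a +/-1 nt re-framing rescue.
#'
#' @param sections List of sections, each `list(offset =, length =, whitelist =)`
#'   with 0-based offsets; sections must be non-overlapping and in ascending
#'   offset order, and each whitelist non-empty with entries of uniform
#'   length equal to the section length.
#' @param umi `list(offset =, length =)`; default length 8 (8-base bead UMIs).
#' @param linkers Optional list of `list(offset =, seq =, max_mismatch =)`.
#' @return A `barcode_geometry` object.
#' @export
barcode_geometry <- function(sections, umi = NULL, linkers = NULL) {
  if (!length(sections)) stop("barcode_geometry: at least one section required")
  prev_end <- -1L
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    if (is.null(s$offset) || is.null(s$length) || is.null(s$whitelist)) {
      stop("barcode_geometry: section ", i, " needs offset, length, whitelist")
    }
    if (s$offset < prev_end + 1L && i > 1L || s$offset <= prev_end) {
      stop("barcode_geometry: sections overlap or are out of order at section ", i)
    }
    if (!length(s$whitelist)) {
      stop("barcode_geometry: empty whitelist in section ", i)
    }
    if (any(nchar(s$whitelist) != s$length)) {
      stop("barcode_geometry: whitelist entries of section ", i,
           " do not all have length ", s$length)
    }
    if (anyDuplicated(s$whitelist)) {
      stop("barcode_geometry: duplicate whitelist entries in section ", i)
    }
    sections[[i]]$whitelist <- as.character(s$whitelist)
    prev_end <- s$offset + s$length - 1L
  }
  if (!is.null(umi)) {
    if (is.null(umi$offset)) stop("barcode_geometry: umi needs an offset")
    umi$length <- umi$length %||% 8L
  }
  structure(list(sections = sections, umi = umi, linkers = linkers),
            class = "barcode_geometry")
}

#' @export
print.barcode_geometry <- function(x, ...) {
  cat("barcode_geometry:", length(x$sections), "sections (lengths",
      paste(vapply(x$sections, function(s) s$length, 1L), collapse = "+"),
      ")")
  if (!is.null(x$umi)) cat(", UMI", x$umi$length, "nt at offset", x$umi$offset)
  cat("\n")
  invisible(x)
}

min_read_length <- function(geometry) {
  ends <- vapply(geometry$sections, function(s) s$offset + s$length, 1L)
  if (!is.null(geometry$umi)) {
    ends <- c(ends, geometry$umi$offset + geometry$umi$length)
  }
  max(ends)
}

#' Parse and error-correct barcode reads
#'
#' Each barcode section is extracted at its configured offset and matched
#' against its whitelist: an exact member stands; otherwise the section is
#' corrected to the whitelist entry at Hamming distance 1 if that neighbour
#' is unique, and the read is rejected if there are zero or two or more
#' candidates (conservative unique-neighbour correction). A read whose
#' length cannot cover the geometry is rejected. The UMI is extracted
#' verbatim and carried along, never used for deduplication.
#'
#' @param reads Character vector of read sequences.
#' @param geometry A [barcode_geometry()].
#' @param reframe If `TRUE`, a read rejected in frame 0 is retried with all
#'   offsets shifted by -1 and +1 nt (linker-anchored frame slippage rescue);
#'   off by default.
#' @return Data frame with one row per read: `barcode` (concatenated
#'   corrected sections, `NA` when rejected), `n_corrected_sections`, `umi`,
#'   `status` (`exact`/`corrected`/`rejected`).
#' @export
parse_barcodes <- function(reads, geometry, reframe = FALSE) {
  stopifnot(inherits(geometry, "barcode_geometry"))
  out <- parse_barcodes_frame(reads, geometry, shift = 0L)
  if (reframe && any(out$status == "rejected")) {
    for (shift in c(-1L, 1L)) {
      idx <- which(out$status == "rejected")
      if (!length(idx)) break
      retry <- parse_barcodes_frame(reads[idx], geometry, shift = shift)
      hit <- retry$status != "rejected"
      out[idx[hit], ] <- retry[hit, ]
    }
  }
  out
}

parse_barcodes_frame <- function(reads, geometry, shift = 0L) {
  n <- length(reads)
  need <- min_read_length(geometry) + shift
  frame_ok <- geometry$sections[[1]]$offset + shift >= 0L
  ok <- frame_ok & nchar(reads) >= need
  sec_calls <- matrix(NA_character_, n, length(geometry$sections))
  sec_corr <- matrix(0L, n, length(geometry$sections))
  for (j in seq_along(geometry$sections)) {
    s <- geometry$sections[[j]]
    sub <- substr(reads, s$offset + 1L + shift, s$offset + s$length + shift)
    res <- match_whitelist(sub[ok], s$whitelist)
    sec_calls[ok, j] <- res$call
    sec_corr[ok, j] <- res$corrected
  }
  rejected <- !ok | rowSums(is.na(sec_calls)) > 0L
  barcode <- ifelse(rejected, NA_character_,
                    apply(sec_calls, 1L, paste0, collapse = ""))
  ncorr <- ifelse(rejected, 0L, rowSums(sec_corr))
  umi <- rep(NA_character_, n)
  if (!is.null(geometry$umi)) {
    u <- geometry$umi
    umi[!rejected] <- substr(reads[!rejected], u$offset + 1L + shift,
                             u$offset + u$length + shift)
  }
  status <- ifelse(rejected, "rejected",
                   ifelse(ncorr > 0L, "corrected", "exact"))
  data.frame(barcode = barcode, n_corrected_sections = as.integer(ncorr),
             umi = umi, status = status, stringsAsFactors = FALSE)
}

# Exact match, else unique Hamming-1 neighbour; NA when 0 or >=2 candidates.
match_whitelist <- function(queries, whitelist) {
  call <- whitelist[match(queries, whitelist)]
  corrected <- rep(FALSE, length(queries))
  todo <- which(is.na(call) & !is.na(queries))
  if (length(todo)) {
    uq <- unique(queries[todo])
    L <- nchar(whitelist[1])
    wl_chars <- matrix(unlist(strsplit(whitelist, "", fixed = TRUE)),
                       nrow = length(whitelist), byrow = TRUE)
    fix <- vapply(uq, function(q) {
      if (nchar(q) != L) return(NA_character_)
      qc <- strsplit(q, "", fixed = TRUE)[[1]]
      d <- rowSums(wl_chars != matrix(qc, nrow(wl_chars), L, byrow = TRUE))
      hit <- which(d == 1L)
      if (length(hit) == 1L) whitelist[hit] else NA_character_
    }, character(1))
    call[todo] <- fix[match(queries[todo], uq)]
    corrected[todo] <- !is.na(call[todo])
  }
  list(call = call, corrected = corrected)
}

#' Parse a single barcode read
#'
#' Convenience wrapper around [parse_barcodes()] returning a one-row list.
#'
#' @inheritParams parse_barcodes
#' @param read A single read sequence.
#' @return A list with fields `barcode`, `n_corrected_sections`, `umi`, `status`.
#' @export
parse_barcode <- function(read, geometry, reframe = FALSE) {
  as.list(parse_barcodes(read, geometry, reframe = reframe)[1L, ])
}

#' Generate a random whitelist with guaranteed pairwise separation
#'
#' Greedy rejection sampler over random DNA k-mers keeping only candidates at
#' Hamming distance `>= min_dist` from everything already accepted. Used to
#' build synthetic section whitelists on which unique-neighbour correction is
#' provably exact for single substitutions (`min_dist >= 3`) and rejection is
#' guaranteed for double substitutions (`min_dist >= 5`).
#'
#' @param n Number of entries.
#' @param length Entry length in nt.
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @return Character vector of `n` distinct sequences.
#' @export
random_whitelist <- function(n, length = 9L, min_dist = 3L, seed = 1L) {
  with_local_seed(seed, {
    acc <- character(0)
    chars <- c("A", "C", "G", "T")
    acc_chars <- matrix(character(0), 0, length)
    tries <- 0L
    while (base::length(acc) < n) {
      tries <- tries + 1L
      if (tries > 10000L * n) {
        stop("random_whitelist: cannot reach n=", n, " at min_dist=",
             min_dist, " and length=", length)
      }
      cand <- sample(chars, length, replace = TRUE)
      if (nrow(acc_chars) == 0L ||
          min(rowSums(acc_chars != matrix(cand, nrow(acc_chars), length,
                                          byrow = TRUE))) >= min_dist) {
        acc <- c(acc, paste0(cand, collapse = ""))
        acc_chars <- rbind(acc_chars, cand)
      }
    }
    acc
  })
}
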