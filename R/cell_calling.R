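#' Build the barcode-rank profile
#'
#' Orders barcodes by decreasing total read count (the "knee plot" curve:
#' total read count versus rank of the read count). Barcodes with zero total
#' are dropped; ties in totals are ordered by barcode id so the profile is
#' deterministic.
#'
#' @param matrix Count matrix (genes x barcodes).
#' @return A `rank_profile` object: data frame columns `barcode`, `total`,
#'   `rank` (1-based), plus `inflection_rank` / `inflection_count` fields
#'   once [find_inflection()] has been applied.
#' @export
rank_barcodes <- function(matrix) {
  totals <- Matrix::colSums(matrix)
  keep <- totals > 0
  if (!any(keep)) stop("rank_barcodes: all barcode totals are zero")
  totals <- totals[keep]
  ord <- order(-totals, names(totals))
  df <- data.frame(barcode = names(totals)[ord], total = unname(totals[ord]),
                   rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(list(profile = df, inflection_rank = NULL, inflection_count = NULL,
                 smoothing = NULL),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat("rank_profile:", nrow(x$profile), "barcodes, totals",
      max(x$profile$total), "..", min(x$profile$total), "\n")
  if (!is.null(x$inflection_rank)) {
    cat("  inflection at rank", x$inflection_rank, "(count",
        x$inflection_count, ")\n")
  }
  invisible(x)
}

#' Locate the inflection point of the barcode-rank curve
#'
#' On the log-log curve `y = log10(total)` vs `x = log10(rank)`, tied totals
#' are first collapsed to their average rank (so plateaus do not create
#' zero-width steps), `y` is smoothed with a running median of window `w`,
#' and the first finite differences `dy/dx` are scanned. The *knee* is the
#' curve's upper shoulder, the point of maximum elevation above the chord
#' joining the endpoints of the smoothed curve; the *inflection* is the segment of
#' steepest descent (most negative `dy/dx`) at or right of the knee, ties
#' broken toward the smaller rank. The threshold count is the total at the
#' upper end of that steepest segment, so a vertical cliff between ranks `r`
#' and `r + 1` yields an inflection at rank `r`.
#'
#' @param profile A `rank_profile` from [rank_barcodes()].
#' @param window Odd running-median window (default 5).
#' @param method `"inflection"` (default) or `"knee"` (threshold at the knee
#'   point instead).
#' @return The profile with `inflection_rank`, `inflection_count` and
#'   `smoothing` filled in. `inflection_rank` is the number of barcodes with
#'   total `>= inflection_count`, i.e. the rank of the last barcode on the
#'   upper plateau.
#' @export
find_inflection <- function(profile, window = 5L, method = c("inflection", "knee")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "rank_profile"))
  df <- profile$profile
  agg <- collapse_ties(df)
  if (nrow(agg) < 10L) {
    stop("find_inflection: only ", nrow(agg), " distinct totals; ",
         "need >= 10 (use a raw count threshold instead)")
  }
  x <- log10(agg$avg_rank)
  y <- log10(agg$total)
  w <- as.integer(window)
  if (w %% 2L == 0L) w <- w + 1L
  ys <- if (w > 1L && nrow(agg) >= w) stats::runmed(y, w) else y
  d1 <- diff(ys) / diff(x)
  # knee: the curve's upper shoulder, located as the point of maximum
  # elevation above the chord joining the curve's endpoints. Differential
  # curvature estimates are unstable where collapsed tie groups make the
  # rank spacing tiny, whereas the chord criterion is global and
  # deterministic.
  n <- length(x)
  chord <- ys[1] + (ys[n] - ys[1]) * (x - x[1]) / (x[n] - x[1])
  knee_idx <- which.max(ys - chord)
  if (method == "knee") {
    thr <- agg$total[knee_idx]
  } else {
    lo <- min(knee_idx, length(d1))
    seg <- lo:length(d1)
    best <- seg[which.min(d1[seg])]
    thr <- agg$total[best]  # upper end of the steepest segment
  }
  profile$inflection_count <- thr
  profile$inflection_rank <- sum(df$total >= thr)
  profile$smoothing <- list(window = w, method = method,
                            n_distinct = nrow(agg))
  profile
}

collapse_ties <- function(df) {
  tot <- sort(unique(df$total), decreasing = TRUE)
  idx <- factor(match(df$total, tot), levels = seq_along(tot))
  avg_rank <- as.numeric(tapply(df$rank, idx, mean))
  data.frame(total = tot, avg_rank = avg_rank)
}

#' Retain barcodes called as cells
#'
#' Keeps exactly the barcodes whose total read count is at or above the
#' inflection count ("total read count over the inflection point" read
#' inclusively, so the inflection barcode itself is kept; set
#' `boundary = "strict"` for a strict greater-than rule). The gene set is
#' unchanged.
#'
#' @param matrix Count matrix (genes x barcodes).
#' @param profile A `rank_profile` with inflection filled in.
#' @param boundary `"inclusive"` (default, `>=`) or `"strict"` (`>`).
#' @return The column-subset count matrix of called cells.
#' @export
call_cells <- function(matrix, profile, boundary = c("inclusive", "strict")) {
  boundary <- match.arg(boundary)
  if (is.null(profile$inflection_count)) {
    stop("call_cells: profile has no inflection; run find_inflection() first")
  }
  totals <- Matrix::colSums(matrix)
  keep <- if (boundary == "inclusive") {
    totals >= profile$inflection_count
  } else {
    totals > profile$inflection_count
  }
  matrix[, keep, drop = FALSE]
}

#' Export the rank curve as a plain table
#'
#' One row per barcode: rank, total, and whether the barcode is called at
#' the profile's inflection threshold. Convenient for plotting the knee.
#'
#' @param profile A `rank_profile` (with or without inflection).
#' @return Data frame with columns `rank`, `total`, `barcode`, `called`.
#' @export
rank_curve_table <- function(profile) {
  df <- profile$profile
  df$called <- if (is.null(profile$inflection_count)) NA else
    df$total >= profile$inflection_count
  df[, c("rank", "total", "barcode", "called")]
}
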