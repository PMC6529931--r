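#' @importFrom rlang .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# All genomic intervals in this package are tibbles with at least
# chrom/start/end, 0-based half-open (BED convention). GenomicRanges is
# 1-based closed, so conversion shifts start by +1.

#' Validate an interval tibble
#'
#' Checks the invariants every interval table in the package relies on:
#' `chrom`, `start`, `end` columns present, `start < end`, `start >= 0`,
#' non-empty chromosome names. Coordinates are 0-based half-open.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return `x` as a tibble, invisibly usable downstream.
#' @export
validate_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) stop(arg, " must be a data frame of intervals")
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0) {
    stop(arg, " is missing interval column(s): ", paste(miss, collapse = ", "))
  }
  x <- as_tibble(x)
  if (nrow(x) == 0) return(x)
  if (any(is.na(x$chrom) | !nzchar(as.character(x$chrom)))) {
    stop(arg, ": chromosome names must be non-empty")
  }
  if (any(x$start < 0)) stop(arg, ": start positions must be >= 0")
  if (any(x$start >= x$end)) stop(arg, ": intervals must satisfy start < end")
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> tibble (0-based half-open)
granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

sort_intervals <- function(x) arrange(x, .data$chrom, .data$start, .data$end)

#' Merge overlapping or nearby intervals
#'
#' Produces the non-overlapping union of an interval set. Two intervals are
#' merged when the gap between them is at most `min_gap` bases; touching
#' half-open intervals (gap 0) merge at the default. Total covered bases are
#' unchanged except for bridged gaps.
#'
#' @param x Interval tibble (`chrom`, `start`, `end`; 0-based half-open).
#' @param min_gap Maximum gap, in bp, across which intervals are joined.
#' @return Tibble of merged intervals, sorted by chromosome and start.
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1", start = c(0, 5), end = c(10, 20)))
#' @export
merge_intervals <- function(x, min_gap = 0) {
  x <- validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = min_gap + 1L)
  sort_intervals(granges_to_tbl(gr))
}

#' Base-level consensus across interval sets
#'
#' Returns the maximal merged regions where at least `min_count` of the input
#' sets overlap, counting occupancy per base. Each input set is first merged
#' so a set contributes at most once per base. This is the primitive behind
#' both the PMD consensus ("present in at least half of the samples") and the
#' enhancer consensus ("identified in at least three" samples).
#'
#' @param sets List of interval tibbles.
#' @param min_count Minimum number of sets that must cover a base.
#' @return Tibble of consensus intervals. `min_count` larger than the number
#'   of sets yields an empty set.
#' @export
coverage_consensus <- function(sets, min_count) {
  stopifnot(is.list(sets), length(sets) >= 1, min_count >= 1)
  if (min_count > length(sets)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  pooled_tbl <- bind_rows(lapply(sets, merge_intervals))
  if (nrow(pooled_tbl) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  cov <- GenomicRanges::coverage(as_granges(pooled_tbl))
  hit <- IRanges::slice(cov, lower = min_count, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(hit)
  sort_intervals(granges_to_tbl(gr))
}

# Overlap hits between two interval tibbles; returns tibble(x_idx, y_idx).
interval_hits <- function(x, y, maxgap = -1L) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(x_idx = integer(), y_idx = integer()))
  }
  h <- GenomicRanges::findOverlaps(as_granges(x), as_granges(y), maxgap = maxgap)
  tibble(x_idx = S4Vectors::queryHits(h), y_idx = S4Vectors::subjectHits(h))
}

#' Which intervals of one set overlap another set
#'
#' Row-wise overlap indicator: `TRUE` where an interval of `x` overlaps
#' (>= 1 bp) any interval of `y`.
#'
#' @param x,y Interval tibbles.
#' @return Logical vector of length `nrow(x)`.
#' @export
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(as_granges(x), as_granges(y))
}

#' Total covered bases of an interval set
#'
#' Bases covered by the merged union of `x` (overlaps counted once).
#'
#' @param x Interval tibble.
#' @return Number of covered bases.
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  if (nrow(m) == 0) return(0)
  sum(as.numeric(m$end - m$start))
}

#' Base-level intersection of two interval sets
#'
#' Merged regions covered by both `x` and `y`.
#'
#' @param x,y Interval tibbles.
#' @return Merged interval tibble of the intersection.
#' @export
intersect_intervals <- function(x, y) {
  x <- merge_intervals(x)
  y <- merge_intervals(y)
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::intersect(as_granges(x), as_granges(y))
  sort_intervals(granges_to_tbl(gr))
}

#' Signed distance histogram from anchors to nearest features
#'
#' For each anchor the signed distance to the midpoint of the nearest feature
#' is computed (positive when the feature lies 3' of the anchor) and binned.
#' Anchors whose nearest feature midpoint lies beyond `max_dist` are counted
#' in an overflow row (`bin_start`/`bin_end` = `NA`).
#'
#' @param features Interval tibble; distance is measured to interval midpoints.
#' @param anchors Tibble with columns `chrom` and `position`.
#' @param max_dist Maximum absolute distance covered by the histogram, bp.
#' @param bin Bin width in bp; must divide `max_dist`.
#' @return Tibble with `bin_start`, `bin_end`, `count`; the final row is the
#'   overflow bucket.
#' @export
nearest_distance_histogram <- function(features, anchors, max_dist, bin) {
  stopifnot(max_dist %% bin == 0, nrow(anchors) >= 1)
  features <- validate_intervals(features, "features")
  mids <- features |>
    mutate(mid = (.data$start + .data$end) %/% 2L) |>
    group_by(.data$chrom) |>
    summarise(mids = list(sort(.data$mid)), .groups = "drop")
  mid_map <- stats::setNames(mids$mids, mids$chrom)

  dist <- vapply(seq_len(nrow(anchors)), function(i) {
    m <- mid_map[[as.character(anchors$chrom[i])]]
    if (is.null(m) || length(m) == 0) return(NA_real_)
    p <- anchors$position[i]
    j <- findInterval(p, m)
    cand <- m[pmax(1L, pmin(length(m), c(j, j + 1L)))]
    d <- cand - p
    d[which.min(abs(d))]
  }, numeric(1))

  edges <- seq(-max_dist, max_dist, by = bin)
  in_range <- !is.na(dist) & abs(dist) <= max_dist
  # right-open bins except the last, which is right-closed at +max_dist
  idx <- pmin(floor((dist[in_range] + max_dist) / bin) + 1L, length(edges) - 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  out <- tibble(
    bin_start = edges[-length(edges)],
    bin_end = edges[-1],
    count = counts
  )
  bind_rows(out, tibble(bin_start = NA, bin_end = NA, count = sum(!in_range)))
}
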