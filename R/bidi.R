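# Detection of bidirectionally transcribed loci (candidate eRNAs) from
# stranded coverage tracks.

# Cumulative integrals of value and position*value for a piecewise-constant
# track on one chromosome; both needed for windowed sums and centroids.
strand_cumulator <- function(segs) {
  segs <- segs[order(segs$start), , drop = FALSE]
  cv <- c(0, cumsum(segs$value * (segs$end - segs$start)))
  cx <- c(0, cumsum(segs$value * (segs$end^2 - segs$start^2) / 2))
  starts <- segs$start; ends <- segs$end; vals <- segs$value
  function(x) {
    j <- findInterval(x, starts)
    jj <- pmax(j, 1L)
    cut <- pmax(starts[jj], pmin(ends[jj], x))
    v <- cv[jj + 1] - vals[jj] * (ends[jj] - cut)
    xv <- cx[jj + 1] - vals[jj] * (ends[jj]^2 - cut^2) / 2
    v[j < 1] <- 0; xv[j < 1] <- 0
    list(v = v, xv = xv)
  }
}

#' Detect bidirectionally transcribed loci
#'
#' Slides a window along each chromosome and calls a window bidirectionally
#' transcribed when (i) the major strand carries at least `min_major_reads`,
#' (ii) the minor strand carries at least `min_minor_ratio` (20%) of the major
#' strand's reads, (iii) the read geometry is divergent - the minus-strand
#' centroid lies at least `min_centroid_sep` bp 5' of the plus-strand centroid
#' and each strand concentrates at least `min_half_fraction` of its reads on
#' its own half of the window - and (iv) the window overlaps no TSS and does
#' not overlap exons on both strands. Overlapping passing windows are merged,
#' with strand read counts and minor ratio recomputed on the union.
#'
#' @param plus,minus Stranded signal tibbles (`chrom`, `start`, `end`,
#'   `value` = reads per interval).
#' @param window Window width, bp.
#' @param step Window step, bp.
#' @param min_minor_ratio Minimum minor/major strand read ratio (inclusive).
#' @param min_major_reads Minimum major-strand reads per window.
#' @param tss Interval tibble of transcription start sites (windows touching
#'   any are excluded); `NULL` disables.
#' @param exons_plus,exons_minus Exon interval tibbles per strand; windows
#'   overlapping exons on both strands are excluded. `NULL` disables.
#' @param min_centroid_sep Minimum 5' offset of the minus centroid vs the plus
#'   centroid, bp (divergence geometry).
#' @param min_half_fraction Minimum fraction of a strand's reads on its own
#'   window half.
#' @return Tibble of merged loci with `plus_reads`, `minus_reads`,
#'   `minor_ratio`.
#' @export
detect_bidirectional <- function(plus, minus, window = 1000, step = 100,
                                 min_minor_ratio = 0.2, min_major_reads = 10,
                                 tss = NULL, exons_plus = NULL,
                                 exons_minus = NULL, min_centroid_sep = 100,
                                 min_half_fraction = 0.6) {
  plus <- validate_intervals(plus, "plus")
  minus <- validate_intervals(minus, "minus")
  chroms <- union(unique(plus$chrom), unique(minus$chrom))
  passing <- bind_rows(lapply(chroms, function(ch) {
    pc <- plus[plus$chrom == ch, ]
    mc <- minus[minus$chrom == ch, ]
    L <- max(c(pc$end, mc$end, window))
    # windows may extend past the last covered base so edge loci are scanned
    starts <- seq(0, L, by = step)
    fp <- if (nrow(pc) > 0) strand_cumulator(pc) else NULL
    fm <- if (nrow(mc) > 0) strand_cumulator(mc) else NULL
    stat <- function(f, a, b) {
      if (is.null(f)) {
        return(list(sum = numeric(length(a)), cen = rep(NA_real_, length(a))))
      }
      ea <- f(a); eb <- f(b)
      s <- eb$v - ea$v
      list(sum = s, cen = ifelse(s > 0, (eb$xv - ea$xv) / s, NA_real_))
    }
    mid <- starts + window / 2
    p_all <- stat(fp, starts, starts + window)
    m_all <- stat(fm, starts, starts + window)
    p_right <- stat(fp, mid, starts + window)
    m_left <- stat(fm, starts, mid)
    major <- pmax(p_all$sum, m_all$sum)
    minor <- pmin(p_all$sum, m_all$sum)
    # ratio comparison (not minor >= ratio*major) so an exactly-20% minor
    # strand passes the inclusive rule without floating-point drift
    ratio <- ifelse(major > 0, minor / major, 0)
    ok <- major >= min_major_reads &
      ratio >= min_minor_ratio &
      !is.na(p_all$cen) & !is.na(m_all$cen) &
      m_all$cen <= p_all$cen - min_centroid_sep &
      p_right$sum >= min_half_fraction * p_all$sum &
      m_left$sum >= min_half_fraction * m_all$sum
    if (!any(ok)) return(NULL)
    tibble(chrom = ch, start = starts[ok], end = starts[ok] + window)
  }))
  if (nrow(passing) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  plus_reads = numeric(), minus_reads = numeric(),
                  minor_ratio = numeric()))
  }
  if (!is.null(tss) && nrow(tss) > 0) {
    passing <- passing[!overlaps_any(passing, tss), ]
  }
  if (!is.null(exons_plus) && !is.null(exons_minus) &&
      nrow(passing) > 0) {
    both <- overlaps_any(passing, exons_plus) &
      overlaps_any(passing, exons_minus)
    passing <- passing[!both, ]
  }
  if (nrow(passing) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  plus_reads = numeric(), minus_reads = numeric(),
                  minor_ratio = numeric()))
  }
  merged <- merge_intervals(passing)
  sum_over <- function(track, iv) {
    cums <- lapply(split(track, track$chrom), strand_cumulator)
    vapply(seq_len(nrow(iv)), function(i) {
      f <- cums[[as.character(iv$chrom[i])]]
      if (is.null(f)) return(0)
      f(iv$end[i])$v - f(iv$start[i])$v
    }, numeric(1))
  }
  merged$plus_reads <- sum_over(plus, merged)
  merged$minus_reads <- sum_over(minus, merged)
  merged$minor_ratio <- with(merged, pmin(plus_reads, minus_reads) /
                               pmax(plus_reads, minus_reads))
  merged
}
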