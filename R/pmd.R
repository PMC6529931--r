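# Partially methylated domain (PMD) calling: sliding-window scan of per-CpG
# beta values, merging of qualifying windows, length filter, gap exclusion,
# and cross-sample consensus.

#' Call partially methylated domains in one methylome
#'
#' Scans each chromosome with a sliding window (10 kb by default, 1-kb step)
#' and retains windows whose mean beta over contained CpGs is below
#' `max_mean_beta` (0.65). Qualifying windows are joined when overlapping or
#' touching, and merged regions of at least `min_length` (100 kb) are called
#' as PMDs. Windows without CpGs never qualify: absence of data is not
#' evidence of hypomethylation. Regions overlapping `gaps` (assembly gaps,
#' centromeres, telomeres) by at least 1 bp are discarded.
#'
#' @param m Methylome tibble (`chrom`, `pos`, `beta`, `coverage`).
#' @param window Sliding window width, bp.
#' @param step Window step, bp (must be <= `window`).
#' @param max_mean_beta Strict upper bound on the window mean beta.
#' @param min_length Minimum merged-region length, bp (inclusive).
#' @param gaps Optional interval tibble of excluded assembly regions.
#' @return Interval tibble of PMDs with `mean_beta`, the mean beta over the
#'   CpGs each region contains.
#' @export
call_pmds <- function(m, window = 10000, step = 1000, max_mean_beta = 0.65,
                      min_length = 100000, gaps = NULL) {
  stopifnot(step <= window, max_mean_beta > 0, max_mean_beta < 1,
            min_length >= window, nrow(m) > 0)
  out <- lapply(split(m, m$chrom), function(mc) {
    mc <- mc[order(mc$pos), ]
    if (nrow(mc) == 0) return(NULL)
    pos <- mc$pos
    cb <- c(0, cumsum(mc$beta))
    starts <- seq(0, max(pos), by = step)
    # CpGs in [s, s+window): cumulative counts at the window edges
    lo <- findInterval(starts - 0.5, pos)
    hi <- findInterval(starts + window - 0.5, pos)
    n <- hi - lo
    mean_beta <- ifelse(n > 0, (cb[hi + 1] - cb[lo + 1]) / n, NA_real_)
    ok <- n > 0 & mean_beta < max_mean_beta
    if (!any(ok)) return(NULL)
    tibble(chrom = mc$chrom[1], start = starts[ok], end = starts[ok] + window)
  })
  qual <- bind_rows(out)
  if (nrow(qual) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  mean_beta = numeric()))
  }
  merged <- merge_intervals(qual) |>
    filter(.data$end - .data$start >= min_length)
  if (!is.null(gaps) && nrow(merged) > 0) {
    merged <- merged[!overlaps_any(merged, gaps), ]
  }
  if (nrow(merged) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  mean_beta = numeric()))
  }
  # per-region mean beta over contained CpGs
  hits <- interval_hits(merged,
                        tibble(chrom = m$chrom, start = m$pos,
                               end = m$pos + 1L))
  mb <- hits |>
    mutate(beta = m$beta[.data$y_idx]) |>
    group_by(.data$x_idx) |>
    summarise(mean_beta = mean(.data$beta), .groups = "drop")
  merged$mean_beta <- NA_real_
  merged$mean_beta[mb$x_idx] <- mb$mean_beta
  merged
}

#' Cross-sample PMD consensus
#'
#' Union of per-sample PMDs present in at least `min_fraction` of the samples
#' (at least half by default, matching the `>= 6` of 11 rule), computed by
#' base-level occupancy counting.
#'
#' @param pmd_sets List of per-sample PMD interval tibbles.
#' @param min_fraction Minimum fraction of samples covering a base; the count
#'   threshold is `ceiling(min_fraction * length(pmd_sets))`.
#' @return Consensus interval tibble.
#' @export
consensus_pmds <- function(pmd_sets, min_fraction = 0.5) {
  stopifnot(length(pmd_sets) >= 1, min_fraction > 0, min_fraction <= 1)
  coverage_consensus(pmd_sets,
                     min_count = ceiling(min_fraction * length(pmd_sets)))
}

#' Signal profiles around PMD boundaries
#'
#' Aggregates one or more signal tracks around PMD boundaries in fixed-width
#' bins (5-kb bins over +/- 50 kb by default), orienting each boundary so the
#' domain interior maps to positive offsets, and normalizing each profile to
#' the mean signal in the flank entirely outside the domain.
#'
#' @param tracks Named list of signal tibbles.
#' @param pmds PMD interval tibble.
#' @param flank Half-width of the profile, bp.
#' @param bin Bin width, bp.
#' @return Tibble of per-track, per-bin profile rows (`track`, `bin`,
#'   `offset_start`, `offset_end`, `mean`, `sd`, `n_anchors`).
#' @export
pmd_boundary_profiles <- function(tracks, pmds, flank = 50000, bin = 5000) {
  pmds <- validate_intervals(pmds, "pmds")
  anchors <- bind_rows(
    tibble(chrom = pmds$chrom, position = pmds$start, orientation = "+"),
    tibble(chrom = pmds$chrom, position = pmds$end, orientation = "-")
  )
  bind_rows(lapply(names(tracks), function(nm) {
    aggregate_around_anchors(tracks[[nm]], anchors, flank = flank, bin = bin,
                             normalize = "flank_outside") |>
      mutate(track = nm, .before = 1)
  }))
}

#' Observed vs expected fraction of point features inside PMDs
#'
#' For a set of point features (e.g. somatic mutations), computes the fraction
#' falling inside PMDs and the fraction expected if features were uniform,
#' i.e. the PMD share of the genome.
#'
#' @param points Tibble with `chrom` and `pos`.
#' @param pmds PMD interval tibble.
#' @param genome_length Total genome length, bp.
#' @return Named list with `observed` and `expected` fractions.
#' @export
feature_in_pmd_fraction <- function(points, pmds, genome_length) {
  pmd_len <- covered_bases(pmds)
  stopifnot(genome_length >= pmd_len)
  if (nrow(points) == 0) {
    warning("empty point list: observed fraction undefined")
    return(list(observed = NA_real_, expected = pmd_len / genome_length))
  }
  pts <- tibble(chrom = points$chrom, start = points$pos,
                end = points$pos + 1L)
  list(observed = mean(overlaps_any(pts, pmds)),
       expected = pmd_len / genome_length)
}
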