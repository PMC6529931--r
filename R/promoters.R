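# Promoter H3K4me3 broadening and nucleosome-gain detection between groups.

#' Build a promoter-by-sample H3K4me3 peak-width table
#'
#' For each promoter and sample, records the width (bp) of the peak
#' overlapping the promoter; when several peaks overlap, the widest is taken.
#' Missing cells mark promoters without a peak in that sample. "Common
#' promoters" - those with a peak in every sample - are the testable universe
#' for [detect_broadened()].
#'
#' @param peaks_per_sample Named list of peak interval tibbles.
#' @param promoters Non-overlapping interval tibble with a `name` column
#'   carrying the gene/promoter id.
#' @return Tibble with `promoter` and one width column per sample.
#' @export
build_width_table <- function(peaks_per_sample, promoters) {
  promoters <- validate_intervals(promoters, "promoters")
  stopifnot(!is.null(names(peaks_per_sample)),
            "name" %in% names(promoters))
  cols <- lapply(names(peaks_per_sample), function(s) {
    peaks <- validate_intervals(peaks_per_sample[[s]], s)
    hits <- interval_hits(promoters, peaks)
    w <- rep(NA_real_, nrow(promoters))
    if (nrow(hits) > 0) {
      best <- hits |>
        mutate(width = peaks$end[.data$y_idx] - peaks$start[.data$y_idx]) |>
        group_by(.data$x_idx) |>
        summarise(width = max(.data$width), .groups = "drop")
      w[best$x_idx] <- best$width
    }
    w
  })
  names(cols) <- names(peaks_per_sample)
  bind_cols(tibble(promoter = promoters$name), as_tibble(cols))
}

#' Detect promoters with broadened H3K4me3 domains
#'
#' Tests, at every common promoter (peak present in all samples), whether the
#' disease group's peak widths are shifted up: a two-sample Wilcoxon rank test
#' must give `p < alpha` and the difference of group medians must be at least
#' `min_median_delta` (400 bp, inclusive).
#'
#' @param widths Width table from [build_width_table()].
#' @param groups Named character vector mapping sample columns to two group
#'   labels; the first label in `unique(groups)` order is the disease group
#'   whose widths are expected to be larger.
#' @param alpha Significance threshold (strict `<`).
#' @param min_median_delta Minimum median width increase, bp (inclusive).
#' @return Tibble of reported promoters with `median_g1`, `median_g2`,
#'   `delta`, `p`.
#' @export
detect_broadened <- function(widths, groups, alpha = 0.05,
                             min_median_delta = 400) {
  samples <- names(groups)
  stopifnot(all(samples %in% names(widths)), length(unique(groups)) == 2)
  g <- unique(groups)
  a <- samples[groups == g[1]]; b <- samples[groups == g[2]]
  stopifnot(length(a) >= 2, length(b) >= 2)
  mat <- as.matrix(widths[, samples])
  common <- rowSums(is.na(mat)) == 0
  res <- purrr::map_dfr(which(common), function(i) {
    wa <- mat[i, a]; wb <- mat[i, b]
    p <- if (all(wa == wa[1]) && all(wb == wb[1]) && wa[1] == wb[1]) {
      1  # degenerate all-equal widths
    } else {
      suppressWarnings(stats::wilcox.test(wa, wb)$p.value)
    }
    tibble(promoter = widths$promoter[i],
           median_g1 = stats::median(wa), median_g2 = stats::median(wb),
           delta = stats::median(wa) - stats::median(wb), p = p)
  })
  if (nrow(res) == 0) {
    return(tibble(promoter = character(), median_g1 = numeric(),
                  median_g2 = numeric(), delta = numeric(), p = numeric()))
  }
  res |> filter(.data$p < alpha, .data$delta >= min_median_delta)
}

#' Detect promoters gaining nucleosomes
#'
#' Computes, per sample, the mean histone-H3 (nucleosome) signal over a
#' fixed window centered on each promoter's TSS after library-size
#' normalization, then applies a one-sided Wilcoxon rank test (disease >
#' control) per promoter. The rank test makes the call invariant to any
#' common rescaling of the tracks.
#'
#' @param h3_tracks Named list of signal tibbles (H3 ChIP coverage).
#' @param promoters Interval tibble with `name` and `strand` columns; the TSS
#'   is the strand-aware 5' end.
#' @param window Window width centered on the TSS, bp.
#' @param groups Named character vector mapping track names to two group
#'   labels (first = disease).
#' @param alpha Significance threshold (strict `<`).
#' @return Tibble of reported promoters with per-group mean occupancy and `p`.
#' @export
detect_nucleosome_gain <- function(h3_tracks, promoters, window = 1000,
                                   groups, alpha = 0.05) {
  promoters <- validate_intervals(promoters, "promoters")
  samples <- names(groups)
  stopifnot(all(samples %in% names(h3_tracks)), length(unique(groups)) == 2)
  if (!"strand" %in% names(promoters)) promoters$strand <- "+"
  tss <- ifelse(promoters$strand == "-", promoters$end, promoters$start)
  anchors <- tibble(chrom = promoters$chrom, position = tss,
                    orientation = "+")
  occ <- vapply(samples, function(s) {
    tr <- h3_tracks[[s]]
    libsize <- sum(tr$value * (tr$end - tr$start))
    tr$value <- tr$value / libsize * 1e6
    prof <- aggregate_around_anchors_per_anchor(tr, anchors,
                                                flank = window / 2)
    prof
  }, numeric(nrow(promoters)))
  g <- unique(groups)
  a <- samples[groups == g[1]]; b <- samples[groups == g[2]]
  res <- purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
    va <- occ[i, a]; vb <- occ[i, b]
    if (all(is.na(va)) || all(is.na(vb))) return(NULL)
    p <- suppressWarnings(
      stats::wilcox.test(va, vb, alternative = "greater")$p.value)
    tibble(promoter = promoters$name[i],
           mean_g1 = mean(va, na.rm = TRUE), mean_g2 = mean(vb, na.rm = TRUE),
           p = p)
  })
  if (nrow(res) == 0) {
    return(tibble(promoter = character(), mean_g1 = numeric(),
                  mean_g2 = numeric(), p = numeric()))
  }
  res |> filter(.data$p < alpha)
}

# Mean signal in [position - flank, position + flank) per anchor (one value
# per anchor, NA when the window has no coverage).
aggregate_around_anchors_per_anchor <- function(track, anchors, flank) {
  cums <- lapply(split(track, track$chrom), track_cumulator)
  vapply(seq_len(nrow(anchors)), function(i) {
    f <- cums[[as.character(anchors$chrom[i])]]
    if (is.null(f)) return(NA_real_)
    ev <- f(c(anchors$position[i] - flank, anchors$position[i] + flank))
    dv <- diff(ev$v); dc <- diff(ev$c)
    if (dc > 0) dv / dc else NA_real_
  }, numeric(1))
}
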