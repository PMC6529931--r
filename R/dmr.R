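# Differentially methylated region (DMR) calling between two groups of
# methylomes, plus the B-cell-maturation filter.

#' Per-CpG two-group methylation test
#'
#' Computes, for every CpG covered in at least two samples of each group, the
#' group difference of mean beta (`delta`, group1 - group2) and a Welch
#' two-sample t-test P-value. This is a deliberately simple location test on
#' beta values; the downstream region chain (significance + length + delta
#' thresholds, maturation filter) is where the calling logic lives.
#'
#' @param group1,group2 Lists of methylome tibbles (group1 = disease by
#'   convention, so hypomethylation in disease gives negative delta).
#' @return Tibble with `chrom`, `pos`, `delta`, `pvalue`, sorted by position.
#' @export
test_cpgs <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  key <- function(m) paste(m$chrom, m$pos)
  gather <- function(tracks) {
    all_keys <- sort(unique(unlist(lapply(tracks, key))))
    mat <- matrix(NA_real_, nrow = length(all_keys), ncol = length(tracks),
                  dimnames = list(all_keys, NULL))
    for (j in seq_along(tracks)) {
      mat[key(tracks[[j]]), j] <- tracks[[j]]$beta
    }
    mat
  }
  m1 <- gather(group1)
  m2 <- gather(group2)
  shared <- intersect(rownames(m1), rownames(m2))
  m1 <- m1[shared, , drop = FALSE]
  m2 <- m2[shared, , drop = FALSE]
  n1 <- rowSums(!is.na(m1)); n2 <- rowSums(!is.na(m2))
  keep <- n1 >= 2 & n2 >= 2
  m1 <- m1[keep, , drop = FALSE]; m2 <- m2[keep, , drop = FALSE]
  n1 <- n1[keep]; n2 <- n2[keep]
  mu1 <- rowMeans(m1, na.rm = TRUE); mu2 <- rowMeans(m2, na.rm = TRUE)
  v1 <- apply(m1, 1, stats::var, na.rm = TRUE)
  v2 <- apply(m2, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v2 / n2
  delta <- mu1 - mu2
  # Welch statistic with a variance floor so constant-beta CpGs stay defined
  se2 <- pmax(se2, 1e-12)
  tstat <- delta / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) +
                   (v2 / n2)^2 / pmax(n2 - 1, 1))
  df[!is.finite(df) | df <= 0] <- n1[!is.finite(df) | df <= 0] +
    n2[!is.finite(df) | df <= 0] - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  ck <- strsplit(rownames(m1), " ", fixed = TRUE)
  tibble(
    chrom = vapply(ck, `[`, "", 1),
    pos = as.numeric(vapply(ck, `[`, "", 2)),
    delta = unname(delta),
    pvalue = unname(p)
  ) |> arrange(.data$chrom, .data$pos)
}

#' Call DMRs from per-CpG statistics
#'
#' Groups runs of consecutive significant CpGs (`pvalue < alpha`, strict) with
#' same-sign delta and inter-CpG gaps at most `max_cpg_gap`, and reports a run
#' as a DMR when its span is at least `min_length` (200 bp) and the absolute
#' mean delta over its CpGs is at least `min_delta` (0.3). Direction is `hypo`
#' when mean delta is negative (disease loses methylation under the
#' group1 - group2 sign convention).
#'
#' @param stats Per-CpG tibble from [test_cpgs()].
#' @param alpha Per-CpG significance threshold (strict `<`).
#' @param min_length Minimum region span, bp (inclusive `>=`).
#' @param min_delta Minimum absolute mean delta (inclusive `>=`).
#' @param max_cpg_gap Maximum distance between consecutive CpGs in a run, bp.
#' @return Tibble of DMRs: `chrom`, `start`, `end`, `mean_delta`, `n_cpgs`,
#'   `direction`.
#' @export
call_dmrs <- function(stats, alpha = 0.05, min_length = 200, min_delta = 0.3,
                      max_cpg_gap = 500) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  mean_delta = numeric(), n_cpgs = integer(),
                  direction = character())
  # runs are consecutive *tested* CpGs: a non-significant CpG between two
  # significant ones breaks the run, as do sign flips and large gaps
  sig <- stats |>
    arrange(.data$chrom, .data$pos) |>
    group_by(.data$chrom) |>
    mutate(
      sig = .data$pvalue < alpha & .data$delta != 0,
      new_run = .data$sig & (
        !dplyr::lag(.data$sig, default = FALSE) |
          .data$pos - dplyr::lag(.data$pos, default = -Inf) > max_cpg_gap |
          sign(.data$delta) != dplyr::lag(sign(.data$delta), default = 0)
      )
    ) |>
    ungroup() |>
    mutate(run = cumsum(.data$new_run)) |>
    filter(.data$sig)
  if (nrow(sig) == 0) return(empty)
  out <- sig |>
    group_by(.data$chrom, .data$run) |>
    summarise(
      start = min(.data$pos), end = max(.data$pos) + 1,
      mean_delta = mean(.data$delta), n_cpgs = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$end - .data$start >= min_length,
           abs(.data$mean_delta) >= min_delta) |>
    mutate(direction = ifelse(.data$mean_delta < 0, "hypo", "hyper")) |>
    select("chrom", "start", "end", "mean_delta", "n_cpgs", "direction") |>
    arrange(.data$chrom, .data$start)
  if (nrow(out) == 0) empty else out
}

#' Filter DMRs that mirror normal B-cell maturation
#'
#' Removes DMRs whose methylation change is similar (absolute difference of
#' deltas below `min_excess`, 0.2 beta by default) to the change seen in the
#' maturation comparison of high-maturity memory B cells vs naive B cells, so
#' that developmental programming is not mistaken for disease-specific change.
#' The maturation delta of a DMR is taken from the maturation region it
#' overlaps most; DMRs without a matching region are treated as maturation
#' delta 0 with a warning.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param maturation Interval tibble with a `mat_delta` column (same
#'   group1 - group2 orientation as the DMR deltas).
#' @param min_excess Minimum absolute difference between DMR delta and
#'   maturation delta for a DMR to be kept (inclusive `>=`).
#' @return Subset of `dmrs` surviving the filter.
#' @export
maturation_filter <- function(dmrs, maturation, min_excess = 0.2) {
  if (nrow(dmrs) == 0) return(dmrs)
  maturation <- validate_intervals(maturation, "maturation")
  hits <- interval_hits(dmrs, maturation)
  mat_delta <- rep(0, nrow(dmrs))
  if (nrow(hits) > 0) {
    best <- hits |>
      mutate(
        ov = pmin(dmrs$end[.data$x_idx], maturation$end[.data$y_idx]) -
          pmax(dmrs$start[.data$x_idx], maturation$start[.data$y_idx])
      ) |>
      group_by(.data$x_idx) |>
      slice_max(.data$ov, n = 1, with_ties = FALSE) |>
      ungroup()
    mat_delta[best$x_idx] <- maturation$mat_delta[best$y_idx]
  }
  if (length(setdiff(seq_len(nrow(dmrs)), hits$x_idx)) > 0) {
    warning("DMR(s) without maturation value: treated as maturation delta 0")
  }
  dmrs[abs(dmrs$mean_delta - mat_delta) >= min_excess, ]
}
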