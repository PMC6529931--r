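# Single-cell ATAC co-accessibility: cell QC, promoter-enhancer candidate
# pairs within 100-kb windows, phi correlations across cells, the
# permutation-derived calling threshold, cross-condition classification and
# rewired-promoter identification.

#' Construct a binary accessibility matrix
#'
#' Container for single-cell accessibility: a binary cells-by-loci matrix plus
#' locus coordinates with roles (promoter or enhancer, gene id for promoters)
#' and per-cell integration counts.
#'
#' @param matrix Binary (0/1) matrix, cells in rows, loci in columns; dense or
#'   `Matrix` sparse.
#' @param loci Interval tibble with `role` (`"promoter"`/`"enhancer"`) and
#'   `gene` columns; a `locus_id` column is added if missing.
#' @param cells Tibble with `cell` ids and integration `count`s; counts
#'   default to the per-cell number of open loci.
#' @return An object of class `acc_matrix`.
#' @export
acc_matrix <- function(matrix, loci, cells = NULL) {
  loci <- validate_intervals(loci, "loci")
  stopifnot(all(c("role", "gene") %in% names(loci)),
            all(loci$role %in% c("promoter", "enhancer")),
            ncol(matrix) == nrow(loci))
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- paste0("loc", seq_len(nrow(loci)))
  }
  if (is.null(cells)) {
    cells <- tibble(cell = paste0("cell", seq_len(nrow(matrix))),
                    count = as.numeric(Matrix::rowSums(matrix)))
  }
  stopifnot(nrow(cells) == nrow(matrix), all(c("cell", "count") %in%
                                               names(cells)))
  structure(list(matrix = matrix, loci = loci, cells = cells),
            class = "acc_matrix")
}

#' @export
print.acc_matrix <- function(x, ...) {
  cat("Binary accessibility matrix:", nrow(x$matrix), "cells x",
      ncol(x$matrix), "loci (", sum(x$loci$role == "promoter"), "promoters,",
      sum(x$loci$role == "enhancer"), "enhancers )\n")
  invisible(x)
}

#' Remove cells with aberrant integration counts
#'
#' Drops cells with very few (below `low_factor` times the mean count) or very
#' frequent (more than `high_sds` population standard deviations above the
#' mean) integrations. Both bounds are computed once on the input matrix, not
#' iterated, so the operation is idempotent.
#'
#' @param m An `acc_matrix`.
#' @param low_factor Lower bound as a multiple of the mean count.
#' @param high_sds Upper bound in population SDs above the mean.
#' @return Filtered `acc_matrix`.
#' @export
qc_cells <- function(m, low_factor = 0.2, high_sds = 3) {
  stopifnot(inherits(m, "acc_matrix"), nrow(m$cells) >= 2)
  counts <- m$cells$count
  mu <- mean(counts)
  sdev <- sqrt(mean((counts - mu)^2))  # population SD
  keep <- counts >= low_factor * mu & counts <= mu + high_sds * sdev
  if (!any(keep)) stop("cell QC removed every cell")
  acc_matrix(m$matrix[keep, , drop = FALSE], m$loci, m$cells[keep, ])
}

#' Candidate promoter-enhancer pairs within the pairing window
#'
#' All same-chromosome promoter-enhancer pairs whose midpoint distance is at
#' most `max_distance` (100 kb, the TAD-sized pairing window).
#' Promoter-promoter and enhancer-enhancer pairs are excluded.
#'
#' @param loci Locus tibble with `role` (and `gene` for promoters).
#' @param max_distance Maximum midpoint distance, bp (inclusive).
#' @return Tibble with promoter/enhancer locus ids, gene, and `distance`.
#' @export
candidate_pairs <- function(loci, max_distance = 100000) {
  loci <- validate_intervals(loci, "loci")
  stopifnot("role" %in% names(loci))
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- paste0("loc", seq_len(nrow(loci)))
  }
  loci$mid <- (loci$start + loci$end) / 2
  prom <- loci[loci$role == "promoter", ]
  enh <- loci[loci$role == "enhancer", ]
  if (nrow(prom) == 0 || nrow(enh) == 0) {
    return(tibble(promoter_id = character(), enhancer_id = character(),
                  gene = character(), chrom = character(),
                  distance = numeric()))
  }
  tidyr::crossing(p = seq_len(nrow(prom)), e = seq_len(nrow(enh))) |>
    filter(prom$chrom[.data$p] == enh$chrom[.data$e]) |>
    mutate(distance = abs(prom$mid[.data$p] - enh$mid[.data$e])) |>
    filter(.data$distance <= max_distance) |>
    transmute(
      promoter_id = prom$locus_id[.data$p],
      enhancer_id = enh$locus_id[.data$e],
      gene = prom$gene[.data$p],
      chrom = prom$chrom[.data$p],
      distance = .data$distance
    )
}

# phi coefficients between promoter and enhancer columns of a binary matrix,
# computed from column sums and cross-products. Returns NA for pairs where a
# column is constant.
phi_for_pairs <- function(mat, pi, ei) {
  n <- nrow(mat)
  cs <- Matrix::colSums(mat)
  p <- cs / n
  n11 <- Matrix::colSums(mat[, pi, drop = FALSE] * mat[, ei, drop = FALSE])
  num <- n11 / n - p[pi] * p[ei]
  den <- sqrt(p[pi] * (1 - p[pi]) * p[ei] * (1 - p[ei]))
  ifelse(den > 0, num / den, NA_real_)
}

#' Co-accessibility correlations for candidate pairs
#'
#' Pearson correlation of the two binary locus columns across cells (the phi
#' coefficient) for each candidate pair. Pairs where either locus is constant
#' (open or closed in every cell) have undefined correlation and are dropped,
#' with the number of skipped pairs reported as a message.
#'
#' @param m An `acc_matrix` (after QC).
#' @param pairs Candidate pair tibble from [candidate_pairs()].
#' @return `pairs` with a `correlation` column, constant-locus pairs removed.
#' @export
pair_correlations <- function(m, pairs) {
  stopifnot(inherits(m, "acc_matrix"))
  if (nrow(pairs) == 0) return(mutate(pairs, correlation = numeric(0)))
  idx <- stats::setNames(seq_len(nrow(m$loci)), m$loci$locus_id)
  phi <- phi_for_pairs(m$matrix, idx[pairs$promoter_id],
                       idx[pairs$enhancer_id])
  skipped <- sum(is.na(phi))
  if (skipped > 0) {
    message(skipped, " pair(s) skipped: constant locus column")
  }
  pairs$correlation <- phi
  pairs[!is.na(phi), ]
}

#' Permutation-derived co-accessibility threshold
#'
#' Estimates the calling threshold from spurious correlations: each
#' permutation independently shuffles every locus column across cells
#' (preserving per-locus open frequencies while destroying all dependence),
#' the candidate-pair correlations are recomputed, and the threshold is the
#' given quantile of the pooled permuted correlations.
#'
#' @param m An `acc_matrix` (after QC).
#' @param pairs Candidate pair tibble.
#' @param n_perm Number of permutations.
#' @param quantile Quantile of the pooled null correlations (type-7).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return The threshold (a single number).
#' @export
permutation_threshold <- function(m, pairs, n_perm = 100, quantile = 0.999,
                                  seed = 1) {
  stopifnot(inherits(m, "acc_matrix"), n_perm >= 10,
            quantile > 0, quantile <= 1, nrow(pairs) > 0)
  idx <- stats::setNames(seq_len(nrow(m$loci)), m$loci$locus_id)
  pi <- idx[pairs$promoter_id]; ei <- idx[pairs$enhancer_id]
  used <- sort(unique(c(pi, ei)))
  dense <- as.matrix(m$matrix[, used, drop = FALSE])
  pi2 <- match(pi, used); ei2 <- match(ei, used)
  n <- nrow(dense)
  withr::with_seed(seed, {
    pooled <- unlist(lapply(seq_len(n_perm), function(k) {
      perm <- apply(dense, 2, function(col) col[sample.int(n)])
      phi <- phi_for_pairs(perm, pi2, ei2)
      phi[!is.na(phi)]
    }))
    stats::quantile(pooled, probs = quantile, names = FALSE)
  })
}

#' Call and classify pairs across two conditions
#'
#' A pair is called in a condition when its correlation is at least that
#' condition's threshold. Called pairs are matched across conditions by
#' identical promoter gene and overlapping (>= 1 bp) enhancer interval, and
#' grouped into disease-only (`C`), control-only (`H`), and shared (`CH`)
#' classes.
#'
#' @param pairs_by_condition Named list with elements `CLL` and `NBC`, each a
#'   pair tibble with `correlation` plus enhancer coordinates (`chrom`,
#'   `e_start`, `e_end`) or an `enhancer_id` resolvable via `loci`.
#' @param thresholds Named numeric vector of per-condition thresholds.
#' @param loci Optional locus tibble used to resolve enhancer coordinates
#'   from `enhancer_id`.
#' @return Tibble of called pairs with a `condition` and a `class` column.
#' @export
call_and_classify <- function(pairs_by_condition, thresholds, loci = NULL) {
  stopifnot(all(c("CLL", "NBC") %in% names(pairs_by_condition)),
            all(c("CLL", "NBC") %in% names(thresholds)))
  resolve <- function(p) {
    if (!all(c("e_start", "e_end") %in% names(p))) {
      stopifnot(!is.null(loci))
      i <- match(p$enhancer_id, loci$locus_id)
      p$e_start <- loci$start[i]; p$e_end <- loci$end[i]
      p$chrom <- loci$chrom[i]
    }
    p
  }
  called <- lapply(c(CLL = "CLL", NBC = "NBC"), function(cond) {
    p <- resolve(pairs_by_condition[[cond]])
    p[p$correlation >= thresholds[[cond]], , drop = FALSE]
  })
  match_other <- function(p, other) {
    # does each called pair have a counterpart: same gene, overlapping enhancer
    if (nrow(p) == 0) return(logical(0))
    if (nrow(other) == 0) return(rep(FALSE, nrow(p)))
    vapply(seq_len(nrow(p)), function(i) {
      o <- other[other$gene == p$gene[i] & other$chrom == p$chrom[i], ]
      any(o$e_start < p$e_end[i] & o$e_end > p$e_start[i])
    }, logical(1))
  }
  in_nbc <- match_other(called$CLL, called$NBC)
  in_cll <- match_other(called$NBC, called$CLL)
  bind_rows(
    called$CLL |> mutate(condition = "CLL",
                         class = c("C", "CH")[in_nbc + 1L]),
    called$NBC |> mutate(condition = "NBC",
                         class = c("H", "CH")[in_cll + 1L])
  )
}

#' Identify rewired promoters
#'
#' Promoters (genes) that share no enhancer between the two conditions but are
#' linked to at least one called enhancer in each: at least one `C` pair, at
#' least one `H` pair, and no `CH` pair.
#'
#' @param classified Classified pair tibble from [call_and_classify()].
#' @return Character vector of rewired promoter gene ids.
#' @export
rewired_promoters <- function(classified) {
  if (nrow(classified) == 0) return(character())
  classified |>
    group_by(.data$gene) |>
    summarise(
      has_c = any(.data$class == "C"),
      has_h = any(.data$class == "H"),
      has_ch = any(.data$class == "CH"),
      .groups = "drop"
    ) |>
    filter(.data$has_c, .data$has_h, !.data$has_ch) |>
    pull(.data$gene)
}
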