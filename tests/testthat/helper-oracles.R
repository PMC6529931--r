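# Brute-force base-level oracles used to check the interval algebra and the
# region callers against an independent computation.

# Logical occupancy vector over [0, L) for a single-chromosome interval table.
base_occupancy <- function(x, L) {
  v <- logical(L)
  for (i in seq_len(nrow(x))) {
    v[seq(x$start[i] + 1, x$end[i])] <- TRUE
  }
  v
}

# Per-base coverage counts across a list of single-chromosome interval tables
# (each set counted at most once per base).
base_counts <- function(sets, L) {
  Reduce(`+`, lapply(sets, function(s) as.integer(base_occupancy(s, L))))
}

# Convert a logical occupancy vector back to 0-based half-open intervals.
occupancy_to_intervals <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(chrom = chrom, start = starts[r$values],
                 end = ends[r$values])
}

# Random single-chromosome interval table.
random_intervals <- function(n, L, max_len = 50) {
  s <- sample.int(L - max_len, n, replace = TRUE) - 1L
  w <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", start = s, end = s + w)
}

# Naive all-placements PMD caller: scans every window start, computes the mean
# beta by direct subsetting, merges qualifying windows by occupancy, applies
# the length filter.
pmd_oracle <- function(m, window = 10000, step = 1000, max_mean_beta = 0.65,
                       min_length = 100000) {
  L <- max(m$pos) + window
  occ <- logical(L)
  for (s in seq(0, max(m$pos), by = step)) {
    b <- m$beta[m$pos >= s & m$pos < s + window]
    if (length(b) > 0 && mean(b) < max_mean_beta) {
      occ[seq(s + 1, s + window)] <- TRUE
    }
  }
  iv <- occupancy_to_intervals(occ, chrom = m$chrom[1])
  iv[iv$end - iv$start >= min_length, ]
}

# Base-level recall/precision of called vs planted regions (one chromosome).
region_recall_precision <- function(called, planted, L) {
  vc <- base_occupancy(called, L)
  vp <- base_occupancy(planted, L)
  list(recall = sum(vc & vp) / sum(vp),
       precision = sum(vc & vp) / sum(vc))
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(k)])
  combs <- utils::combn(n, k)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# Independent classifier for C/H/CH pair classes on small instances.
classify_oracle <- function(cll, nbc, thr_cll, thr_nbc) {
  called_cll <- cll[cll$correlation >= thr_cll, ]
  called_nbc <- nbc[nbc$correlation >= thr_nbc, ]
  ov <- function(p, q) p$e_start < q$e_end & p$e_end > q$e_start
  lab <- function(called, other) {
    if (nrow(called) == 0) return(character())
    vapply(seq_len(nrow(called)), function(i) {
      hit <- FALSE
      for (j in seq_len(nrow(other))) {
        if (called$gene[i] == other$gene[j] &&
            called$chrom[i] == other$chrom[j] &&
            ov(called[i, ], other[j, ])) hit <- TRUE
      }
      if (hit) "CH" else NA_character_
    }, character(1))
  }
  cl_c <- lab(called_cll, called_nbc)
  cl_h <- lab(called_nbc, called_cll)
  cl_c[is.na(cl_c)] <- "C"
  cl_h[is.na(cl_h)] <- "H"
  dplyr::bind_rows(
    dplyr::mutate(called_cll, condition = "CLL", class = cl_c),
    dplyr::mutate(called_nbc, condition = "NBC", class = cl_h)
  )
}
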