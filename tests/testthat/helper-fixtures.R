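# Shared fixtures: hand-constructed mixture fits, accessibility matrices and
# toy networks used by several test files.

manual_fit <- function(weights, means, sds) {
  structure(list(weights = weights, means = means, sds = sds,
                 loglik = 0, n_iter = 1, converged = TRUE, n = 0),
            class = "mixfit3")
}

# fine-grid intersection of two weighted component densities
grid_crossing <- function(w1, m1, s1, w2, m2, s2) {
  g <- seq(m1, m2, length.out = 2e6)
  d <- w1 * stats::dnorm(g, m1, s1) - w2 * stats::dnorm(g, m2, s2)
  i <- which(diff(sign(d)) != 0)[1]
  lo <- g[i]; hi <- g[i + 1]
  f <- function(x) w1 * stats::dnorm(x, m1, s1) - w2 * stats::dnorm(x, m2, s2)
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

toy_matrix <- function(counts, n_loci = 20) {
  # cells with prescribed integration counts (first `count` loci open)
  m <- t(vapply(counts, function(k) {
    as.numeric(seq_len(n_loci) <= k)
  }, numeric(n_loci)))
  loci <- tibble::tibble(chrom = "chr1",
                         start = seq(0, by = 200000, length.out = n_loci),
                         end = seq(0, by = 200000, length.out = n_loci) + 500,
                         role = rep(c("promoter", "enhancer"),
                                    length.out = n_loci),
                         gene = paste0("G", seq_len(n_loci)))
  acc_matrix(m, loci, tibble::tibble(cell = paste0("c", seq_along(counts)),
                                     count = counts))
}

pair_row <- function(gene, e_start, e_end, cond, class, chrom = "chr1") {
  tibble::tibble(gene = gene, chrom = chrom, e_start = e_start,
                 e_end = e_end, correlation = 0.5, condition = cond,
                 class = class)
}

toy_gren <- function() {
  edges <- tibble::tibble(
    regulator = c("TF1", "TF1", "TF2", "TF2"),
    target = c("GA", "GB", "GB", "GC")
  )
  pairs <- dplyr::bind_rows(
    pair_row("GA", 0, 1000, "CLL", "C"),
    pair_row("GB", 5000, 6000, "NBC", "H"),
    pair_row("GX", 9000, 9500, "CLL", "C")  # gene not in the network
  )
  dd <- dedup_enhancers(pairs)
  numbered <- number_enhancers(dd$enhancers)
  list(edges = edges, numbered = numbered, pairs = dd$pairs)
}
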