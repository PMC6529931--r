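make_methylome <- function(blocks, L, spacing = 100, beta_bg = 0.90,
                           beta_in = 0.30) {
  pos <- seq(0, L - 1, by = spacing)
  beta <- rep(beta_bg, length(pos))
  for (b in blocks) {
    beta[pos >= b[1] & pos < b[2]] <- beta_in
  }
  tibble::tibble(chrom = "chr1", pos = pos, beta = beta, coverage = 30)
}

test_that("a 150-kb hypomethylated block is called as one PMD", {
  m <- make_methylome(list(c(400000, 550000)), L = 1e6)
  pmds <- call_pmds(m)
  expect_equal(nrow(pmds), 1)
  expect_lte(abs(pmds$start - 400000), 10000)
  expect_lte(abs(pmds$end - 550000), 10000)
  expect_lt(pmds$mean_beta, 0.65)
})

test_that("blocks below 100 kb and uniform genomes give no PMDs", {
  short <- make_methylome(list(c(400000, 490000)), L = 1e6, beta_in = 0.45)
  expect_equal(nrow(call_pmds(short)), 0)
  expect_equal(nrow(call_pmds(make_methylome(list(), L = 5e5))), 0)
})

test_that("call_pmds matches the naive all-placements window oracle", {
  withr::with_seed(13, {
    # noisy two-block instance so window means hover near the threshold
    m <- make_methylome(list(c(150000, 320000), c(600000, 780000)), L = 1e6)
    m$beta <- pmin(1, pmax(0, m$beta + stats::rnorm(nrow(m), 0, 0.15)))
    got <- call_pmds(m)
    want <- pmd_oracle(m)
    expect_equal(as.data.frame(got[, c("chrom", "start", "end")]),
                 as.data.frame(want))
  })
})

test_that("PMD calls satisfy their own contract on re-scan", {
  g <- gen_methylomes(n_samples = 1, genome_length = 3e6, n_pmds = 4,
                      pmd_length_range = c(150e3, 400e3), seed = 21)
  m <- g$tracks[[1]]
  pmds <- call_pmds(m)
  expect_true(all(pmds$end - pmds$start >= 100000))
  expect_true(all(pmds$mean_beta < 0.65))
})

test_that("raising max_mean_beta never shrinks called coverage", {
  g <- gen_methylomes(n_samples = 1, genome_length = 2e6, n_pmds = 3,
                      pmd_length_range = c(150e3, 300e3),
                      beta_concentration = 6, seed = 22)
  m <- g$tracks[[1]]
  cov <- vapply(c(0.5, 0.65, 0.8), function(th) {
    p <- call_pmds(m, max_mean_beta = th)
    if (nrow(p) == 0) 0 else sum(p$end - p$start)
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("gap regions knock out overlapping PMDs", {
  m <- make_methylome(list(c(200000, 400000)), L = 1e6)
  gaps <- tibble::tibble(chrom = "chr1", start = 250000, end = 251000)
  expect_equal(nrow(call_pmds(m)), 1)
  expect_equal(nrow(call_pmds(m, gaps = gaps)), 0)
})

test_that("consensus threshold matches the at-least-half rule for 11 samples", {
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 200000)
  other <- tibble::tibble(chrom = "chr1", start = 500000, end = 700000)
  six <- c(rep(list(region), 6), rep(list(other), 5))
  five <- c(rep(list(region), 5), rep(list(other), 6))
  expect_equal(nrow(dplyr::filter(consensus_pmds(six), start == 0)), 1)
  expect_equal(nrow(dplyr::filter(consensus_pmds(five), start == 0)), 0)
  # single sample: consensus is the set itself
  expect_equal(consensus_pmds(list(region))[, c("start", "end")],
               tibble::tibble(start = 0L, end = 200000L))
  # disjoint single-sample sets at full agreement: empty
  expect_equal(nrow(consensus_pmds(list(region, other), 1.0)), 0)
  # full-agreement consensus is contained in every input
  sets <- list(tibble::tibble(chrom = "chr1", start = c(0, 300000),
                              end = c(100000, 500000)),
               tibble::tibble(chrom = "chr1", start = 50000, end = 400000))
  cons <- consensus_pmds(sets, 1.0)
  for (s in sets) {
    hits <- nrow(cons) == 0 ||
      all(base_occupancy(cons, 5e5 + 1) <= base_occupancy(s, 5e5 + 1))
    expect_true(hits)
  }
})

test_that("boundary profiles are flat at 1 for a constant track", {
  pmds <- tibble::tibble(chrom = "chr1", start = 200000, end = 500000)
  tracks <- list(h3k9me3 = tibble::tibble(chrom = "chr1", start = 0,
                                          end = 1e6, value = 2))
  prof <- pmd_boundary_profiles(tracks, pmds)
  expect_equal(nrow(prof), 20)
  expect_equal(prof$mean, rep(1, 20))
  expect_equal(unique(prof$track), "h3k9me3")
})

test_that("boundary profiles recover a planted repressive step", {
  pmds <- tibble::tibble(chrom = "chr1", start = 300000, end = 700000)
  track <- tibble::tibble(chrom = "chr1",
                          start = c(0, 300000, 700000),
                          end = c(300000, 700000, 1e6),
                          value = c(1, 3, 1))
  prof <- pmd_boundary_profiles(list(k9 = track), pmds)
  expect_true(all(prof$mean[prof$offset_start >= 0] > 1))
  expect_equal(prof$mean[prof$offset_end <= 0], rep(1, 10))
})

test_that("feature_in_pmd_fraction computes observed and expected shares", {
  pmds <- tibble::tibble(chrom = "chr1", start = 0, end = 500000)
  pts <- tibble::tibble(chrom = "chr1",
                        pos = c(seq(1000, 400000, length.out = 7),
                                seq(600000, 900000, length.out = 3)))
  res <- feature_in_pmd_fraction(pts, pmds, genome_length = 1e6)
  expect_equal(res$observed, 0.7)
  expect_equal(res$expected, 0.5)
  outside <- tibble::tibble(chrom = "chr1", pos = c(600000, 700000))
  expect_equal(feature_in_pmd_fraction(outside, pmds, 1e6)$observed, 0)
  expect_warning(
    res0 <- feature_in_pmd_fraction(tibble::tibble(chrom = character(),
                                                   pos = numeric()),
                                    pmds, 1e6),
    "empty")
  expect_true(is.na(res0$observed))
  # uniform points land inside at the expected rate (binomial tolerance)
  withr::with_seed(5, {
    u <- tibble::tibble(chrom = "chr1", pos = sample.int(1e6, 2000) - 1)
    r <- feature_in_pmd_fraction(u, pmds, 1e6)
    expect_lt(abs(r$observed - r$expected), 3 * sqrt(0.25 / 2000))
  })
})
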