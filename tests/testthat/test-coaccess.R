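test_that("cell QC reproduces the hand-computed bounds", {
  # counts {10,10,10,10,1}: mean 8.2, low bound 1.64 -> the count-1 cell goes
  m1 <- qc_cells(toy_matrix(c(10, 10, 10, 10, 1)))
  expect_equal(m1$cells$count, rep(10, 4))
  # counts {10,10,10,10,100}: mean 28, population sd 36, high bound 136 ->
  # nothing is removed
  m2 <- qc_cells(toy_matrix(c(10, 10, 10, 10, 100)))
  expect_equal(m2$cells$count, c(10, 10, 10, 10, 100))
  # equal counts: nothing removed; QC is idempotent (bounds fixed, not
  # iterated)
  m3 <- qc_cells(toy_matrix(rep(7, 6)))
  expect_equal(nrow(m3$cells), 6)
  expect_equal(qc_cells(m1)$cells, m1$cells)
})

test_that("candidate pairs respect roles and the 100-kb midpoint window", {
  loci <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 50000, 150000), end = c(500, 50500, 150500),
    role = c("promoter", "enhancer", "enhancer"),
    gene = c("G1", NA, NA), locus_id = c("p1", "e1", "e2")
  )
  got <- candidate_pairs(loci)
  expect_equal(nrow(got), 1)  # enhancer at 150 kb is out of range
  expect_equal(got$promoter_id, "p1")
  expect_equal(got$enhancer_id, "e1")
  expect_equal(got$distance, 50000)
  # boundary: exactly 100 kb is included
  loci2 <- loci
  loci2$start[3] <- 100000; loci2$end[3] <- 100500
  expect_equal(nrow(candidate_pairs(loci2)), 2)
  # no enhancers, no pairs
  expect_equal(nrow(candidate_pairs(loci[1, ])), 0)
  # exhaustive check against brute-force enumeration on a random layout
  withr::with_seed(20, {
    n <- 30
    loci3 <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(5e5, n), role = sample(c("promoter", "enhancer"),
                                                n, replace = TRUE)
    ) |>
      dplyr::mutate(end = start + 500, gene = paste0("G", seq_len(n)),
                    locus_id = paste0("L", seq_len(n)))
    got3 <- candidate_pairs(loci3)
    want <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (loci3$role[i] == "promoter" && loci3$role[j] == "enhancer" &&
            loci3$chrom[i] == loci3$chrom[j] &&
            abs((loci3$start[i] + 250) - (loci3$start[j] + 250)) <= 1e5) {
          want <- want + 1
        }
      }
    }
    expect_equal(nrow(got3), want)
  })
})

test_that("pair correlations are the phi coefficient of the 2x2 table", {
  # hand table: n11=40, n10=10, n01=10, n00=40 -> phi = 0.6
  col_a <- c(rep(1, 50), rep(0, 50))
  col_b <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  m <- matrix(c(col_a, col_b, col_a), ncol = 3)
  loci <- tibble::tibble(chrom = "chr1", start = c(0, 10000, 20000),
                         end = c(500, 10500, 20500),
                         role = c("promoter", "enhancer", "enhancer"),
                         gene = c("G1", NA, NA),
                         locus_id = c("p", "e1", "e2"))
  am <- acc_matrix(m, loci)
  pairs <- candidate_pairs(loci)
  got <- pair_correlations(am, pairs)
  expect_equal(got$correlation[got$enhancer_id == "e1"], 0.6)
  # identical columns correlate at exactly 1
  expect_equal(got$correlation[got$enhancer_id == "e2"], 1)
  # a constant column is skipped with a message
  m2 <- m; m2[, 2] <- 1
  am2 <- acc_matrix(m2, loci)
  expect_message(got2 <- pair_correlations(am2, pairs), "constant")
  expect_equal(got2$enhancer_id, "e2")
  # independent columns stay near zero
  withr::with_seed(21, {
    mi <- matrix(stats::rbinom(3000, 1, 0.3), ncol = 3)
    gi <- pair_correlations(acc_matrix(mi, loci), pairs)
    expect_true(all(abs(gi$correlation) < 0.1))
  })
})

test_that("the permutation threshold is deterministic and tracks the null", {
  g <- gen_scatac(n_cells_per_condition = 200, n_promoters = 8,
                  n_enhancers = 32, n_linked_pairs = 0, n_rewired = 0,
                  seed = 30)
  m <- qc_cells(g$matrices$CLL)
  pairs <- candidate_pairs(m$loci)
  t1 <- permutation_threshold(m, pairs, n_perm = 20, seed = 5)
  t2 <- permutation_threshold(m, pairs, n_perm = 20, seed = 5)
  expect_identical(t1, t2)
  # quantile 1 is the maximum pooled null correlation, so nothing exceeds it
  tmax <- permutation_threshold(m, pairs, n_perm = 20, quantile = 1, seed = 5)
  expect_gte(tmax, t1)
  # null threshold is in the ballpark of the binary-correlation null scale
  expect_gt(t1, 0.05)
  expect_lt(t1, 0.5)
})

test_that("classification matches the brute-force oracle on small instances", {
  withr::with_seed(22, {
    for (rep_i in 1:5) {
      mk <- function() {
        n <- 6
        tibble::tibble(
          gene = sample(paste0("G", 1:3), n, replace = TRUE),
          chrom = "chr1",
          e_start = sample(seq(0, 5000, by = 500), n),
          correlation = stats::runif(n, -0.2, 0.6)
        ) |> dplyr::mutate(e_end = e_start + 600)
      }
      cll <- mk(); nbc <- mk()
      got <- call_and_classify(list(CLL = cll, NBC = nbc),
                               c(CLL = 0.22, NBC = 0.25))
      want <- classify_oracle(cll, nbc, 0.22, 0.25)
      key <- function(d) {
        d |> dplyr::arrange(condition, gene, e_start) |>
          dplyr::select(condition, gene, e_start, class)
      }
      expect_equal(as.data.frame(key(got)), as.data.frame(key(want)))
    }
  })
})

test_that("rewired promoters follow the C/H/no-CH set logic", {
  mk_pair <- function(gene, class, cond) {
    tibble::tibble(gene = gene, chrom = "chr1", e_start = 0, e_end = 100,
                   correlation = 0.5, condition = cond, class = class)
  }
  classified <- dplyr::bind_rows(
    mk_pair("G1", "C", "CLL"), mk_pair("G1", "H", "NBC"),        # rewired
    mk_pair("G2", "C", "CLL"), mk_pair("G2", "H", "NBC"),
    mk_pair("G2", "CH", "CLL"),                                   # shares one
    mk_pair("G3", "C", "CLL"),                                    # CLL only
    mk_pair("G4", "H", "NBC")                                     # NBC only
  )
  expect_equal(rewired_promoters(classified), "G1")
  # exhaustive small instances against an independent set-logic oracle
  withr::with_seed(23, {
    for (rep_i in 1:10) {
      cls <- tibble::tibble(
        gene = sample(paste0("G", 1:4), 8, replace = TRUE),
        class = sample(c("C", "H", "CH"), 8, replace = TRUE)
      )
      got <- rewired_promoters(cls)
      want <- sort(Filter(function(g) {
        k <- cls$class[cls$gene == g]
        any(k == "C") && any(k == "H") && !any(k == "CH")
      }, unique(cls$gene)))
      expect_equal(sort(got), want)
    }
  })
})
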