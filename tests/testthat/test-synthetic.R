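test_that("generators are pure functions of their parameters and seed", {
  a <- gen_methylomes(n_samples = 2, genome_length = 1e6, n_pmds = 2,
                      pmd_length_range = c(150e3, 250e3), seed = 5)
  b <- gen_methylomes(n_samples = 2, genome_length = 1e6, n_pmds = 2,
                      pmd_length_range = c(150e3, 250e3), seed = 5)
  expect_identical(a, b)
  expect_identical(gen_fc_mixture(n = 1000, seed = 2),
                   gen_fc_mixture(n = 1000, seed = 2))
  expect_identical(gen_stranded_coverage(n_bidi = 3, n_unidirectional = 3,
                                         seed = 4),
                   gen_stranded_coverage(n_bidi = 3, n_unidirectional = 3,
                                         seed = 4))
  s1 <- gen_scatac(n_cells_per_condition = 50, n_promoters = 4,
                   n_enhancers = 16, seed = 9, n_linked_pairs = 2,
                   n_rewired = 1)
  s2 <- gen_scatac(n_cells_per_condition = 50, n_promoters = 4,
                   n_enhancers = 16, seed = 9, n_linked_pairs = 2,
                   n_rewired = 1)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.matrix(s1$matrices$CLL$matrix),
                   as.matrix(s2$matrices$CLL$matrix))
  expect_identical(gen_grn(seed = 3), gen_grn(seed = 3))
  expect_identical(gen_dmr_scenario(n_dmrs = 5, seed = 6),
                   gen_dmr_scenario(n_dmrs = 5, seed = 6))
})

test_that("planted methylome window means bracket the PMD threshold", {
  g <- gen_methylomes(n_samples = 1, genome_length = 2e6, cpg_spacing = 100,
                      n_pmds = 3, pmd_length_range = c(150e3, 300e3),
                      beta_in_mean = 0.45, beta_out_mean = 0.85, seed = 2)
  m <- g$tracks[[1]]
  pmds <- g$truth$pmds
  inside <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(pmds))) {
    inside[m$pos >= pmds$start[i] & m$pos < pmds$end[i]] <- TRUE
  }
  # 10-kb windows fully inside / fully outside land on opposite sides of 0.65
  win_means <- function(lo, hi) {
    starts <- seq(lo, hi - 10000, by = 10000)
    vapply(starts, function(s) {
      mean(m$beta[m$pos >= s & m$pos < s + 10000])
    }, numeric(1))
  }
  for (i in seq_len(nrow(pmds))) {
    expect_true(all(win_means(pmds$start[i], pmds$end[i]) < 0.65))
  }
  expect_true(all(win_means(0, pmds$start[1]) > 0.65))
})

test_that("a PMD-free genome has no hypomethylated windows", {
  g <- gen_methylomes(n_samples = 1, genome_length = 5e5, n_pmds = 0, seed = 3)
  m <- g$tracks[[1]]
  starts <- seq(0, max(m$pos) - 10000, by = 1000)
  means <- vapply(starts, function(s) {
    mean(m$beta[m$pos >= s & m$pos < s + 10000])
  }, numeric(1))
  expect_true(all(means > 0.65))
})

test_that("over-full genomes are rejected", {
  expect_error(gen_methylomes(n_samples = 1, genome_length = 1e6, n_pmds = 10,
                              pmd_length_range = c(150e3, 200e3), seed = 1),
               "capacity")
})

test_that("fc mixture generator respects degenerate and symmetric settings", {
  one <- gen_fc_mixture(weights = c(1, 0, 0) + c(0, 1e-12, 1e-12),
                        means = c(0, 5, 10), sds = c(1, 1, 1),
                        n = 5000, seed = 1)
  expect_lt(abs(mean(one$values)), 0.1)
  expect_lt(abs(stats::sd(one$values) - 1), 0.1)
  sym <- gen_fc_mixture(n = 50000, seed = 2)
  expect_lt(abs(mean(sym$values)), 0.02)   # symmetric components center at 0
  expect_equal(unname(sym$truth$crossovers["upper"]),
               -unname(sym$truth$crossovers["lower"]), tolerance = 1e-9)
})

test_that("planted scATAC structure behaves as designed", {
  g <- gen_scatac(n_cells_per_condition = 300, n_promoters = 6,
                  n_enhancers = 24, n_linked_pairs = 3, n_rewired = 0,
                  seed = 4)
  m <- g$matrices$CLL
  counts <- m$cells$count
  mu <- mean(counts); sdev <- sqrt(mean((counts - mu)^2))
  fail <- m$cells$cell %in% g$truth$qc_fail_cells
  outside <- counts < 0.2 * mu | counts > mu + 3 * sdev
  expect_true(all(outside[fail]))       # planted QC cells are outside bounds
  expect_true(mean(outside[!fail]) < 0.02)

  # unlinked loci are uncorrelated; planted pairs have elevated phi that
  # grows with the co-open boost
  phi_of <- function(boost) {
    gg <- gen_scatac(n_cells_per_condition = 400, n_promoters = 6,
                     n_enhancers = 24, n_linked_pairs = 3, n_rewired = 0,
                     co_open_boost = boost, seed = 5)
    mm <- qc_cells(gg$matrices$CLL)
    lk <- gg$truth$links[gg$truth$links$condition == "CLL", ]
    pr <- candidate_pairs(mm$loci)
    pc <- pair_correlations(mm, pr)
    planted <- paste(lk$promoter_id, lk$enhancer_id)
    idx <- paste(pc$promoter_id, pc$enhancer_id) %in% planted
    list(planted = mean(pc$correlation[idx]),
         null = mean(abs(pc$correlation[!idx])))
  }
  lo <- phi_of(0.3); hi <- phi_of(0.6)
  expect_lt(lo$null, 0.1)
  expect_gt(hi$planted, lo$planted)   # monotone in the boost
  expect_gt(lo$planted, 0.05)
})

test_that("grn generator plants detectable deregulation and clean nulls", {
  g <- gen_grn(n_deregulated = 5, seed = 7)
  sel <- select_deregulated_genes(g$de_table)
  expect_true(all(g$truth$deregulated_genes %in% sel))
  act <- differential_activity(g$activity, g$groups)
  regs <- select_differential_regulators(act)
  expect_true(all(g$truth$deregulated_regulators %in% regs))
  # BH keeps false selections rare but not impossible at this scale
  expect_lte(length(setdiff(regs, g$truth$deregulated_regulators)), 2)

  g0 <- gen_grn(n_deregulated = 0, seed = 8)
  act0 <- differential_activity(g0$activity, g0$groups)
  expect_lte(length(select_differential_regulators(act0)),
             ceiling(0.05 * nrow(act0)))
  expect_length(g0$truth$deregulated_genes, 0)
})

test_that("dmr scenario maturation fractions hit both extremes", {
  none <- gen_dmr_scenario(n_dmrs = 10, maturation_overlap_fraction = 0,
                           seed = 2)
  all_f <- gen_dmr_scenario(n_dmrs = 10, maturation_overlap_fraction = 1,
                            seed = 2)
  as_dmr <- function(truth) {
    tibble::tibble(chrom = truth$planted$chrom, start = truth$planted$start,
                   end = truth$planted$end,
                   mean_delta = truth$planted$delta)
  }
  expect_equal(nrow(maturation_filter(as_dmr(none$truth), none$maturation)),
               10)
  expect_equal(nrow(maturation_filter(as_dmr(all_f$truth), all_f$maturation)),
               0)
})
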