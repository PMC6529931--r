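# End-to-end synthetic pipeline: generates every input with seeded generators
# and runs each caller, returning all intermediate and final results. Used to
# check end-to-end determinism and as a worked example of the full analysis.

#' Run the full pipeline on synthetic data
#'
#' Chains all stages on seeded synthetic inputs: PMD calling and consensus,
#' the DMR chain with maturation filter, mixture-derived fold-change
#' thresholds and the FDR inflection, bidirectional-locus detection, active
#' enhancer consensus, single-cell co-accessibility wiring with
#' permutation-calibrated thresholds and rewired-promoter calling, and GREN
#' assembly and disease-subnetwork extraction. Problem sizes are desk-scale;
#' rerunning with the same seed reproduces every output identically.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return Named list of all stage outputs and the generator truths.
#' @export
run_synthetic_pipeline <- function(seed = 1) {
  seeds <- seed + 0:9

  # methylation: PMDs per sample and consensus
  meth <- gen_methylomes(n_samples = 5, genome_length = 6e6,
                         cpg_spacing = 200, n_pmds = 5,
                         pmd_length_range = c(150e3, 500e3),
                         shared_fraction = 0.6, seed = seeds[1])
  pmd_sets <- lapply(meth$tracks, call_pmds)
  pmd_cons <- consensus_pmds(pmd_sets, min_fraction = 0.5)

  # DMR chain
  dmr_sc <- gen_dmr_scenario(n_per_group = 6, n_dmrs = 20, delta = 0.4,
                             maturation_overlap_fraction = 0.25,
                             seed = seeds[2])
  cpg_stats <- test_cpgs(dmr_sc$group1, dmr_sc$group2)
  dmrs <- call_dmrs(cpg_stats)
  dmrs_filtered <- maturation_filter(dmrs, dmr_sc$maturation)

  # fold-change thresholds
  fc <- gen_fc_mixture(n = 20000, seed = seeds[3])
  fit <- fit_three_gaussians(fc$values, seed = seeds[3])
  thresholds_fc <- crossover_points(fit)
  q <- withr::with_seed(seeds[4], c(stats::runif(400, 0, 0.01),
                                    stats::runif(600, 0, 1)))
  fdr_cut <- fdr_inflection(q)

  # bidirectional transcription
  bidi_sc <- gen_stranded_coverage(n_bidi = 15, n_unidirectional = 15,
                                   seed = seeds[5])
  bidi <- detect_bidirectional(bidi_sc$plus, bidi_sc$minus,
                               tss = bidi_sc$tss,
                               exons_plus = bidi_sc$exons_plus,
                               exons_minus = bidi_sc$exons_minus)

  # single-cell co-accessibility wiring
  sc <- gen_scatac(n_cells_per_condition = 400, n_promoters = 20,
                   n_enhancers = 80, n_linked_pairs = 10, n_rewired = 4,
                   seed = seeds[6])
  wire <- lapply(sc$matrices, function(m) {
    mq <- qc_cells(m)
    pr <- candidate_pairs(mq$loci)
    pair_correlations(mq, pr)
  })
  thr <- vapply(names(sc$matrices), function(cond) {
    mq <- qc_cells(sc$matrices[[cond]])
    permutation_threshold(mq, candidate_pairs(mq$loci), n_perm = 50,
                          seed = seeds[7])
  }, numeric(1))
  classified <- call_and_classify(wire, thr, loci = sc$truth$loci)
  rewired <- rewired_promoters(classified)

  # enhancer consensus around the single-cell enhancer loci
  enh_loci <- sc$truth$loci |> filter(.data$role == "enhancer")
  states <- tibble(chrom = enh_loci$chrom,
                   start = pmax(0, enh_loci$start - 500),
                   end = enh_loci$end + 500, state = 9L)
  tss <- sc$truth$loci |> filter(.data$role == "promoter")
  per_sample <- withr::with_seed(seeds[8], lapply(1:4, function(i) {
    keep <- stats::runif(nrow(enh_loci)) < 0.8
    active_enhancers(enh_loci[keep, ], states, tss = tss)
  }))
  enh_cons <- consensus_enhancers(per_sample[1:3], per_sample[4],
                                  evidence = "atac", min_cll = 2)

  # GREN
  grn <- gen_grn(seed = seeds[9])
  act <- differential_activity(grn$activity, grn$groups)
  regs_sel <- select_differential_regulators(act)
  genes_sel <- select_deregulated_genes(grn$de_table)
  dedup <- dedup_enhancers(classified)
  numbered <- number_enhancers(dedup$enhancers)
  # wire the synthetic enhancer-gene links onto the generated network's genes
  gene_map <- stats::setNames(
    sample_gene_map(unique(dedup$pairs$gene), grn$edges$target, seeds[10]),
    unique(dedup$pairs$gene))
  pairs_mapped <- dedup$pairs |>
    mutate(gene = unname(gene_map[.data$gene]))
  gren <- assemble_gren(grn$edges, numbered, pairs_mapped,
                        modifier_list = utils::head(grn$edges$target, 3))
  sub <- extract_disease_subnetwork(
    gren, core_tfs = grn$truth$deregulated_regulators,
    deregulated_genes = genes_sel,
    selected_modifiers = utils::head(grn$edges$target, 3))

  list(
    pmds = pmd_sets, pmd_consensus = pmd_cons, pmd_truth = meth$truth,
    cpg_stats = cpg_stats, dmrs = dmrs, dmrs_filtered = dmrs_filtered,
    dmr_truth = dmr_sc$truth,
    mixture_fit = fit, fc_thresholds = thresholds_fc, fdr_cut = fdr_cut,
    bidi = bidi, bidi_truth = bidi_sc$truth,
    pair_correlations = wire, wiring_thresholds = thr,
    classified_pairs = classified, rewired = rewired, scatac_truth = sc$truth,
    enhancer_consensus = enh_cons,
    regulators_selected = regs_sel, genes_selected = genes_sel,
    gren = gren, disease_subnetwork = sub, grn_truth = grn$truth
  )
}

# deterministic assignment of synthetic promoter genes to network genes
sample_gene_map <- function(from, universe, seed) {
  withr::with_seed(seed, sample(unique(universe), length(from)))
}
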