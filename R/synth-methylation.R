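# Seeded generators for methylome scenarios: genomes with planted partially
# methylated domains (PMDs) and two-group scenarios with planted DMRs plus a
# B-cell-maturation reference. Every generator is a pure function of its
# parameters and seed; the returned truth suffices to score any caller.

rbeta_mean <- function(n, mean, concentration) {
  stats::rbeta(n, shape1 = mean * concentration,
               shape2 = (1 - mean) * concentration)
}

# Place n non-overlapping intervals of the given lengths on [0, genome_length)
# with at least min_gap between them (and to both ends), spreading the slack
# randomly. Positions snapped to `snap`.
place_intervals <- function(lengths, genome_length, min_gap, snap = 1) {
  n <- length(lengths)
  slack <- genome_length - sum(lengths) - (n + 1) * min_gap
  if (slack < 0) {
    stop("planted regions exceed genome capacity: need ",
         sum(lengths) + (n + 1) * min_gap, " bp, have ", genome_length)
  }
  w <- stats::rexp(n + 1)
  gaps <- min_gap + slack * w / sum(w)
  starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, lengths[-n]))
  starts <- floor(starts / snap) * snap
  tibble(start = as.integer(starts), end = as.integer(starts + lengths))
}

#' Generate multi-sample methylomes with planted PMDs
#'
#' Simulates per-CpG methylation (beta) tracks for several samples on one
#' synthetic chromosome, with hypomethylated blocks planted as PMDs. Betas are
#' drawn from Beta distributions parameterized by mean and concentration
#' (bounded in \[0,1\], matching WGBS marginals). A fraction of the planted
#' PMDs is shared by all samples; the rest appear in random sample subsets.
#' PMD lengths are drawn log-uniformly over `pmd_length_range` so that
#' many domains spanning a wide length range fit a desk-scale genome.
#'
#' @param n_samples Number of samples (defaults to the 11-sample cohort scale
#'   the consensus rule assumes).
#' @param genome_length Length of the single synthetic chromosome, bp.
#' @param cpg_spacing Distance between consecutive CpGs, bp.
#' @param n_pmds Number of planted PMDs.
#' @param pmd_length_range Length range (min, max) of planted PMDs, bp;
#'   minimum must be >= 100,000 so planted domains are callable.
#' @param beta_in_mean,beta_out_mean Mean beta inside / outside PMDs; must
#'   bracket the 0.65 calling threshold.
#' @param beta_concentration Beta-distribution concentration (higher = less
#'   per-CpG noise).
#' @param shared_fraction Fraction of PMDs planted in every sample.
#' @param coverage_mean Mean sequencing coverage per CpG.
#' @param seed Integer seed; identical seeds reproduce outputs bit-identically.
#' @return List with `tracks` (named list of methylome tibbles) and `truth`
#'   (planted PMDs, per-sample membership, parameters).
#' @export
gen_methylomes <- function(n_samples = 11, genome_length = 20e6,
                           cpg_spacing = 100, n_pmds = 15,
                           pmd_length_range = c(150e3, 2e6),
                           beta_in_mean = 0.45, beta_out_mean = 0.85,
                           beta_concentration = 15, shared_fraction = 0.6,
                           coverage_mean = 30, seed = 1) {
  stopifnot(beta_in_mean < 0.65, beta_out_mean > 0.65,
            n_pmds >= 0, n_samples >= 1)
  if (n_pmds > 0 && pmd_length_range[1] < 100e3) {
    stop("pmd_length_range minimum must be >= 100,000 bp")
  }
  withr::with_seed(seed, {
    if (n_pmds > 0) {
      lens <- exp(stats::runif(n_pmds, log(pmd_length_range[1]),
                               log(pmd_length_range[2])))
      lens <- round(lens / cpg_spacing) * cpg_spacing
      pmds <- place_intervals(lens, genome_length, min_gap = 50e3,
                              snap = cpg_spacing)
      pmds <- tibble(chrom = "chr1", start = pmds$start, end = pmds$end,
                     pmd_id = paste0("PMD", seq_len(n_pmds)))
    } else {
      pmds <- tibble(chrom = character(), start = integer(), end = integer(),
                     pmd_id = character())
    }
    n_shared <- round(shared_fraction * n_pmds)
    membership <- matrix(FALSE, nrow = n_pmds, ncol = n_samples)
    if (n_pmds > 0) {
      shared_idx <- seq_len(n_shared)
      membership[shared_idx, ] <- TRUE
      for (i in setdiff(seq_len(n_pmds), shared_idx)) {
        take <- stats::runif(n_samples) < 0.5
        if (!any(take)) take[sample.int(n_samples, 1)] <- TRUE
        membership[i, take] <- TRUE
      }
    }
    pos <- seq(0L, as.integer(genome_length) - 1L, by = as.integer(cpg_spacing))
    tracks <- list()
    for (s in seq_len(n_samples)) {
      inside <- rep(FALSE, length(pos))
      if (n_pmds > 0) {
        for (i in which(membership[, s])) {
          inside[pos >= pmds$start[i] & pos < pmds$end[i]] <- TRUE
        }
      }
      beta <- numeric(length(pos))
      beta[inside] <- rbeta_mean(sum(inside), beta_in_mean, beta_concentration)
      beta[!inside] <- rbeta_mean(sum(!inside), beta_out_mean,
                                  beta_concentration)
      tracks[[paste0("S", s)]] <- tibble(
        chrom = "chr1", pos = pos, beta = beta,
        coverage = 5L + stats::rpois(length(pos), coverage_mean - 5)
      )
    }
    truth <- list(
      scenario = "methylomes", pmds = pmds,
      membership = membership,
      params = list(n_samples = n_samples, genome_length = genome_length,
                    cpg_spacing = cpg_spacing,
                    beta_in_mean = beta_in_mean, beta_out_mean = beta_out_mean,
                    beta_concentration = beta_concentration,
                    shared_fraction = shared_fraction),
      seed = seed
    )
    list(tracks = tracks, truth = truth)
  })
}

#' Generate a two-group DMR scenario with a maturation reference
#'
#' Simulates methylomes for a disease and a control group with planted
#' differentially methylated regions (group-mean beta difference = `delta`,
#' random sign per region), plus a maturation-delta table in which a stated
#' fraction of the planted DMRs carries a matching B-cell-maturation change,
#' making them removable by the maturation filter.
#'
#' @param n_per_group Samples per group.
#' @param n_dmrs Number of planted DMRs.
#' @param delta Planted absolute group difference in mean beta (>= 0.3 so
#'   planted regions are callable at the standard threshold).
#' @param maturation_overlap_fraction Fraction of planted DMRs whose
#'   maturation delta equals the planted delta (hence filterable).
#' @param genome_length,cpg_spacing Synthetic chromosome geometry, bp.
#' @param dmr_length_range Planted DMR length range, bp.
#' @param beta_base Background mean beta in both groups.
#' @param beta_concentration Beta-distribution concentration.
#' @param coverage_mean Mean sequencing coverage per CpG.
#' @param seed Integer seed.
#' @return List with `group1` / `group2` (lists of methylome tibbles),
#'   `maturation` (region table with `mat_delta`), and `truth`.
#' @export
gen_dmr_scenario <- function(n_per_group = 6, n_dmrs = 40, delta = 0.4,
                             maturation_overlap_fraction = 0.25,
                             genome_length = 2e6, cpg_spacing = 50,
                             dmr_length_range = c(400, 1500),
                             beta_base = 0.55, beta_concentration = 60,
                             coverage_mean = 30, seed = 1) {
  stopifnot(delta >= 0.3, n_per_group >= 2)
  withr::with_seed(seed, {
    lens <- round(stats::runif(n_dmrs, dmr_length_range[1],
                               dmr_length_range[2]) / cpg_spacing) * cpg_spacing
    regs <- place_intervals(lens, genome_length, min_gap = 5000,
                            snap = cpg_spacing)
    sign <- sample(c(-1, 1), n_dmrs, replace = TRUE)
    # group1 (disease) mean inside region i is beta_base + sign*delta,
    # bounded away from 0/1 for the Beta parameterization
    mean_in <- pmin(0.97, pmax(0.03, beta_base + sign * delta))
    planted <- tibble(
      chrom = "chr1", start = regs$start, end = regs$end,
      dmr_id = paste0("DMR", seq_len(n_dmrs)),
      delta = mean_in - beta_base,  # group1 - group2 sign convention
      filterable = seq_len(n_dmrs) %in%
        sample.int(n_dmrs, round(maturation_overlap_fraction * n_dmrs))
    )
    pos <- seq(0L, as.integer(genome_length) - 1L, by = as.integer(cpg_spacing))
    region_of <- rep(0L, length(pos))
    for (i in seq_len(n_dmrs)) {
      region_of[pos >= planted$start[i] & pos < planted$end[i]] <- i
    }
    make_track <- function(mean_by_region) {
      mu <- ifelse(region_of > 0, mean_by_region[pmax(region_of, 1L)],
                   beta_base)
      tibble(
        chrom = "chr1", pos = pos,
        beta = rbeta_mean(length(pos), mu, beta_concentration),
        coverage = 5L + stats::rpois(length(pos), coverage_mean - 5)
      )
    }
    group1 <- lapply(seq_len(n_per_group),
                     function(i) make_track(mean_in))
    group2 <- lapply(seq_len(n_per_group),
                     function(i) make_track(rep(beta_base, n_dmrs)))
    names(group1) <- paste0("D", seq_len(n_per_group))
    names(group2) <- paste0("C", seq_len(n_per_group))
    maturation <- tibble(
      chrom = planted$chrom, start = planted$start, end = planted$end,
      mat_delta = ifelse(planted$filterable, planted$delta, 0)
    )
    truth <- list(scenario = "dmr", planted = planted,
                  params = list(n_per_group = n_per_group, delta = delta,
                                beta_base = beta_base,
                                beta_concentration = beta_concentration),
                  seed = seed)
    list(group1 = group1, group2 = group2, maturation = maturation,
         truth = truth)
  })
}
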