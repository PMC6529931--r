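# Generator for a small regulator-target network with group-shifted regulator
# activities and differentially expressed target genes.

#' Generate a regulator-target network scenario
#'
#' Produces a regulator-to-target edge list, per-sample activity and
#' expression tables for two groups, and a differential-expression table.
#' Deregulated regulators carry a group shift in activity; deregulated target
#' genes carry a log2 fold change of magnitude `lfc_magnitude` (random sign)
#' with noise small enough that the planted genes clear the standard
#' `P < 0.01`, `|LFC| > 1.7` gate at the stated sample size.
#'
#' @param n_regulators Number of regulators.
#' @param targets_per_regulator Targets sampled per regulator (with sharing).
#' @param n_deregulated Number of regulators with shifted activity; three
#'   target genes per deregulated regulator are planted as deregulated.
#' @param lfc_magnitude Planted absolute log2 fold change of deregulated genes.
#' @param n_samples_per_group Samples per group.
#' @param activity_shift Group shift of deregulated regulator activity (SD
#'   units).
#' @param noise_sd Per-sample expression noise SD (log2 scale).
#' @param seed Integer seed.
#' @return List with `edges`, `activity` (regulator x sample tibble),
#'   `expression` (gene x sample tibble), `de_table` (gene, lfc, p), `groups`
#'   (sample -> group labels), and `truth`.
#' @export
gen_grn <- function(n_regulators = 30, targets_per_regulator = 15,
                    n_deregulated = 8, lfc_magnitude = 2.5,
                    n_samples_per_group = 5, activity_shift = 3,
                    noise_sd = 0.25, seed = 1) {
  withr::with_seed(seed, {
    regulators <- paste0("TF", seq_len(n_regulators))
    n_genes <- max(2 * targets_per_regulator,
                   round(n_regulators * targets_per_regulator / 2))
    genes <- paste0("G", seq_len(n_genes))
    edges <- bind_rows(lapply(regulators, function(r) {
      tibble(regulator = r,
             target = sample(genes, targets_per_regulator))
    }))
    dereg_regs <- if (n_deregulated > 0) {
      sample(regulators, n_deregulated)
    } else character()
    # three planted deregulated targets per deregulated regulator
    dereg_genes <- unique(unlist(lapply(dereg_regs, function(r) {
      tg <- edges$target[edges$regulator == r]
      sample(tg, min(3, length(tg)))
    })))
    lfc_sign <- stats::setNames(
      sample(c(-1, 1), length(dereg_genes), replace = TRUE), dereg_genes)

    n <- n_samples_per_group
    samples <- c(paste0("CLL", seq_len(n)), paste0("NBC", seq_len(n)))
    groups <- stats::setNames(rep(c("CLL", "NBC"), each = n), samples)

    act <- matrix(stats::rnorm(n_regulators * 2 * n), nrow = n_regulators,
                  dimnames = list(regulators, samples))
    act[dereg_regs, seq_len(n)] <- act[dereg_regs, seq_len(n)] + activity_shift
    activity <- as_tibble(act, rownames = "regulator")

    base <- stats::rnorm(n_genes, 5, 1)
    expr <- matrix(stats::rnorm(n_genes * 2 * n, mean = base, sd = noise_sd),
                   nrow = n_genes, dimnames = list(genes, samples))
    for (g in dereg_genes) {
      expr[g, seq_len(n)] <- expr[g, seq_len(n)] + lfc_sign[g] * lfc_magnitude
    }
    expression <- as_tibble(expr, rownames = "gene")

    de_table <- tibble(
      gene = genes,
      lfc = rowMeans(expr[, seq_len(n), drop = FALSE]) -
        rowMeans(expr[, n + seq_len(n), drop = FALSE]),
      p = apply(expr, 1, function(v) {
        stats::t.test(v[seq_len(n)], v[n + seq_len(n)])$p.value
      })
    )
    truth <- list(scenario = "grn",
                  deregulated_regulators = dereg_regs,
                  deregulated_genes = dereg_genes,
                  lfc_sign = lfc_sign,
                  params = list(lfc_magnitude = lfc_magnitude,
                                n_samples_per_group = n_samples_per_group,
                                activity_shift = activity_shift,
                                noise_sd = noise_sd),
                  seed = seed)
    list(edges = edges, activity = activity, expression = expression,
         de_table = de_table, groups = groups, truth = truth)
  })
}

#' Differential regulator activity between two groups
#'
#' Applies a two-sided Student's t-test per regulator to an activity table and
#' adjusts P-values with Benjamini-Hochberg, producing the differential table
#' consumed by [select_differential_regulators()].
#'
#' @param activity Tibble with a `regulator` column and one numeric column per
#'   sample.
#' @param groups Named character vector mapping sample column names to two
#'   group labels.
#' @return Tibble with `regulator`, `mean_diff`, `p`, `padj`.
#' @export
differential_activity <- function(activity, groups) {
  samples <- names(groups)
  stopifnot(all(samples %in% names(activity)),
            length(unique(groups)) == 2)
  g <- unique(groups)
  a <- samples[groups == g[1]]
  b <- samples[groups == g[2]]
  mat <- as.matrix(activity[, samples])
  res <- tibble(
    regulator = activity$regulator,
    mean_diff = rowMeans(mat[, a, drop = FALSE]) -
      rowMeans(mat[, b, drop = FALSE]),
    p = apply(mat, 1, function(v) {
      stats::t.test(v[match(a, samples)], v[match(b, samples)])$p.value
    })
  )
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res
}
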