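# Generator for binary single-cell accessibility matrices with planted
# co-accessible promoter-enhancer links and rewired promoters.

#' Generate two-condition single-cell accessibility matrices
#'
#' Simulates binary cell-by-locus accessibility for two conditions (disease,
#' control) on one synthetic chromosome. Loci are arranged in neighborhoods of
#' one promoter plus a few enhancers within `max_pair_distance` of it, with
#' neighborhoods spaced far beyond the 100-kb pairing window. Unlinked loci
#' open independently with `Bernoulli(baseline_rate)` per cell; a linked
#' promoter-enhancer pair shares a per-cell latent factor that raises the open
#' probability of both loci by `co_open_boost`, creating co-accessibility
#' without modelling spatial contacts explicitly. `n_linked_pairs` links are
#' present in both conditions; `n_rewired` promoters are linked to one
#' enhancer in the disease condition and a different one in the control
#' condition. A few cells with extreme integration counts are planted to
#' exercise cell QC.
#'
#' @param n_cells_per_condition Cells per condition (before planted QC cells).
#' @param n_promoters,n_enhancers Locus counts; enhancers are distributed
#'   evenly across promoter neighborhoods.
#' @param baseline_rate Per-cell open probability of an unlinked locus.
#' @param n_linked_pairs Links planted identically in both conditions.
#' @param co_open_boost Increase in open probability when the shared latent
#'   factor is on (expected phi of a planted pair grows with this).
#' @param n_rewired Promoters whose linked enhancer differs between the two
#'   conditions.
#' @param max_pair_distance Maximum promoter-enhancer midpoint distance within
#'   a neighborhood, bp (<= 100,000 so planted pairs are discoverable).
#' @param n_qc_low,n_qc_high Planted QC-failing cells (near-empty / saturated).
#' @param seed Integer seed.
#' @return List with `matrices` (named list of [acc_matrix()] objects for
#'   `CLL` and `NBC`) and `truth` (planted links with expected C/H/CH class,
#'   rewired promoters, QC-fail cell ids, parameters).
#' @export
gen_scatac <- function(n_cells_per_condition = 500, n_promoters = 40,
                       n_enhancers = 160, baseline_rate = 0.15,
                       n_linked_pairs = 20, co_open_boost = 0.6,
                       n_rewired = 5, max_pair_distance = 80e3,
                       n_qc_low = 3, n_qc_high = 2, seed = 1) {
  stopifnot(max_pair_distance <= 100e3,
            n_linked_pairs + n_rewired <= n_promoters,
            baseline_rate + co_open_boost < 1)
  per_nbh <- ceiling(n_enhancers / n_promoters)
  stopifnot(per_nbh >= 2)
  withr::with_seed(seed, {
    nbh_spacing <- 400e3
    width <- 500L
    loci <- list()
    for (i in seq_len(n_promoters)) {
      p0 <- i * nbh_spacing
      loci[[length(loci) + 1]] <- tibble(
        chrom = "chr1", start = p0, end = p0 + width,
        role = "promoter", gene = paste0("G", i)
      )
      n_e <- min(per_nbh, n_enhancers - (i - 1) * per_nbh)
      if (n_e > 0) {
        offs <- round(seq(max_pair_distance / n_e, max_pair_distance,
                          length.out = n_e))
        loci[[length(loci) + 1]] <- tibble(
          chrom = "chr1", start = p0 + offs, end = p0 + offs + width,
          role = "enhancer", gene = NA_character_
        )
      }
    }
    loci <- bind_rows(loci) |> arrange(.data$start)
    loci$locus_id <- paste0("loc", seq_len(nrow(loci)))
    prom_idx <- which(loci$role == "promoter")
    enh_of <- function(p) {
      # enhancers in the same neighborhood as promoter index p (within window)
      which(loci$role == "enhancer" &
              abs((loci$start + loci$end) / 2 -
                    (loci$start[p] + loci$end[p]) / 2) <= max_pair_distance)
    }

    proms <- sample(prom_idx)
    shared_proms <- proms[seq_len(n_linked_pairs)]
    rewired_proms <- proms[n_linked_pairs + seq_len(n_rewired)]
    links <- list()
    for (p in shared_proms) {
      e <- sample(enh_of(p), 1)
      links[[length(links) + 1]] <-
        tibble(promoter = p, enhancer = e, condition = c("CLL", "NBC"),
               expected_class = "CH")
    }
    for (p in rewired_proms) {
      es <- sample(enh_of(p), 2)
      links[[length(links) + 1]] <-
        tibble(promoter = p, enhancer = es, condition = c("CLL", "NBC"),
               expected_class = c("C", "H"))
    }
    links <- if (length(links) > 0) {
      bind_rows(links)
    } else {
      tibble(promoter = integer(), enhancer = integer(),
             condition = character(), expected_class = character())
    }

    simulate_condition <- function(cond) {
      lk <- links[links$condition == cond, ]
      n_loci <- nrow(loci)
      n <- n_cells_per_condition
      p_open <- matrix(baseline_rate, nrow = n, ncol = n_loci)
      for (j in seq_len(nrow(lk))) {
        z <- stats::rbinom(n, 1, 0.5)
        p_open[, lk$promoter[j]] <- baseline_rate + co_open_boost * z
        p_open[, lk$enhancer[j]] <- baseline_rate + co_open_boost * z
      }
      m <- matrix(stats::rbinom(n * n_loci, 1, p_open), nrow = n)
      # planted QC failures: near-empty and saturated cells
      low <- matrix(stats::rbinom(n_qc_low * n_loci, 1, 0.005),
                    nrow = n_qc_low)
      high <- matrix(1L, nrow = n_qc_high, ncol = n_loci)
      m <- rbind(m, low, high)
      cells <- tibble(
        cell = paste0(cond, "_cell", seq_len(nrow(m))),
        count = as.numeric(rowSums(m))
      )
      qc_fail <- cells$cell[n + seq_len(n_qc_low + n_qc_high)]
      list(mat = acc_matrix(Matrix::Matrix(m, sparse = TRUE),
                            loci = loci, cells = cells),
           qc_fail = qc_fail)
    }
    cll <- simulate_condition("CLL")
    nbc <- simulate_condition("NBC")

    # expected phi of a planted pair under the latent-factor model
    p1 <- baseline_rate + co_open_boost / 2
    exp_phi <- (co_open_boost^2 / 4) / (p1 * (1 - p1))
    truth <- list(
      scenario = "scatac", loci = loci,
      links = links |> mutate(
        promoter_id = loci$locus_id[.data$promoter],
        enhancer_id = loci$locus_id[.data$enhancer],
        gene = loci$gene[.data$promoter]
      ),
      rewired_genes = loci$gene[rewired_proms],
      qc_fail_cells = c(cll$qc_fail, nbc$qc_fail),
      expected_phi = exp_phi,
      params = list(n_cells_per_condition = n_cells_per_condition,
                    baseline_rate = baseline_rate,
                    co_open_boost = co_open_boost,
                    max_pair_distance = max_pair_distance),
      seed = seed
    )
    list(matrices = list(CLL = cll$mat, NBC = nbc$mat), truth = truth)
  })
}
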