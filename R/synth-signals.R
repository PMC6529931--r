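# Generators for log2 fold-change mixtures and stranded coverage with planted
# divergent (bidirectional) transcription loci.

#' Generate draws from a three-component Gaussian mixture
#'
#' Emulates the empirical distribution of log2 fold changes in differential
#' chromatin signal: an unchanged central component flanked by a decreased and
#' an increased component. The truth records the generating parameters and the
#' analytic crossover points between adjacent weighted components.
#'
#' @param weights,means,sds Numeric length-3 mixture parameters; weights must
#'   sum to 1 and sds be positive.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List with `values` (numeric vector) and `truth` (parameters plus
#'   `crossovers`, the analytic lower/upper thresholds).
#' @export
gen_fc_mixture <- function(weights = c(0.25, 0.5, 0.25),
                           means = c(-2, 0, 2), sds = c(0.5, 1, 0.5),
                           n = 50000, seed = 1) {
  stopifnot(length(weights) == 3, abs(sum(weights) - 1) < 1e-8, all(sds > 0))
  withr::with_seed(seed, {
    comp <- sample.int(3, n, replace = TRUE, prob = weights)
    values <- stats::rnorm(n, means[comp], sds[comp])
  })
  cross <- tryCatch(
    c(lower = gaussian_crossing(weights[1], means[1], sds[1],
                                weights[2], means[2], sds[2]),
      upper = gaussian_crossing(weights[2], means[2], sds[2],
                                weights[3], means[3], sds[3])),
    error = function(e) c(lower = NA_real_, upper = NA_real_)
  )
  list(values = values,
       truth = list(scenario = "fc_mixture", weights = weights, means = means,
                    sds = sds, crossovers = cross, seed = seed))
}

#' Generate stranded coverage with planted divergent loci
#'
#' Builds plus- and minus-strand read-density tracks on one synthetic
#' chromosome. Planted bidirectional loci have minus-strand mass 5' of the
#' plus-strand mass within a window (divergent geometry) and a minor-strand
#' share well above the 20% calling rule; unidirectional loci have only trace
#' minor-strand signal. Some divergent loci are planted on top of a TSS or of
#' exons on both strands and are recorded as excluded in the truth.
#'
#' @param n_bidi Number of detectable planted divergent loci.
#' @param n_unidirectional Number of planted one-strand loci.
#' @param window Window size the detector uses, bp.
#' @param minor_ratio Minor/major strand read ratio at planted divergent loci.
#' @param major_reads Expected major-strand reads per locus.
#' @param n_tss_excluded,n_exon_excluded Divergent loci planted under a TSS /
#'   under exons on both strands (detector must exclude them).
#' @param bin Track bin size, bp.
#' @param seed Integer seed.
#' @return List with `plus`, `minus` (signal tibbles), `tss`, `exons_plus`,
#'   `exons_minus` (interval tibbles), and `truth`.
#' @export
gen_stranded_coverage <- function(n_bidi = 20, n_unidirectional = 20,
                                  window = 1000, minor_ratio = 0.5,
                                  major_reads = 200, n_tss_excluded = 3,
                                  n_exon_excluded = 3, bin = 10, seed = 1) {
  n_total <- n_bidi + n_unidirectional + n_tss_excluded + n_exon_excluded
  spacing <- 10L * window
  genome_length <- (n_total + 1L) * spacing
  withr::with_seed(seed, {
    kind <- sample(c(rep("bidi", n_bidi),
                     rep("uni", n_unidirectional),
                     rep("bidi_tss", n_tss_excluded),
                     rep("bidi_exon", n_exon_excluded)))
    centers <- (seq_len(n_total)) * spacing
    plus_rows <- list(); minus_rows <- list()
    half <- window %/% 2L
    spread <- function(center_lo, center_hi, total) {
      # Poisson reads over 10-bp bins within [center_lo, center_hi)
      edges <- seq(center_lo, center_hi, by = bin)
      k <- length(edges) - 1L
      counts <- stats::rpois(k, total / k)
      tibble(start = edges[-length(edges)], end = edges[-1],
             value = counts)[counts > 0, ]
    }
    for (i in seq_len(n_total)) {
      c0 <- centers[i]
      divergent <- kind[i] != "uni"
      plus_total <- stats::rpois(1, major_reads)
      if (divergent) {
        minus_total <- stats::rpois(1, minor_ratio * major_reads)
        # minus mass on the 5' (left) half, plus mass on the right half
        minus_rows[[length(minus_rows) + 1]] <-
          spread(c0 - half + 50, c0 - 50, minus_total)
        plus_rows[[length(plus_rows) + 1]] <-
          spread(c0 + 50, c0 + half - 50, plus_total)
      } else {
        minus_total <- stats::rpois(1, 0.05 * major_reads)
        plus_rows[[length(plus_rows) + 1]] <-
          spread(c0 + 50, c0 + half - 50, plus_total)
        minus_rows[[length(minus_rows) + 1]] <-
          spread(c0 + 50, c0 + half - 50, minus_total)
      }
    }
    mk_track <- function(rows) {
      bind_rows(rows) |>
        mutate(chrom = "chr1", .before = 1) |>
        arrange(.data$start)
    }
    plus <- mk_track(plus_rows); minus <- mk_track(minus_rows)
    tss <- tibble(chrom = "chr1",
                  start = centers[kind == "bidi_tss"],
                  end = centers[kind == "bidi_tss"] + 1L)
    exon_centers <- centers[kind == "bidi_exon"]
    exons_plus <- tibble(chrom = "chr1", start = exon_centers - half,
                         end = exon_centers + half)
    exons_minus <- exons_plus
    truth <- tibble(
      locus_id = paste0("L", seq_len(n_total)),
      chrom = "chr1", center = centers,
      start = centers - half, end = centers + half,
      kind = kind,
      expected_detected = kind == "bidi"
    )
    list(plus = plus, minus = minus, tss = tss,
         exons_plus = exons_plus, exons_minus = exons_minus,
         truth = list(scenario = "stranded_coverage", loci = truth,
                      genome_length = genome_length, window = window,
                      seed = seed))
  })
}
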