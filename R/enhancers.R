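# Active-enhancer annotation: replicate consistency, intersection of signal
# loci with active chromatin states, promoter exclusion, and cross-sample
# consensus.

#' Keep loci identified in both replicates
#'
#' Returns the loci of replicate 1 that overlap (>= 1 bp) a replicate-2 locus;
#' reported intervals are the replicate-1 loci.
#'
#' @param rep1,rep2 Interval tibbles of per-replicate loci.
#' @return Subset of `rep1`.
#' @export
replicate_consistent_loci <- function(rep1, rep2) {
  rep1 <- validate_intervals(rep1, "rep1")
  rep2 <- validate_intervals(rep2, "rep2")
  rep1[overlaps_any(rep1, rep2), ]
}

#' Per-sample active enhancers from signal loci and chromatin states
#'
#' For each ATAC or bidirectional-transcription locus, the region of
#' `+/- flank` (1 kb) around the locus center is retained when it overlaps an
#' active-enhancer chromatin state segment (states 1 and 9 of the 12-state
#' segmentation, which carry the strong H3K27ac signal). Regions overlapping
#' a TSS `+/- promoter_exclusion` (1 kb) are dropped, and the surviving
#' regions are merged.
#'
#' @param loci Interval tibble of signal loci (peaks or Bidi loci).
#' @param states Interval tibble with a `state` column (integer labels 1-12),
#'   non-overlapping per sample.
#' @param active_states Integer vector of enhancer state labels.
#' @param flank Half-width of the region around each locus center, bp.
#' @param tss Interval tibble of transcription start sites.
#' @param promoter_exclusion Exclusion half-width around each TSS, bp.
#' @return Merged interval tibble of active enhancers.
#' @export
active_enhancers <- function(loci, states, active_states = c(1, 9),
                             flank = 1000, tss = NULL,
                             promoter_exclusion = 1000) {
  loci <- validate_intervals(loci, "loci")
  states <- validate_intervals(states, "states")
  stopifnot("state" %in% names(states))
  if (nrow(loci) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  center <- (loci$start + loci$end) %/% 2L
  regions <- tibble(chrom = loci$chrom,
                    start = pmax(0L, center - as.integer(flank)),
                    end = center + as.integer(flank))
  act <- states[states$state %in% active_states, ]
  regions <- regions[overlaps_any(regions, act), ]
  if (!is.null(tss) && nrow(tss) > 0 && nrow(regions) > 0) {
    excl <- tibble(chrom = tss$chrom,
                   start = pmax(0L, tss$start - as.integer(promoter_exclusion)),
                   end = tss$end + as.integer(promoter_exclusion))
    regions <- regions[!overlaps_any(regions, excl), ]
  }
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  merge_intervals(regions)
}

#' Consensus active-enhancer sets across samples
#'
#' Builds disease (CLL) and control (NBC) consensus enhancer lists by
#' base-level occupancy: a region must be identified in at least `min_cll` of
#' the patient lists and at least `min_nbc` of the control lists. The control
#' minimum depends on the evidence kind - 1 for ATAC, 2 for bidirectional
#' transcription - matching the different replication depth of the two
#' assays. Evidence kinds are never mixed within one consensus call.
#'
#' @param cll_lists,nbc_lists Lists of per-sample enhancer interval tibbles.
#' @param evidence `"atac"` or `"bidi"`; sets the default `min_nbc`.
#' @param min_cll Minimum patient samples covering a base.
#' @param min_nbc Minimum control samples covering a base (defaults by
#'   evidence kind).
#' @return List with `cll`, `nbc`, and `shared` (base-level intersection of
#'   the two consensus sets, merged).
#' @export
consensus_enhancers <- function(cll_lists, nbc_lists,
                                evidence = c("atac", "bidi"),
                                min_cll = 3, min_nbc = NULL) {
  evidence <- match.arg(evidence)
  if (is.null(min_nbc)) min_nbc <- if (evidence == "atac") 1 else 2
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  if (length(cll_lists) < min_cll || length(nbc_lists) < min_nbc) {
    warning("fewer sample lists than the consensus minimum: empty consensus")
    return(list(cll = empty, nbc = empty, shared = empty))
  }
  cll <- coverage_consensus(cll_lists, min_count = min_cll)
  nbc <- coverage_consensus(nbc_lists, min_count = min_nbc)
  list(cll = cll, nbc = nbc, shared = intersect_intervals(cll, nbc))
}
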