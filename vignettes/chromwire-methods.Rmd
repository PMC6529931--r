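---
title: "Methods: chromatin-landscape callers and enhancer wiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-landscape callers and enhancer wiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromwire)
```

chromwire implements the chain of bespoke procedures used to compare the
chromatin landscape of chronic lymphocytic leukemia (CLL) B cells with
non-malignant B cells (NBCs): methylation-domain and DMR calling, promoter
H3K4me3 and nucleosome statistics, distribution-derived differential
thresholds, eRNA detection, enhancer annotation, single-cell co-accessibility
wiring, and assembly of a gene regulatory enhancer network (GREN). This
vignette explains each model, its assumptions, the parameters that matter,
and the design decisions taken where the procedure leaves room.

All genomic intervals in the package are tibbles with 0-based half-open
coordinates (BED convention); 1-based formats are converted at the readers.
Touching half-open intervals merge at `min_gap = 0`, matching base-level
union semantics.

## Partially methylated domains

A PMD is a large (≥ 100 kb) region of intermediate, disordered methylation,
associated with heterochromatin and late replication. `call_pmds()` slides a
`window` (10 kb) in steps of `step` (1 kb) along each chromosome, flags
windows whose mean β over contained CpGs is *strictly below*
`max_mean_beta` (0.65), merges overlapping or touching flagged windows, and
keeps merged regions of at least `min_length` (100 kb, inclusive). Regions
overlapping assembly gaps by ≥ 1 bp are discarded when a gap table is given.

Decisions worth knowing:

- **Stride.** Only the window size is canonical; the stride of the original
  scan is not. The default of 1 kb gives a dense approximation of a running
  mean while keeping the scan cheap; it is exposed because coarser strides
  (e.g. window-aligned) shift boundaries by up to one window.
- **Empty windows never qualify.** A window with no covered CpG carries no
  evidence of hypomethylation; treating missingness as hypomethylation would
  hallucinate PMDs in CpG deserts.
- **CpGs are weighted equally** within a window (not by read coverage); the
  read-depth filter at input (`read_methylome()`, ≥ 5 reads) already removes
  unreliable calls.
- **Boundary behaviour.** A window qualifies as soon as enough of it lies in
  the hypomethylated region to pull the mean under 0.65, so called domains
  extend beyond the true boundary by up to about half a window at the
  default β levels. At extreme hypomethylation this spill can nudge a
  slightly-sub-100-kb block over the length cutoff; at the intermediate
  methylation levels PMDs actually show (β ≈ 0.4–0.5 inside) it cannot.

`consensus_pmds()` counts per-base occupancy across samples and keeps bases
covered by at least `ceiling(min_fraction × n)` per-sample PMDs (6 of 11 at
the default one-half). Base-level occupancy was chosen over whole-region
voting because it is insensitive to how individual callers fragment a
domain; the two differ only at partial overlaps.

`pmd_boundary_profiles()` aggregates signal tracks in 5-kb bins over ± 50 kb
around each boundary, orienting both boundaries of a domain so that the
interior maps to positive offsets, and normalizes by the mean over bins
entirely outside the domain. Bins without track coverage are treated as
missing and excluded from means — zero-filling would deflate the flank
normalization in unmappable regions.

## Differentially methylated regions

`test_cpgs()` computes, per CpG covered in ≥ 2 samples of each group, the
group difference of mean β (disease − control) and a Welch t-test P-value.
This is a deliberate, documented substitution: the dispersion-smoothing
model of dedicated WGBS callers is out of scope here, and the package's
contribution is the region chain on top — `call_dmrs()` groups runs of
consecutive tested CpGs that are significant (P < 0.05, strict) with
same-sign difference and inter-CpG gaps ≤ `max_cpg_gap` (500 bp, a module
default; the original grouping rule is unstated), and reports a run when it
spans ≥ 200 bp and |mean Δβ| ≥ 0.3 (both inclusive, mirroring the quoted
inequalities). A non-significant CpG between two significant ones breaks the
run.

`maturation_filter()` removes DMRs whose change is "similar" to the change
seen between high-maturity memory and naive B cells, operationalized as
|Δβ(DMR) − Δβ(maturation)| < 0.2; the maturation value of a DMR comes from
the maturation region it overlaps most (region-level means; a CpG-level
variant would need the underlying maturation methylomes). DMRs without a
maturation value are treated as unchanged (0) with a warning.

A note on the monotonicity property: relaxing the per-CpG significance
threshold can merge adjacent runs, so *region identities* are not stable
under relaxation, but the *bases covered* by called DMRs are monotone
non-decreasing; the tests formalize it that way.

## Promoter H3K4me3 broadening and nucleosome gain

`build_width_table()` records, per promoter and sample, the width of the
H3K4me3 peak overlapping the promoter (the widest, when several overlap).
Only "common" promoters — peak present in every sample — are testable.
`detect_broadened()` reports a promoter when a two-sample Wilcoxon rank test
on the widths gives p < 0.05 *and* the disease-group median exceeds the
control median by ≥ 400 bp (inclusive; the gate is per promoter, not
global). The rank test replaces the original study's in-house per-region
P-value, which is tied to an unpublished read-correlation tool; the
significance-plus-effect-size structure of the gate is preserved.

`detect_nucleosome_gain()` averages library-size-normalized H3 (nucleosome)
signal over a 1,000-bp window centered on each promoter's strand-aware TSS
and applies a one-sided rank test (disease > control). Because the test is
rank-based, any common rescaling of the tracks leaves the calls unchanged;
library-size normalization only removes per-sample depth differences.

## Distribution-derived differential thresholds

`fit_three_gaussians()` fits a three-component Gaussian mixture to the
observed log2 fold changes by expectation–maximization on the raw values
(a least-squares fit to histogram counts was considered and rejected: it
adds a binning parameter and loses efficiency; EM on values is the standard
estimator for this model). The three components model unchanged, decreased
and increased regions. Numerical choices: initialization is deterministic —
means at the 10th/50th/90th percentiles, equal weights, pooled-SD/2 scales —
so the common path needs no seed; responsibilities are computed in log space
with log-sum-exp; convergence is a relative log-likelihood change below
`tol` (1e-8); the log-likelihood is asserted non-decreasing every iteration;
a component SD falling below `sd_floor` (1e-3) triggers a seeded, perturbed
restart, and five failed restarts are an error (degenerate data such as
all-equal values end up here). With a single generating component the
3-component likelihood is flat in how the mass is split, so EM may return
near-identical components sharing weight; the identifiable quantities
(mixture mean, variance, likelihood) are what the tests pin down.

`crossover_points()` returns the thresholds as the intersections of adjacent
*weighted* component densities — the points where the posterior
responsibility flips, which is what "cross-over points" of a mixture mean.
Unweighted density crossings are available via `weighted = FALSE` since the
weighting convention is a modelling choice. The crossing of two Gaussian
log-densities is a quadratic equation, so the root inside the bracket
(between the two component means) is computed in closed form rather than by
iterative search; this makes shift/scale equivariance hold to floating-point
accuracy, and the weighted densities at the returned points agree to 1e-10
by assertion. If no root lies between the means, one component dominates the
whole interval and the function stops with the offending pair named.

`fdr_inflection()` builds N(t) = #{q ≤ t} on a 200-point uniform grid over
(0, max q], smooths with a 5-point moving average, and returns the grid
point of maximum absolute second difference — the point where relaxing the
FDR stops yielding discoveries at the initial rate. The original study gives
no formula for its "inflection point", so maximum discrete curvature is this
module's definition. If the maximum curvature is below 1% of the total count
(a near-uniform discovery curve has only counting noise), there is no
meaningful inflection and the first grid point is returned with a warning;
a single distinct q-value is returned as-is (a degenerate step).

## Bidirectional transcription (eRNA candidates)

`detect_bidirectional()` slides a 1-kb window (step 100 bp) over stranded
coverage and calls a window when (i) the major strand has ≥ `min_major_reads`
(default 10 — a floor so the ratio rule is not tested on noise; the original
floor is unstated), (ii) the minor strand carries ≥ 20% of the major
strand's reads (inclusive; implemented as a ratio comparison so an exactly
20% minor strand passes without floating-point drift), (iii) the geometry is
divergent, and (iv) the window overlaps no TSS and not exons on both
strands. "Bimodal shape" is not defined in the source procedure; it is
operationalized here — flagged prominently — as the minus-strand read
centroid lying ≥ 100 bp 5′ of the plus-strand centroid with each strand
keeping ≥ 60% of its reads on its own window half. Both knobs are exposed.
Overlapping passing windows are merged and strand totals recomputed on the
union.

## Active-enhancer annotation

`replicate_consistent_loci()` keeps loci identified in both replicates
(≥ 1 bp overlap, reported as the replicate-1 interval).
`active_enhancers()` takes ± 1 kb around each locus center — the midpoint,
since summits are unavailable from BED input — keeps regions overlapping
chromatin states 1 or 9 (the states carrying strong H3K27ac, i.e. predicted
genic/intergenic active enhancers in the 12-state segmentation), drops
regions touching a TSS ± 1 kb, and merges. `consensus_enhancers()` requires
a base to be covered in ≥ 3 patient lists and ≥ 1 (ATAC evidence) or ≥ 2
(Bidi evidence) control lists; the two evidence kinds are never mixed in one
consensus. The control-side minimum is read as the NBC consensus threshold
(the plausible alternative — a cross-condition requirement — would make the
"NBC list" undefined).

## Single-cell co-accessibility wiring

`qc_cells()` removes cells with integration counts below 0.2× the mean or
above the mean + 3 standard deviations. The SD is the population SD
(divide by n), which is what the procedure's arithmetic implies, and the
bounds are computed once on the input rather than iterated, making QC
idempotent. `candidate_pairs()` enumerates same-chromosome
promoter–enhancer pairs with midpoint distance ≤ 100 kb (TAD-sized windows;
the window is symmetric in the two anchors). `pair_correlations()` computes
the Pearson correlation of the two binary columns across cells — the phi
coefficient; pairs with a constant locus are undefined and skipped with a
count.

`permutation_threshold()` derives the calling threshold from spurious
correlations: each permutation shuffles every locus column independently
across cells, preserving per-locus open frequencies while destroying all
dependence (per-cell totals are only approximately preserved; a
marginal-preserving swap scheme would be slower and the column shuffle is
the natural null for column–column correlation). The threshold is the
`quantile` (default 0.999) of the pooled permuted correlations. The original
analysis reports the resulting value (0.22 on its cohort), not the rule;
the rule — a high quantile of the permutation null — is the contract here,
and the value it produces depends on cell number and locus frequencies.

`call_and_classify()` calls a pair in a condition when its correlation
reaches that condition's threshold and matches pairs across conditions by
identical promoter gene and ≥ 1 bp enhancer overlap (exact-identity matching
is stricter and unnecessary once enhancers are deduplicated), yielding the
C (CLL-only), H (NBC-only), CH (shared) classes. `rewired_promoters()`
returns promoters with at least one C pair, at least one H pair, and no CH
pair — promoters whose enhancer partners are disjoint between conditions.

## GREN assembly

`dedup_enhancers()` merges overlapping enhancer intervals across conditions;
a merged region is CH when called pairs from both conditions land on it,
otherwise C or H. (The corner case of a merged region built from a C-pair
and an H-pair targeting *different* genes is undefined in the source
procedure; the both-conditions rule is this module's documented choice.)
Promoters are mapped to gene symbols, collapsing multiple TSSs of one gene
onto the symbol; unmappable pairs are dropped with a count.
`number_enhancers()` assigns class-prefixed serials (C1, C2, …) in genomic
order, so input order never changes ids. `select_differential_regulators()`
applies BH-adjusted P < 0.05 (strict) to a per-regulator two-sided t-test
table (`differential_activity()` produces one from an activity matrix);
`select_deregulated_genes()` applies P < 0.01 and |LFC| > 1.7, both strict —
the quoted notation "−1.7 < LFC > 1.7" is read as |LFC| > 1.7, the only
coherent reading for a deregulation gate. `assemble_gren()` integrates
enhancer–gene edges into the regulator→target network (edges to genes
absent from the network are dropped with a count) and flags chromatin
modifiers; `extract_disease_subnetwork()` induces the subgraph on core TFs,
their deregulated targets, selected modifiers, and enhancers linked to
retained genes, removing dangling enhancers but keeping isolated core TFs
for visual completeness (configurable by simply filtering the node table).
The graph is a pair of node/edge tibbles that round-trips exactly through
TSV (`write_gren()`/`read_gren()`); `as_igraph()` converts for graph
algorithms or export.

## What the synthetic data emulates — and what it does not

Each generator is a pure function of its parameters and seed, and its truth
object suffices to score the downstream caller.

- `gen_methylomes()` draws per-CpG β from Beta distributions parameterized
  by mean and concentration (bounded in [0,1], matching WGBS marginals;
  default concentration 15, i.e. realistic per-CpG noise around means of
  0.45 inside and 0.85 outside planted domains). PMD lengths are drawn
  log-uniformly over the requested range so that a cohort-scale scenario
  (15 domains of 150 kb–2 Mb) fits a 20-Mb genome; domains are separated by
  ≥ 50 kb so calls never bridge. CpGs are evenly spaced — real CpG density
  varies and CpG islands are not modelled.
- `gen_dmr_scenario()` plants regions with a fixed group-mean β difference
  (±0.4 by default, random sign) on a 0.55 background, and a maturation
  table in which a chosen fraction of planted DMRs carries the matching
  maturation change (hence is filterable).
- `gen_fc_mixture()` samples the three-Gaussian model directly and records
  the analytic crossovers.
- `gen_stranded_coverage()` places divergent loci (minus-strand mass 5′ of
  plus-strand mass) and unidirectional loci on a spaced grid, with Poisson
  read noise; some divergent loci are planted under a TSS or under exons on
  both strands to exercise the exclusions.
- `gen_scatac()` opens unlinked loci independently (Bernoulli, rate 0.15)
  and gives each linked promoter–enhancer pair a shared per-cell latent
  factor that raises both open probabilities by `co_open_boost` (0.6, for an
  expected phi of ≈ 0.36) — correlated openness without an explicit contact
  model, which is all the wiring statistic assumes. Rewired promoters link
  to different enhancers in the two conditions. Near-empty and saturated
  cells are planted for QC. Sequence-dependent transposase bias and
  copy-number effects are not modelled.
- `gen_grn()` builds a regulator→target edge list with shared targets,
  shifts the activity of deregulated regulators between groups, and plants
  target genes with |LFC| 2.5 at noise small enough that the standard gate
  finds them at n = 5 per group.

Passing on these generators shows the callers implement their rules
correctly and recover structure under the stated noise; it does not certify
performance on real data, where methylation noise is coverage-dependent,
accessibility is sparser and confounded by depth per cell, and fold-change
distributions are not exactly Gaussian mixtures.

## Problem sizes and reproducibility

The test-suite and acceptance scenarios use a 20-Mb single-chromosome genome
at 100-bp CpG spacing for PMD recovery, 6 samples per group on a 2-Mb genome
for the DMR chain, 50,000 mixture draws, 40 promoters/160 enhancers with
400–500 cells per condition and 100 permutations for the wiring stage, and
toy networks for GREN — sizes chosen so every property is measurable with
comfortable statistical margins on a single CPU. All randomness flows
through explicit seeds (`withr::with_seed` internally), and
`run_synthetic_pipeline(seed)` reproduces every output identically for a
given seed.

## Known limitations

- The per-CpG test and the promoter rank tests are substitutions for
  out-of-scope external tools; absolute P-values will differ from the
  original pipeline even where the decision chains match.
- Cross-sample consensus is base-level, not region-voting; the two differ at
  partial overlaps.
- Distances use interval midpoints throughout (peak summits are not
  available from BED input).
- The permutation null preserves locus marginals but not per-cell totals;
  with strong per-cell depth variation the threshold is slightly
  conservative.
- Single-chromosome synthetic genomes: all interval operations are
  per-chromosome, so multi-chromosome behaviour is exercised only by the
  small interval-algebra tests.
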