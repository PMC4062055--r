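---
title: "Methods: species-specific DMR discovery by three-species triangulation"
author: "triodmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-specific DMR discovery by three-species triangulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the inference

MeDIP-seq measures DNA methylation indirectly: immunoprecipitated fragment
density over a locus scales with its methylated-CpG content. Given pooled
whole-blood methylomes for a reference species (human-like) and two
out-groups (chimp-like and macaque-like), the question is which loci carry a
methylation state unique to the reference lineage — species-specific
differentially methylated regions (s-DMRs).

The inference has three legs:

1. **Robust peak calling.** Enrichment peaks are called per species on the
   native assembly with two independent callers, and only peaks confirmed by
   at least 1 bp of overlap with the second caller's output are kept
   ("consensus" peaks). This trades a small loss of sensitivity for a
   substantially cleaner peak universe.
2. **Cross-assembly triangulation.** Out-group peaks are lifted onto the
   reference assembly through chain alignments (minMatch = 0.7).
   *Hypomethylated* s-DMRs are shared chimp∩macaque peaks (1-bp rule, chimp
   lifted coordinates define the region) with no reference-species peak from
   either caller. *Hypermethylated* s-DMRs are reference consensus peaks
   with no out-group peak from either caller in either species, that
   additionally survive a reciprocal back-lift through both out-group
   genomes and avoid a poor-mappability blacklist. The third species is the
   out-group that polarizes the change: without it, any human–chimp
   difference would be attributed to the human branch.
3. **Downstream characterization.** Island/shore prevalence with
   fractional-overlap counting, position-weight-matrix occupancy divergence
   between the orthologous sequences, and gene-body methylation
   differentials that rank promoter-hypomethylated transcripts by
   reference-elevated exonic signal.

## Peak callers

**Poisson sliding window.** Fragment midpoints are binned (default 50 bp); a
window of one nominal fragment length (default 200 bp) slides one bin at a
time. A window with count $k$ is significant when
$P(X \ge k \mid \lambda = \text{rate} \times \text{window bins}) <
10^{-3}$, with the rate taken genome-wide. Significant windows closer than
one fragment length merge into a peak; the score is $-10\log_{10} p$ of the
best window (a `minuslog10` switch is provided because transformed-p
conventions differ between tools), the summit the center of the leftmost
best window. The genome-wide $\lambda$ (no local background) is a
deliberate simplification: the synthetic background is homogeneous by
construction, and a single-rate null keeps the caller auditable against
direct tail summation. On real data with copy-number or mappability
structure a local-lambda correction would be needed.

**Poisson mixture posterior.** The second caller fits a two-component
Poisson mixture (background, enriched) to the bin counts by EM over the
count histogram, with deterministic moment-based initialization (bins split
at the overall mean), 200 iterations maximum, and a relative log-likelihood
tolerance of 1e-8. Bins with enriched-state posterior above 0.5 merge into
peaks; scores are $-10\log_{10}(1-\text{posterior})$ capped at 1000. A fit
whose enriched mean is below twice the background mean is treated as
degenerate and yields no peaks — on a truly homogeneous track nothing is
called. This caller is *not* a reimplementation of any published
hidden-Markov peak caller; the analysis only requires an independent second
opinion for consensus, and a mixture-posterior caller provides one with
fully deterministic behavior.

## Liftover

Chains are parsed from the standard UCSC format with block-sum validation.
Mapping is per-base: the mapped fraction is the number of query bases
inside aligned blocks over the query length; the target interval is the
[min, max+1) envelope of mapped positions, strand-adjusted for minus-strand
chains. minMatch comparison is inclusive (`>=` 0.7), matching liftOver.
Bases mapping through more than one chain produce a `split` failure —
split hits are never stitched, mirroring liftOver's default behavior for
regions; how the original study handled splits is not stated, so the
conservative default is documented rather than inferred. The reciprocal
filter lifts a region over and back (same minMatch both ways) and requires
at least 1 bp of overlap with the original location; an exact-coordinate
strict mode is available.

Internally all intervals are `GRanges` (1-based, closed), the idiomatic R
container with native overlap machinery; BED, chain and bedGraph files are
converted at the I/O boundary (0-based half-open on disk). FASTA I/O goes
through Biostrings, which normalizes case on read; soft-masking is not
used anywhere in the analysis.

## The synthetic trio generator

The generator is first-class, tested code. It emulates, at desk scale, the
study design the pipeline targets: a reference genome with CpG islands, two
descendant genomes produced by branch-specific substitutions (default
1.2%/bp chimp-like, 5.5%/bp macaque-like) and indels (geometric lengths,
mean 3 bp; rates 0.0015 and 0.004/bp), *exact* chain files in both
directions derived from the edit log, and MeDIP-like fragments whose
sampling weight is $1 + e \cdot (\text{methylated CpG mass in a nominal
fragment window})$ with enrichment factor $e = 1$.

Planted truth comprises five classes — reference-hypo, reference-hyper,
chimp-only, shared-methylated and unmethylated background (default
30/30/20/30/10 over 2 × 1 Mb) — placed in islands, island shores and open
genome. Three placement rules matter and were fixed after studying the
generator's own failure modes, before freezing the defaults:

* **Planted levels are 0 and 0.85.** The "low" state is fully
  unmethylated. A residual low level (e.g. 0.05) inside a CpG-dense island
  produces weak but real MeDIP enrichment that intermittently crosses a
  global-rate threshold, blurring the class semantics the truth table is
  supposed to pin down.
* **Island-placed regions span their whole island.** A methylation switch
  at an island is an island-level event; a partially planted island leaves
  a baseline-methylated CpG-dense remainder with its own weak signal
  adjacent to the planted region.
* **Shore-placed regions attach to islands that host no planted region**,
  sit fully inside the 2-kb shore band at least 200 bp off the island
  edge, and keep 1 kb from any other planted region, so peaks at distinct
  planted regions can never merge across a gap shorter than the caller's
  merge distance.

Edits are excluded from planted regions (indels with a 100-bp margin), so
planted orthology is exact and mapped fractions there are 1.0; sequence
divergence lives in the rest of the genome. One region hosts a planted
motif locus: a 14-bp RFX-like consensus written into the reference inside a
hypomethylated island, weakened in both out-groups by a single targeted
substitution, with a linked gene-body hypermethylated region downstream and
a gene model anchored on the island — the promoter/gene-body divergence
situation the ranking stage is designed to surface.

Per-species library sizes differ by design (depth scale 1 / 0.85 / 1.15
around 30× coverage) so the normalization code is genuinely exercised.
Duplicate (3%), low-quality (2%) and improperly-paired (2%) fragments are
emitted to exercise filtering. All randomness flows from one master seed
through named substreams; a fixed seed reproduces every artifact
byte-identically.

**What the generator does not emulate:** inter-individual variation within
a species pool (one landscape per species), sequencing errors and base-level
reads (fragments are intervals, not FASTQ), CpG-density-dependent
fragmentation biases, ancestral-state asymmetry (the reference genome plays
the ancestor; both branches are edited away from it), and realistic repeat
biology (repeats are labeled annotation only). Passing recovery tests on
this generator therefore demonstrates the *logic* of triangulation,
filtering and ranking — not robustness to the full noise structure of real
MeDIP-seq.

## Motif occupancy and divergence

Occupancy follows the biophysical mismatch-energy model: for each window,
$E = \lambda^{-1} \sum_j \ln(f_{max,j}/f(b_j,j))$ with $\lambda = 0.7$, and
window occupancy $p = R_0 e^{-E}/(1+R_0 e^{-E})$ with
$\ln R_0 = 0.584\,W - 5.66$; total affinity sums windows over both strands,
skipping windows containing N. The parameterization follows the published
affinity-prediction method this model family comes from and is exposed in
`affinity_model()`.

The aggregate statistic for a region set is the summed affinity; its
p-value resamples length-matched subsequences from a background pool
(B draws; p = (r+1)/(B+1), ties counted as exceeding, so p is never 0).
This sum-plus-resampling null is a documented stand-in: the exact
aggregation behind "one total binding p-value per motif per species" is not
fully specified in the source analysis. Per-species p-values are BH-adjusted
across motifs before the two-dimensional divergence map
($\Delta_{HC}, \Delta_{HM}$ in $-\log_{10}$ units); a motif is flagged for
consistent reference-lineage change when both deltas share a sign and the
smaller magnitude reaches 1 log10 unit. The directional randomization test
redraws region sets of the observed sizes from candidate pools (default
4 × 1000 draws) and counts draws exceeding the observed divergence in the
same direction on both axes.

The shipped motif set is 22 synthetic demonstration matrices (CTCF-like,
SP1-like, RFX-like, MeCP2-like and others) in a TRANSFAC-like count format;
they are not derived from any licensed database, and real analyses should
supply their own matrices via `read_weight_matrix()`. Regions over 5 kb are
rejected at the type level.

## Gene-body ranking

Transcripts whose 5′ promoter island (TSS ± 1 kb intersected with the
island) overlaps a hypomethylated s-DMR are scored per species as the
*maximum* peak score over their exons (0 when no peak overlaps any exon;
exons are chain-mapped for the out-groups, unmappable exons contribute
nothing). How multiple exon peaks were combined in the source analysis is
unstated; max was chosen over sum because it is insensitive to exon count
and to exon fragmentation across assemblies. Differentials (H−C, H−M,
H−mean(C,M)) use exact arithmetic; the hypo-promoter table ranks descending
by H−mean(C,M) (the promoter-hypo/gene-body-high signature), ties broken
lexicographically by transcript id. Printed tables of this kind carry
hidden decimals, so recomputed differentials are compared with absolute
tolerance 0.11 in tests; cells that are pure arithmetic are compared
exactly.

## Enrichment machinery

Shores are the ±2 kb island flanks minus all island sequence, clipped and
merged — by construction they contain zero island bp. Fractional overlap
counting applies the threshold to the *query region* (intersect `-f`
semantics), inclusive at the boundary, so a region exactly half inside a
feature counts at 0.5. Densities are per Mb of merged feature sequence,
computed from the union, never taken on trust. The 2×2 chi-square is
Pearson without continuity correction, with an automatic, flagged Fisher
fallback when any expected cell drops below 5. The shuffle control
preserves the region count and exact length multiset, re-placing uniformly
outside a blacklist; its empirical p uses the same (r+1)/(n+1) convention.

## Numerical and degenerate-input choices

* Poisson tail p-values are computed in log space
  (`ppois(log.p = TRUE)`), so scores stay finite for arbitrarily strong
  peaks; tests verify agreement with direct term summation to 1e-12.
* The EM likelihood runs over the count histogram, not the bin vector,
  making its cost independent of genome size; non-convergence warns and
  uses the best iterate.
* p = 0 inputs to the divergence map are clamped to the smallest positive
  double and flagged.
* Empty inputs (no fragments, no peaks, empty blacklist, zero planted
  regions) return empty-but-typed objects rather than errors; classes with
  fewer than 5 regions in the signal benchmark report "insufficient n".
* Score output rounding (1 decimal in BED) is presentation-only.

## Problem sizes

The default synthetic trio is 2 chromosomes × 1 Mb with 120 planted
regions at 30× nominal coverage — small enough that a full
generate→call→lift→triangulate pass runs in well under a minute on one
core, while leaving every per-class count large enough for rank-based
tests. The test suite's recovery battery runs this default over 20 seeds;
unit tests use a 2 × 250 kb trio. These sizes are the package's chosen
trade-off between statistical resolution and an edit-test cycle fast
enough to keep the whole suite routinely runnable.

## Known limitations

* The genome-wide counts of the motivating study are not reproducible at
  toy scale and are out of scope; recovery metrics on planted truth are
  the package's accuracy claims.
* Two-species mode exists to quantify the out-group's value, not as a
  recommended analysis.
* The mixture caller's posterior threshold (0.5) and the divergence-map
  threshold (1 log10 unit) are conventions, not fitted quantities.
* Real-data mode expects filtered fragment BED, chain files and annotation
  BEDs; BAM parsing and alignment are intentionally outside the package.
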