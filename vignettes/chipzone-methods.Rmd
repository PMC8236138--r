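---
title: "Calling direct TF-DNA interactions from ChIP-seq peaks"
author: "chipzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling direct TF-DNA interactions from ChIP-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipzone)
```

## The problem

A ChIP-seq peak marks a region where a transcription factor (TF) was
cross-linked to chromatin, but not every peak contains a sequence the TF
reads directly: many peaks arise from indirect (tethered) binding, open
chromatin, or assay noise. chipzone separates the direct TF-DNA
interactions from the rest by requiring two independent kinds of support
for a binding site: a strong match to the TF's position weight matrix
(computational evidence) and proximity to the peak summit, the point of
maximal read pile-up (experimental evidence).

All coordinates are 0-based half-open (BED convention); summits are stored
as offsets from the peak start (MACS narrowPeak convention); motif scores
are log-odds in log2 units and are normalised per motif to `[0, 1]` as
`(score - min_score) / (max_score - min_score)`.

## The per-dataset pipeline

`run_dataset()` runs four stages on one (TF, ChIP-seq experiment) pair.

### 1. Dataset-specific PWM optimisation

The canonical JASPAR-style position frequency matrix is converted to
log-odds with a background-distributed pseudocount (default 0.8, uniform
background; both configurable). Training sequences are the 101 bp windows
centred on each peak summit (positives) and one 100 bp genomic window per
positive sampled to match its %GC bin (negatives; 5%-wide bins centred on
multiples of 5). GC matching prevents the optimiser from learning genome
composition instead of binding preference. When a positive's GC bin is
unreachable in the genome, the sampler relaxes to the closest achievable
%GC and says so; a strict mode errors instead.

The optimiser is a pairwise ranking perceptron on best-window one-hot
encodings: each epoch scores every sequence by its best window on either
strand, samples misranked positive/negative pairs (capped at
`10 * min(n_pos, n_neg)`), and moves the weight matrix by `learning_rate`
times the *mean* one-hot difference over the sampled pairs. Averaging
rather than summing the pair updates is deliberate: with hundreds of
misranked pairs a summed update is one to two orders of magnitude larger
than the log-odds weights themselves and destroys the matrix in a single
epoch (we observed AUROC collapsing from 0.73 to ~0.5); the averaged step
keeps the update at the learning-rate scale whatever the pair count. The
default learning rate of 0.3 matches the typical magnitude of log-odds
weights (about 2-4). After every epoch the AUROC (computed as the
Mann-Whitney statistic, ties at half weight) is re-evaluated and the
best-so-far matrix kept, so the final AUROC can never fall below the
initial one; training stops early after 10 epochs without improvement
(50 epochs maximum by default). Motif length never changes.

### 2. The enrichment zone

Every peak is scanned with the optimised PWM — both strands, no score
floor, windows containing N skipped — keeping exactly one best hit per
peak. Each hit contributes a point on the (distance-to-summit,
normalised-score) plane, where distance is measured from the site midpoint
(floor) to the summit. The two marginals of this landscape are then
thresholded independently with Kapur's maximum-entropy criterion: an
equal-width 100-bin histogram is built over the observed range, and the
bin boundary maximising the sum of Shannon entropies of the renormalised
histograms below and above it is selected. The criterion is flat across
runs of empty bins, so among tied boundaries the middle one is taken —
between two separated modes the threshold lands mid-gap rather than on a
mode's edge. The *enrichment zone* is the rectangle
`{norm_score >= s*} & {distance <= d*}`; with fewer than 50 landscape
hits the zone is declared undefined and the dataset is excluded
explicitly rather than silently. Both thresholds are learned from, and
the final calls made with, the optimised PWM, so the score scale used to
learn `s*` is the same one later compared against it.

Kapur thresholding was chosen because it is parameter-free (only the bin
count, exposed in the configuration), auditable in one line, and has an
exact brute-force oracle — the tests compare every threshold against
exhaustive evaluation of the criterion at all 99 boundaries.

### 3. Site calling

Peaks are rescanned with the optimised PWM and the best hit per peak is
emitted if and only if it lies in the zone: at most one TFBS per peak,
sorted output. These calls form the *permissive* set for the dataset.

### 4. Quality control and the robust collection

Two dataset-level filters, both at p < 0.05 (strict), decide whether the
permissive calls are also *robust*:

* **Motif similarity.** The optimised matrix (converted back to
  frequencies by inverting the log-odds transform) is compared with the
  canonical motif. The statistic is the best ungapped alignment over all
  offsets with at least 4 overlapping columns and both orientations,
  scoring the mean per-column Pearson correlation of frequency columns
  over `max(La, Lb)` positions — overhangs count zero, so a short chance
  overlap cannot outscore a full-length faithful alignment (with a plain
  overlap mean, a column-shuffled 14-column motif achieves a perfect
  4-column chance alignment about 4% of the time, which would make even
  self-similarity marginal). Significance comes from a column-shuffling
  permutation null (1000 shuffles, seeded). Because permutations that fix
  the best-aligned columns leave the statistic unchanged, exact ties are
  common (~10% of shuffles); the p-value therefore uses the seeded
  randomised rank over the tied block, which is exactly uniform under the
  null — the plain count-ties-as-greater estimator is visibly lumpy and
  fails a KS uniformity check. Identical motifs score statistic 1.0 and
  p = 1/(n_null + 1).
* **Summit centrality.** Following the CentriMo idea, the per-peak
  best-hit distances (over *all* peaks, not only zone-passing ones —
  zone-filtered distances are concentrated by construction and would make
  the test vacuous) are compared with a uniform placement null: for each
  central half-width `w` in 5, 10, ..., H bp the count of hits within `w`
  is tested against Binomial(n, w/H) by the exact upper tail, and the
  smallest window p-value is Bonferroni-corrected by the number of
  windows. The test half-width H defaults to 250 bp but is capped at the
  maximum observed distance (rounded up to 5 bp): with 400 bp peaks the
  achievable distance range ends near 194 bp, and testing against a
  uniform on [0, 250] would mistake that geometric truncation for central
  enrichment. The Bonferroni scan keeps the test conservative — its
  false-positive rate on uniform hits measures below the nominal 5%.

Robust datasets route their calls into the robust collection; the
permissive output always contains the robust one.

## Downstream computations

* `unique_loci()` counts binding at the (chrom, start, end, TF) level:
  the same locus from several datasets of one TF counts once.
* `call_crms()` clusters unique loci into cis-regulatory modules with a
  defined, testable rule: pool the gaps between consecutive locus starts
  genome-wide, take the 0.25 quantile as the chaining threshold, chain
  neighbours at or below it, and keep chains of at least 3 loci. The
  learned threshold is recorded on the result; re-running on a CRM's own
  members reproduces it only at that recorded threshold (re-estimating
  the quantile on members alone would shrink it), which is how the
  idempotence of the clustering is defined and tested.
* `motif_similarity_matrix()` + `cluster_motifs()` build motif
  archetypes: `-log10` of the (symmetrised, conservative max) permutation
  p-values, complete-linkage clustering on the correlation distance
  between matrix rows, flat clusters cut at height 0.7. The cut height
  replaces a manual curation step and is deliberately configurable;
  `consensus_motif()` aligns members to the first (best offset and
  orientation) and averages frequency columns, padding overhangs with the
  uniform background. `collapse_to_archetypal_sites()` merges overlapping
  same-archetype sites into single archetypal loci.
* `enrich_with_universe()` and friends implement LOLA-style Fisher-exact
  region-set enrichment in three universe modes (explicit universe,
  differential against a second query, whole-database universe). Overlap
  is counted at the query-region level; the test is one-sided (greater)
  — enrichment is the tool's question, depletion maps to p = 1 — with
  Benjamini-Hochberg q-values across sets and ranking by ascending p then
  descending sample odds ratio.
* `region_stats`: genome coverage (merge, then divide by genome length),
  chromosome-preserving interval shuffling, bedtools-reldist-style
  relative distances anchored at interval midpoints, expression
  specificity `1 - H/log2(N)`, and pairwise co-localization (±50 bp
  expansion, merge, intersection fractions, Pearson correlation of the
  fraction matrix rows).

## The synthetic test bed

`make_genome()` draws i.i.d. bases at a chosen GC content; the default
study genome is 2 x 300 kb at 50% GC — large enough to place 400
non-overlapping 400 bp peaks and to sample GC-matched backgrounds, small
enough that a full pipeline run takes seconds. `plant_peaks()` writes one
motif instance per bound peak, sampled from the PFM's column
distributions (so scores have realistic spread; a consensus-only mode
exists for exact geometric tests) at `summit + round(N(0, 10))` on a
random strand, and records the exact coordinates in a truth table; decoy
peaks are untouched genome. `make_pfm()` draws one consensus base per
column with probability 0.85-0.97 over 14 columns (~22 bits): the long,
information-rich end of the TF spectrum — CTCF-class profiles — which is
the regime in which best-hit landscapes separate cleanly and which
dominates high-confidence direct-binding collections. This choice is a
fixture calibration, not a claim about all TFs: for short or degenerate
motifs the planted and decoy score distributions overlap heavily and no
threshold rule can reach high precision and recall simultaneously, which
mirrors the real pipeline's behaviour of failing or QC-rejecting
weak-motif datasets rather than over-calling them.

What the generator does *not* emulate: read-level noise and peak-calling
artefacts, sequence composition beyond i.i.d. bases (no repeats, no CpG
islands), co-occurring partner motifs, and indirect-binding peaks that
carry a *different* TF's motif. Passing tests therefore demonstrate the
internal correctness and calibration of the method under its own model
assumptions, not performance on any particular public dataset.

## Numerical choices and degenerate inputs

* Window scoring skips any window containing N (no background imputation),
  so assembly gaps cannot inflate scores. Ties between windows break to
  the leftmost start, then the plus strand.
* `max_entropy_threshold()` requires at least two distinct values;
  all-identical input is an error, not a guess.
* Zero-variance (uniform) motif columns contribute correlation 0 in the
  similarity statistic.
* Binomial tail p-values use the exact upper-tail sum; the final
  centrality p is floored at the smallest positive double so reported
  values stay in (0, 1].
* Every stochastic function takes a seed and restores the caller's RNG
  state; `run_dataset()` expands one global seed into fixed per-stage
  offsets so stages are individually reproducible, and identical
  configurations produce byte-identical output files.

## Problem sizes used by the test-suite and acceptance script

The standard conditions are 200 planted + 200 decoy peaks of 400 bp with
summit jitter SD 10 bp, evaluated over 5 seeds; QC specificity is
estimated on decoy-only datasets of 150 peaks (25 in the acceptance
script, 100 in the test-suite) run with identity optimisation — the
perceptron does not move the distance geometry that the centrality filter
tests, and the identity configuration isolates the QC behaviour. Oracle
blocks enumerate all 2x2 tables with total at most 30 exhaustively plus
10,000 random tables with totals 31-60, 1000 random histograms for the
threshold oracle, and 200 replicates for each calibration check.

## Known limitations

* The two marginal thresholds approximate a joint 2-D criterion; a
  diagonal trade-off between score and distance is not modelled.
* The ranking perceptron is a stated, testable stand-in for dataset-level
  PWM optimisation in general; it recovers corrupted columns and improves
  AUROC, but no claim is made that it reproduces any particular
  optimiser's trajectories.
* CRM calling with the quantile-gap rule depends on the locus density of
  the input; thresholds learned on one collection should not be reused on
  another without re-estimation.
* The enrichment tool assumes query regions are drawn from the universe;
  queries outside it are dropped with a message rather than resolved.
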