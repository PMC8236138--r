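# chipzone

Direct TF-DNA binding site calling from ChIP-seq peaks.

A ChIP-seq peak says a transcription factor (TF) was near a locus; it does
not say the TF actually read the DNA there. Peaks from indirect (tethered)
binding, open chromatin and assay noise carry no binding sequence at all.
`chipzone` extracts the **direct** interactions by demanding two
independent kinds of evidence per site — a strong position weight matrix
(PWM) match (computational) and proximity to the peak summit
(experimental) — and packages the surrounding ecosystem: dataset-specific
PWM optimization, quality control into permissive/robust collections,
cis-regulatory module (CRM) clustering, motif archetypes, Fisher-exact
region-set enrichment, and region statistics. It is aimed at regulatory
genomicists who work from MACS-style peak files, FASTA genomes and
JASPAR-format motifs.

## The method in brief

For one ChIP-seq dataset with peaks `P`, genome `G` and canonical motif
`M`:

1. **Optimize** the PWM `W = log2(p_smoothed / background)` with a ranking
   perceptron that maximizes the AUROC separating summit-centred ±50 bp
   peak sequences from %GC-matched 100 bp genomic background
   (best-so-far acceptance, so AUROC never decreases).
2. **Scan** every peak with the optimized PWM, both strands, keeping the
   single best window per peak; each hit is a point
   `(d, s)` = (distance from site midpoint to summit, normalized score
   `(score − min) / (max − min)`).
3. **Learn the enrichment zone**: Kapur maximum-entropy thresholds on the
   two marginals give `s*` (keep high) and `d*` (keep low); the zone is
   `{s ≥ s*} ∩ {d ≤ d*}`.
4. **Call** at most one TFBS per peak — the best rescanned hit, emitted
   iff inside the zone (the *permissive* set).
5. **Quality control**: the dataset enters the *robust* collection iff the
   optimized motif still matches the canonical one (permutation p < 0.05)
   and the best-hit distances are centrally enriched around summits
   (CentriMo-style Bonferroni binomial scan, p < 0.05).

Everything downstream (CRMs, archetypes, enrichment, coverage, reldist,
specificity `1 − H/log2 N`) operates on the called site sets. See the
methods vignette (`vignettes/chipzone-methods.Rmd`) for assumptions,
parameter defaults and limitations.

## Worked example

The package ships a seeded generator for its study conditions — a 2 × 300
kb genome, a 14-column information-rich motif, and 200 motif-planted plus
200 decoy peaks of 400 bp with summit jitter SD 10 bp:

```r
library(chipzone)
fx  <- standard_fixture(seed = 1)
run <- run_dataset(fx$peaks, fx$genome, fx$pfm,
                   run_config(seed = 1, dataset_id = "demo"))
print(run)
print(run$zone)
print(run$qc)
head(run$permissive_sites, 3)
```

```
Dataset demo: 400 peaks -> 214 sites (robust)
Enrichment zone: norm_score >= 0.7338 & dist_to_summit <= 81.1 bp (400 hits, 100 bins)
QC: similarity p = 0.000999 (pass), centrality p = 3.016e-99 (pass) -> ROBUST
  chrom start  end strand    score norm_score   peak_id dist_to_summit
1  chr1  1058 1072      - 4.188287  0.8892635 peak_0032             10
2  chr1  1908 1922      - 4.807654  0.8999860 peak_0122             10
3  chr1  6182 6196      + 6.186178  0.9238513 peak_0179             14
```

Reading this: of 400 peaks, 214 carried a best hit inside the learned
zone (a normalized PWM score of at least 0.734 within 81 bp of the
summit). Since half the peaks are motif-free decoys, ~200 calls is the
expected order; against the generator's truth table these calls reach
precision 0.93 and recall 0.99 at ±3 bp. Both QC filters pass, so the
same sites are also emitted as the robust set. Each site row gives the
BED-style half-open interval, strand, log-odds score, normalized score,
source peak and distance to that peak's summit.

`write_run(run, "out/")` serializes `permissive.bed`, `robust.bed`,
`qc.tsv` and `manifest.json`; reruns of the same configuration are
byte-identical. A thin command-line wrapper with `simulate`, `run`,
`enrich` and `coverage` subcommands lives at `inst/cli/chipzone.R`.

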