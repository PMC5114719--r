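---
title: "Methods: simulating and detecting RAP1 redistribution with telomere shortening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting RAP1 redistribution with telomere shortening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific setting

RAP1 is the shelterin subunit recruited to telomeres through TRF2, so the
amount of telomere-bound RAP1 scales with the amount of telomeric repeat DNA.
When telomeres shorten — as they do generation after generation in
telomerase-null (*Terc⁻/⁻*) cells — the pool of RAP1 that can no longer be
accommodated at telomeres becomes available to bind extratelomeric sites,
where RAP1 acts as a transcriptional regulator. The measurable ChIP-seq
signatures of this redistribution are:

1. a drop in telomeric repeat reads in the RAP1 ChIP (quantified on raw
   reads, before alignment, because perfect-repeat reads cannot be mapped
   uniquely);
2. a growing number of nontelomeric binding peaks in later generations; and
3. a flattening of the peak-density gradient that normally decays from the
   subtelomere toward the chromosome centre.

`rap1shift` implements this analysis end to end and, because the original raw
data live in an external repository, ships a synthetic read simulator with
planted ground truth so that every step can be validated against a known
answer.

## The simulator

### Genome

`build_genome()` produces `n_chrom` equal-length chromosomes (default
3 × 1 Mb — large enough for 20 distance strata of 25 kb per arm, small enough
for exhaustive oracles). Each chromosome carries a perfect `(TTAGGG)ₙ` tract
at its left end and the forward-strand image of the opposite G-strand,
`(CCCTAA)ₙ`, at its right end (default n = 800 units, i.e. 4.8 kb per end),
followed inward by a `subtelomere_len` window (default 25 kb). Writing the
right tract as `(CCCTAA)ₙ` makes both-strand scanning a genuine requirement
rather than a formality. Arm sequence is uniform random A/C/G/T, resampled
until no eight-unit telomeric run survives outside the recorded tracts, so an
exhaustive scan of the FASTA finds `(TTAGGG)₈` / `(CCCTAA)₈` only inside
them. Shorter repeat fragments may remain in the arms by construction; they
are harmless because the statistic requires eight consecutive units.

### Conditions and the redistribution model

A `condition_spec` couples a generation (G0/G1/G3) and a genotype (WT/KO)
with the simulator knobs. The default generation design uses telomere scales
1 / 0.6 / 0.3 and 40 / 240 / 600 planted nontelomeric sites (25 subtelomeric
everywhere; 15 gradient-placed interstitial sites plus 200 / 560 uniformly
placed "new" sites in G1 / G3), chosen so the planted counts grow roughly 6-
and 15-fold, the magnitude reported for the real experiment.

Wild-type ChIP reads are allocated to three compartments:

* telomere tracts, with probability `tel_frac × telomere_scale`
  (default `tel_frac = 0.3`): telomere-bound protein proportional to
  telomere length;
* planted sites, with probability
  `site_frac = 0.4 + tel_frac × (1 − telomere_scale)`, split between sites
  in proportion to their occupancy weights: the protein freed by tract
  shortening re-binds extratelomeric sites, which is precisely the
  redistribution hypothesis under study. Keeping the background fraction
  constant across generations also removes a bias in the input-normalized
  fold statistic that background reads landing in the tracts would otherwise
  introduce;
* uniform background otherwise.

Input samples, and knockout ChIP samples regardless of their site catalog,
draw all reads from the background compartment, making KO ChIP
distributionally identical to input — the property that lets KO samples
certify peak specificity. Reads are 50-mers sampled at points (no
fragment-length convolution: the point model keeps the Poisson assumptions
of the peak caller exact), from either strand with probability 1/2, with an
optional substitution error rate (default 0) and constant `I` base
qualities. Every output is a deterministic function of the seed.

### One reference genome, not one genome per generation

`build_genome()` can shorten the tracts physically via `telomere_scale`, and
that feature is exercised in the tests. The default pipeline, however,
simulates every generation on one shared reference genome and expresses
telomere shortening entirely through the ChIP allocation. The reason is
arithmetic: the headline statistic divides the ChIP telomeric read fraction
by the matched input's. If the input is drawn from a genome whose tracts
shrink by the same factor as the ChIP allocation, the factor cancels and the
normalized fold is constant by construction — no simulator could then
"recover" the telomere scale from it. In the real experiment the input
telomeric read count is buffered against telomere shortening by the large
load of interstitial telomeric-like repeats in the mouse genome, which do not
shorten; a toy genome whose arms are scrubbed of such repeats loses that
buffer, so we hold the reference fixed instead and let `telomere_scale` model
the biology it actually represents here: less telomere-bound protein.

## The telomeric read statistic

`count_telomeric_reads()` counts a read as telomeric iff the repeat unit
repeated `min_copies` times (default `(TTAGGG)₈`, 48 nt) occurs verbatim in
the read or its reverse complement. Matching is perfect-match only, each read
counts once, and `N` bases never match. One geometric subtlety: a 50-nt read
fully inside a perfect tract contains an in-phase 48-nt run only when its
start offset modulo 6 leaves at most 2 nt of slack, i.e. for about half of
the possible phases. This constant factor multiplies every sample equally and
cancels from all input- and reference-normalized folds; it only matters if
raw fractions are interpreted as tract coverage, which the package never
does.

`telomeric_enrichment()` forms `fold_vs_input = chip fraction / input
fraction` and normalizes to a designated reference sample (the G0 wild type
in the pipeline), mirroring an analysis where per-sample folds are expressed
relative to the telomerase-proficient baseline. Fractions rather than raw
counts are used so unequal depths cannot masquerade as enrichment.

## Mapping and coverage

`map_reads()` is a deliberately transparent stand-in for a production
aligner: a read maps iff its sequence or reverse complement occurs exactly
once in the genome (zero mismatches); reads with several occurrences are
multimapped and discarded — which is exactly what happens to perfect-repeat
telomeric reads, and why the telomeric statistic is computed before
alignment. Matching uses Biostrings' Aho–Corasick `PDict` machinery in a
count pass plus a position pass for the unique reads. `bin_coverage()`
histograms read starts into half-open 200-bp bins; the track sum equals the
mapped count by construction. For repeated large simulations whose purpose is
not to test the mapper, `alignments_from_truth()` converts the simulator's
recorded positions directly into an alignment set.

## Peak calling against the knockout

For each bin the control expectation is

```
lambda = max( (control + pseudocount) × chipLib / ctrlLib ,
              (ctrlLib / nBins + pseudocount) × chipLib / ctrlLib )
```

and the per-bin p-value is the exact upper Poisson tail `P(X ≥ chip |
lambda)`. Bins with `p < 1e-3` (raw cutoff, no multiplicity correction by
default; a Benjamini–Hochberg option exists) and `chip > lambda` are
significant, and significant bins separated by at most one non-significant
bin merge into a peak whose p-value is the member minimum and whose
enrichment is the member maximum of `count/lambda`.

Two numerical choices deserve comment. The pseudocount (0.5) prevents
zero-expectation singularities. The second term above — the genome-wide
background floor — exists because the local scaled control alone is
anti-conservative: wherever the control count fluctuates low, the estimated
expectation is too small and ordinary background bins in the ChIP reach
nominal significance far more often than the cutoff implies. Flooring the
expectation at the global background rate (the same device MACS uses for its
local lambda) restores calibration without affecting genuinely enriched
bins, whose counts exceed both terms by an order of magnitude. The
calibration is verified empirically in the acceptance suite under a
no-signal simulation, and the p-value computation itself is checked against
direct pmf summation to 1e-12 relative error.

The intended control is the matched knockout ChIP (wild type versus null
comparison); input can be supplied as the control instead. Peaks are labelled
by midpoint — telomeric inside a tract (and excluded from the nontelomeric
count), subtelomeric inside a subtelomere window, interstitial otherwise —
with half-open intervals, so a midpoint exactly on the tract/subtelomere
boundary belongs to the subtelomere. Overlap between peak sets uses a 1-bp
intersection threshold with A-side peak units, and fold changes of
nontelomeric counts are reported raw (2 decimals) and rounded half away from
zero, the convention that turns 894/147 into "6-fold".

## Distance-density profiles

`distance_profile()` assigns each nontelomeric peak to one of 20 equal-width
strata by its midpoint's distance to the nearest chromosome end
(`min(pos, L − 1 − pos)`; a flag switches the origin to the telomere-tract
boundary, since a figure's x-axis origin is a matter of convention).
Density is peaks per Mb of sequence actually available at that distance:
positions with distance < x number `min(2⌈x⌉, L)` per chromosome, which
handles the midpoint parity exactly and is verified against brute-force
enumeration. Midpoint assignment is used instead of bp-weighted overlap
because peaks are far narrower than strata. `gradient_stats()` summarizes a
profile by the Spearman correlation of density against stratum index
(`trend_corr`), the first-stratum density over the mean of the rest
(`subtel_ratio`), and the coefficient of variation across strata
(`evenness_cv`). The expected contrast is a strongly negative trend, a large
subtelomeric ratio and a large CV in G0, all collapsing toward flatness in
G3.

## Pipeline, determinism and problem sizes

`run_pipeline()` wires the stages together for the full generation × genotype
matrix: simulate (WT ChIP, KO ChIP, input per generation), quantify telomeric
content, map, bin, call peaks WT-vs-KO, classify, count and fold-change,
overlap the generations pairwise, and profile. All per-sample seeds derive
deterministically from one base seed; a rerun with the same config reproduces
every output byte for byte. Each stage logs its wall time and any failure
aborts with the stage name while earlier outputs remain on disk. Configs are
YAML with fail-fast validation (unknown keys are errors), and the JSON report
echoes the config and seed so every number is re-derivable.

Default problem sizes — a 3 Mb genome and 1e5 reads per sample — were chosen
so that binomial counting error on the telomeric statistic stays in the
few-percent range (the matched input contributes the dominant term, roughly
`1/sqrt(depth × input telomeric fraction)` ≈ 5%), while a full pipeline run
remains a desk-scale computation. Enrichment recoveries in the acceptance
suite are reported as means over 3 replicate simulations at that depth, a
replication protocol fixed in advance from this error budget.

## What the simulator does not emulate

Fragment-length convolution and read pileup shape, PCR duplicates, GC and
mappability bias, sequencing-error calibration, paired ends, diploidy,
subtelomeric segmental duplications, and — as noted above — interstitial
telomeric-like repeats in the arms. Consequently, passing tests demonstrate
that the statistics and the caller behave correctly under their stated
model, not that they would be unbiased on real libraries; in particular the
absolute ChIP allocation fractions are free parameters of the simulation,
not estimates of the real experiment's ChIP efficiency. The exact-match
mapper is a declared stand-in for whatever aligner produced the original
alignments, and the Poisson bin model is the package's own declared caller,
not a reconstruction of the original tool.
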