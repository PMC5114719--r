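# rap1shift

Simulated ChIP-seq analysis of how the shelterin subunit **RAP1**
redistributes across the genome as telomeres shorten.

RAP1 sits at telomeres via TRF2, so the telomere-bound pool scales with
telomeric repeat content. In successive telomerase-null generations
(G0 → G1 → G3) telomeres shorten, telomere-bound RAP1 drops, and the freed
protein accumulates at extratelomeric binding sites. In ChIP-seq this shows
up three ways, all implemented here as a tested pipeline:

1. **Telomeric repeat reads** — the fraction of raw 50-bp ChIP reads
   containing a perfect `(TTAGGG)₈` run on either strand, counted *before*
   alignment (perfect-repeat reads cannot map uniquely), normalized to the
   matched input and then to the G0 wild type:
   `fold = (chipFrac / inputFrac) / (chipFrac / inputFrac)₍G0₎`.
2. **Nontelomeric peaks** — per-bin Poisson enrichment of wild-type ChIP over
   the matched RAP1-knockout ChIP,
   `p = P(X ≥ chip | λ)`, `λ = max(local, global) scaled control + 0.5`,
   at a raw cutoff `p < 10⁻³`; peaks whose midpoint falls in a telomeric
   tract are excluded from the count, and counts are expressed as fold
   changes versus G0.
3. **Distance-density profiles** — nontelomeric peaks per Mb of available
   sequence in 20 strata of distance to the nearest chromosome end, with a
   subtelomere/arm density ratio and an evenness CV that quantify the
   collapse of the subtelomeric binding gradient.

Because the original raw data live in an external repository, the package
ships a deterministic read simulator with planted ground truth (telomeric
tracts, subtelomeric and interstitial sites, knockout and input controls)
that emulates the whole G0/G1/G3 × WT/KO design; every analysis step is
validated against known answers. See the methods vignette
(`vignettes/rap1shift-methods.Rmd`) for the model and all defaults.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → telomeric content → map/coverage → peaks/overlap → profiles),
each a thin narrative over the package functions, writing to `results/demo/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_telomeric_content.R
Rscript analysis/03_map_and_coverage.R
Rscript analysis/04_call_peaks.R
Rscript analysis/05_density_profiles.R
```

Stage 2 prints the telomeric-content table (demo seed 1):

```
  sample_id  total telomeric fraction fold_vs_input fold_vs_reference
 G0_WT_chip 100000     15164  0.15164    34.0764045        1.00000000
 G1_WT_chip 100000      9220  0.09220    18.1496063        0.53261506
 G3_WT_chip 100000      4581  0.04581     9.8304721        0.28848326
 G0_KO_chip 100000       482  0.00482     1.0831461        0.03178581
 G1_KO_chip 100000       477  0.00477     0.9389764        0.02755503
 G3_KO_chip 100000       466  0.00466     1.0000000        0.02934582
```

Wild-type telomeric enrichment falls with telomere length (1 → 0.53 → 0.29,
tracking the configured telomere scales 1/0.6/0.3), while knockout ChIP sits
at input level (`fold_vs_input ≈ 1`) — the specificity control. Stage 4
counts knockout-controlled nontelomeric peaks:

```
 condition n_peaks  fold fold_rounded
        G0      38  1.00            1
        G1     233  6.13            6
        G3     552 14.53           15
```

a 6- and 15-fold increase with shortening telomeres. Stage 5 summarizes the
positional redistribution: the subtelomeric density advantage drops from
about 21× (G0) to below 1× (G3) and the profile's evenness CV falls from
2.40 to 0.11 — binding spreads from the chromosome ends across the arms.

The same run is available programmatically:

```r
library(rap1shift)
report <- run_pipeline(default_run_config(seed = 1))
report$telomeric_table
report$peak_table
report$profile_stats
```

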